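#!/usr/bin/env Rscript
# Site frequency spectra of the simulated datasets: unfolded spectra
# polarized on the outgroup, their folded versions, and mode structure.
# The balanced locus shows the trimodal signature (singletons + two
# complementary high-frequency modes at the haplogroup sizes); the neutral
# comparison is L-shaped. Writes results/sfs/.

library(lambdasfs)

dat <- "results/data"; out <- "results/sfs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (name in c("balanced_locus", "neutral")) {
  aln <- read_alignment(file.path(dat, paste0(name, ".fasta")),
                        file.path(dat, paste0(name, "_metadata.tsv")))
  sf <- unfolded_sfs(aln, "outgroup_1")
  write_sfs(sf, file.path(out, paste0(name, "_unfolded.tsv")))
  write_sfs(fold(sf), file.path(out, paste0(name, "_folded.tsv")))
  modes <- find_modes(sf, min_separation = 5)
  write.table(modes, file.path(out, paste0(name, "_modes.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: S = %d of which %d polarized; top modes at class %s",
                  name, summary_stats(aln)$S,
                  sf$S,
                  paste(utils::head(modes$class, 3), collapse = ", ")))
  drop <- sf$polarization_log
  message(sprintf("  polarization: %s",
                  paste(names(drop), drop, sep = "=", collapse = " ")))
}

# within-haplogroup spectra of the balanced locus are L-shaped again
aln <- read_alignment(file.path(dat, "balanced_locus.fasta"),
                      file.path(dat, "balanced_locus_metadata.tsv"))
truth <- jsonlite::read_json(file.path(dat, "balanced_locus_truth.json"),
                             simplifyVector = TRUE)
labs <- classify_haplogroup(aln, truth$diagnostic_column,
                            unlist(truth$allele_map))
for (g in c("A-group", "B-group")) {
  ids <- names(labs)[labs == g]
  sfg <- unfolded_sfs(aln, "outgroup_1", subset = ids)
  write_sfs(sfg, file.path(out, paste0(tolower(sub("-group", "", g)),
                                       "_unfolded.tsv")))
  message(sprintf("%s (n=%d): S = %d, singleton share %.2f",
                  g, length(ids), sfg$S,
                  if (sfg$S > 0) sfg$counts[1] / sfg$S else NA))
}
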