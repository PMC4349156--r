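#!/usr/bin/env Rscript
# Summary statistics, haplogroup frequencies, differentiation and LD on the
# simulated balanced locus: a per-group polymorphism table (all samples,
# each haplogroup, each region), haplogroup frequencies per locality,
# Hudson F_ST with permutation P (haplogroups and regions), divergence to
# the outgroup, and the filtered |D'| LD matrix. Reads results/data/,
# writes results/tables/.

library(lambdasfs)

dat <- "results/data"; out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

aln <- read_alignment(file.path(dat, "balanced_locus.fasta"),
                      file.path(dat, "balanced_locus_metadata.tsv"))
truth <- jsonlite::read_json(file.path(dat, "balanced_locus_truth.json"),
                             simplifyVector = TRUE)
labs <- classify_haplogroup(aln, truth$diagnostic_column,
                            unlist(truth$allele_map))
ing <- aln$samples[aln$samples$role == "ingroup", ]

groups <- list(
  all = ing$id,
  `A-group` = names(labs)[labs == "A-group"],
  `B-group` = names(labs)[labs == "B-group"],
  North = ing$id[ing$region == "North"],
  South = ing$id[ing$region == "South"])

sumtab <- do.call(rbind, lapply(names(groups), function(g) {
  ss <- summary_stats(aln, groups[[g]])
  data.frame(group = g, n = ss$n, S = ss$S, H = ss$H,
             h = round(ss$h, 3), K = round(ss$K, 2),
             theta_S = signif(ss$theta_S, 3), pi = signif(ss$pi, 3),
             tajima_d = round(ss$tajima_d, 2))
}))
write.table(sumtab, file.path(out, "summary_stats.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("polymorphism by group:")
print(sumtab, row.names = FALSE)

freqs <- haplogroup_frequencies(labs, ing$locality, ing$region)
write.table(freqs, file.path(out, "haplogroup_frequencies.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

fst_hap <- hudson_fst(aln, labs, n_perm = 1000, seed = 42)
fst_reg <- hudson_fst(aln, setNames(ing$region, ing$id), n_perm = 1000,
                      seed = 42)
fst_tab <- data.frame(
  comparison = c("A-group vs B-group", "North vs South"),
  fst = round(c(fst_hap$estimate, fst_reg$estimate), 3),
  p_perm = signif(c(fst_hap$p_perm, fst_reg$p_perm), 3),
  n_perm = c(fst_hap$n_perm, fst_reg$n_perm))
write.table(fst_tab, file.path(out, "fst.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message("\ndifferentiation:")
print(fst_tab, row.names = FALSE)

div_ab <- divergence(aln, groups$`A-group`, groups$`B-group`)
div_out <- divergence(aln, groups$all, "outgroup_1")
div_tab <- data.frame(
  comparison = c("A-group vs B-group", "ingroup vs outgroup"),
  dxy = signif(c(div_ab$dxy, div_out$dxy), 3),
  da = signif(c(div_ab$da, div_out$da), 3),
  sd = signif(c(div_ab$sd, div_out$sd), 2))
write.table(div_tab, file.path(out, "divergence.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("\ndivergence (Jukes-Cantor corrected, per site):")
print(div_tab, row.names = FALSE)

ld <- ld_dprime(aln, exclude_singletons = TRUE, maf_min = 0.1)
write.table(round(ld$dprime, 3), file.path(out, "ld_dprime_maf10.tsv"),
            sep = "\t", quote = FALSE)
message(sprintf("\nLD: %d sites retained at MAF > 0.1; mean |D'| = %.2f",
                length(ld$retained_sites),
                mean(ld$dprime[upper.tri(ld$dprime)])))

st <- segregating_site_table(aln)
write_site_table(st, file.path(out, "segregating_sites.tsv"))
message(sprintf("segregating-site table: %d rows", nrow(st)))
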