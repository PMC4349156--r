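#!/usr/bin/env Rscript
# Generate the synthetic datasets for the analysis:
#  (a) the two-haplogroup balanced-locus emulation (122 sequences, 2,500 bp,
#      haplogroups of 43 and 79, ~20 diagnostic sites, singleton excess), and
#  (b) a neutral single-population comparison dataset of the same size.
# Writes FASTA + metadata + truth JSON under results/data/.

library(lambdasfs)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- preset_ckma_like()
message(sprintf(
  "balanced scenario: n=%d (A=%d, B=%d), L=%d, %d diagnostic sites,",
  cfg$n, cfg$balanced$n_a, cfg$balanced$n_b, cfg$L, cfg$balanced$d_fixed))
message(sprintf(
  "  within-group model beta(alpha=%.2f), theta_within=%.3f, seed=%d",
  cfg$model$param, cfg$balanced$theta_within, cfg$seed))

sim <- simulate_balanced_locus(cfg)
write_alignment(sim$alignment, file.path(out, "balanced_locus.fasta"),
                file.path(out, "balanced_locus_metadata.tsv"))
truth <- sim$truth
truth$model <- unclass(truth$model)
truth$allele_map <- as.list(truth$allele_map)  # keep base -> label names
jsonlite::write_json(
  c(unclass(truth), list(site_map = sim$site_map)),
  file.path(out, "balanced_locus_truth.json"),
  auto_unbox = TRUE, digits = NA)
message(sprintf("balanced dataset: %d segregating sites",
                summary_stats(sim$alignment)$S))

neutral_cfg <- scenario_config(
  n = 122, L = 2500,
  theta = 2 * 87 / expected_total_length(122, coal_model("beta", 1.1)),
  model = coal_model("beta", 1.1), seed = cfg$seed + 1)
neutral <- simulate_neutral(neutral_cfg)
write_alignment(neutral$alignment, file.path(out, "neutral.fasta"),
                file.path(out, "neutral_metadata.tsv"))
message(sprintf("neutral dataset: %d segregating sites",
                summary_stats(neutral$alignment)$S))

message("wrote ", out)
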