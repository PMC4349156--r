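test_that("summary statistics match the hand-verified 4 x 10 toy", {
  ss <- summary_stats(toy_aln())
  expect_equal(ss$n, 4)
  expect_equal(ss$S, 3)
  expect_equal(ss$H, 4)
  expect_equal(ss$h, 1)                       # all-distinct haplotypes
  expect_equal(ss$K, 10 / 6, tolerance = 1e-12)
  expect_equal(ss$theta_S, 3 / ((11 / 6) * 10), tolerance = 1e-12)
  expect_equal(ss$pi, (10 / 6) / 10, tolerance = 1e-12)
  expect_equal(ss$tajima_d, oracle_tajima_d(4, 3, 10 / 6), tolerance = 1e-12)
  expect_equal(round(ss$tajima_d, 3), 0.168)
})

test_that("degenerate summary cases: no variation, subsets, errors", {
  ident <- labeled_alignment(c(a = "ACGTACGT", b = "ACGTACGT",
                               c = "ACGTACGT"))
  ss <- summary_stats(ident)
  expect_equal(ss$S, 0)
  expect_equal(ss$H, 1)
  expect_equal(ss$h, 0)
  expect_equal(ss$K, 0)
  expect_true(is.na(ss$tajima_d))

  aln <- toy_aln()
  sub <- summary_stats(aln, subset = c("s1", "s2"))
  expect_equal(sub$n, 2)
  expect_equal(sub$S, 1)
  expect_error(summary_stats(aln, subset = "s1"), "at least 2")
  expect_error(summary_stats(aln, subset = c("s1", "nope")), "unknown")
})

test_that("Jukes-Cantor correction matches the closed form and its domain", {
  expect_equal(jc_correct(0), 0)
  expect_equal(jc_correct(0.1), -(3 / 4) * log(1 - 0.4 / 3))
  expect_equal(round(jc_correct(0.1), 5), 0.10733)
  expect_error(jc_correct(0.75), "domain error")
  # monotone increasing and >= argument on (0, 3/4)
  p <- seq(0.01, 0.74, by = 0.01)
  d <- jc_correct(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("divergence: gross, net and the symmetry / closed-form toys", {
  # groups with duplicated compositions: no net divergence beyond the
  # small-sample offset between within (excludes self-pairs) and between
  # means, which vanishes as group size grows
  m <- 10
  seqs <- c(rep("ACGTACGTAC", m), rep("ACGTACGTAT", m),
            rep("ACGTACGTAC", m), rep("ACGTACGTAT", m))
  names(seqs) <- sprintf("s%02d", seq_along(seqs))
  gx <- names(seqs)[1:(2 * m)]; gy <- names(seqs)[(2 * m + 1):(4 * m)]
  div <- divergence(labeled_alignment(seqs), gx, gy)
  expect_equal(div$dxy, jc_correct(0.05), tolerance = 1e-12)
  expect_lt(abs(div$da), 0.005)
  # symmetric in the group arguments
  div_rev <- divergence(labeled_alignment(seqs), gy, gx)
  expect_equal(div_rev$dxy, div$dxy)
  expect_equal(div_rev$da, div$da)

  # two monomorphic groups differing at 2 of 100 sites
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("A", 98), "C", "C"), collapse = "")
  aln <- labeled_alignment(c(x1 = a, x2 = a, y1 = b, y2 = b))
  div2 <- divergence(aln, c("x1", "x2"), c("y1", "y2"))
  expect_equal(div2$dxy, jc_correct(0.02), tolerance = 1e-12)
  expect_equal(round(div2$dxy, 5), 0.02027)
  expect_equal(div2$da, div2$dxy)
  expect_true(div2$sd > 0)

  expect_error(divergence(aln, c("x1", "x2"), c("x2", "y1")), "overlap")

  # da <= dxy on random inputs
  set.seed(21)
  for (r in 1:10) {
    aln <- random_aln(n = 6)
    ids <- aln$samples$id[aln$samples$role == "ingroup"]
    d <- divergence(aln, ids[1:3], ids[4:6])
    expect_lte(d$da, d$dxy + 1e-12)
  }
})

test_that("Hudson FST: toy values and permutation behaviour", {
  # 2+2 toy: within diffs 1 and 1, between diffs all exactly 3 -> 1 - 1/3
  aln <- labeled_alignment(c(a1 = "AAA", a2 = "AAC",
                             b1 = "GGG", b2 = "GGT"))
  part <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  fst <- hudson_fst(aln, part, n_perm = 300, seed = 5)
  expect_equal(fst$estimate, 1 - mean(c(1, 1)) / 3, tolerance = 1e-12)
  expect_equal(fst$estimate, 2 / 3, tolerance = 1e-12)
  expect_gte(fst$p_perm, 1 / (fst$n_perm + 1))

  # two internally monomorphic groups fixed for different haplotypes
  fixed <- labeled_alignment(c(a1 = "AAAA", a2 = "AAAA",
                               b1 = "GGGG", b2 = "GGGG"))
  expect_equal(hudson_fst(fixed, part, n_perm = 0)$estimate, 1)

  # identical haplotype compositions across groups are exchangeable:
  # no differentiation signal, non-significant permutation P
  seqs <- rep(c("AAAA", "CCCC"), 10)
  names(seqs) <- sprintf("s%02d", 1:20)
  same <- labeled_alignment(seqs)
  part20 <- setNames(c(rep("A", 10), rep("B", 10)), names(seqs))
  fst_same <- hudson_fst(same, part20, n_perm = 200, seed = 9)
  expect_lt(fst_same$estimate, 0.15)
  expect_gt(fst_same$p_perm, 0.1)

  expect_error(hudson_fst(aln, c(a1 = "A", a2 = "A", b1 = "B"), n_perm = 0),
               "at least 2 samples")
})

test_that("FST permutation P-values are uniform under random labels", {
  set.seed(31)
  n <- 12
  pvals <- replicate(200, {
    aln <- random_aln(n = n, L = 40)
    ids <- aln$samples$id[aln$samples$role == "ingroup"]
    part <- setNames(sample(rep(c("A", "B"), each = n / 2)), ids)
    hudson_fst(aln, part, n_perm = 99, seed = sample.int(1e6, 1))$p_perm
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("D-prime: complete LD, equilibrium, filters, label invariance", {
  # two sites in perfect coupling
  aln <- labeled_alignment(c(a = "AC", b = "AC", c = "GT", d = "GT"))
  ld <- ld_dprime(aln)
  expect_equal(unname(ld$dprime[1, 2]), 1)

  # independent sites with all four gametes at equilibrium frequencies
  eq <- labeled_alignment(c(a = "AC", b = "AT", c = "GC", d = "GT"))
  expect_equal(unname(ld_dprime(eq)$dprime[1, 2]), 0)

  # MAF filter: minor count 2 of 20 is dropped at maf_min = 0.1
  seqs <- c(rep("AC", 18), "GC", "GC")
  names(seqs) <- sprintf("s%02d", 1:20)
  seqs[1:10] <- "AT"  # second site at frequency 1/2
  aln2 <- labeled_alignment(seqs)
  expect_warning(ld2 <- ld_dprime(aln2, maf_min = 0.1), "fewer than 2")
  expect_equal(length(ld2$retained_sites), 1)
  expect_warning(ld_dprime(aln2, maf_min = 0.4), "fewer than 2")

  # singleton exclusion drops both (singleton-only) sites
  sing <- labeled_alignment(c(a = "AC", b = "AC", c = "AT", d = "GC"))
  expect_warning(ld3 <- ld_dprime(sing, exclude_singletons = TRUE),
                 "fewer than 2")
  expect_equal(length(ld3$retained_sites), 0)

  # |D'| invariant to which allele is called minor (complement a column)
  flip <- labeled_alignment(c(a = "GC", b = "GC", c = "AT", d = "AT"))
  expect_equal(unname(ld_dprime(flip)$dprime[1, 2]),
               unname(ld$dprime[1, 2]))
})

test_that("haplogroup frequency tables count and normalize per locality", {
  labels <- rep(c("A-allele", "B-allele"), c(43, 79))
  locs <- rep("Ice", 122)
  tab <- haplogroup_frequencies(labels, locs)
  expect_equal(tab$`A-allele`, 43)
  expect_equal(tab$`freq_A-allele`, 43 / 122, tolerance = 1e-12)
  expect_equal(tab$`freq_B-allele`, 79 / 122, tolerance = 1e-12)

  # regional aggregates and omission of empty localities
  tab2 <- haplogroup_frequencies(c("A", "A", "B"),
                                 c("Ice", "Ice", "Far"),
                                 regions = c("North", "North", "South"))
  expect_true(all(c("locality", "region") %in% tab2$level))
  expect_equal(nrow(tab2[tab2$level == "locality", ]), 2)
  expect_error(haplogroup_frequencies(c("A", "B"), "Ice"), "aligned")
})
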