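test_that("merger rates match definitions and independent integrals", {
  king <- coal_model("kingman")
  expect_equal(merger_rate(10, 2, king), 1)
  expect_error(merger_rate(5, 6, king), "domain error")
  expect_error(merger_rate(5, 1, king), "domain error")

  # beta rates against direct numerical integration of
  # x^(k-2) (1-x)^(b-k) against the Beta(2-alpha, alpha) density
  for (alpha in c(1, 1.25, 1.5, 1.9)) {
    m <- coal_model("beta", alpha)
    for (b in 3:6) {
      for (k in 2:b) {
        num <- integrate(function(x)
          x^(k - 2) * (1 - x)^(b - k) * dbeta(x, 2 - alpha, alpha),
          0, 1, rel.tol = 1e-10)$value
        expect_equal(merger_rate(b, k, m), num, tolerance = 1e-6)
      }
    }
  }
  expect_equal(merger_rate(3, 3, coal_model("beta", 1.5)), 0.25,
               tolerance = 1e-12)

  # dirac rates: psi^(k-2) (1-psi)^(b-k)
  expect_equal(merger_rate(4, 3, coal_model("dirac", 0.1)), 0.1 * 0.9)
  expect_equal(merger_rate(4, 4, coal_model("dirac", 1)), 1)

  expect_error(coal_model("beta", 2.5), "alpha")
  expect_error(coal_model("dirac", 0), "psi")
  expect_error(coal_model("exp_growth", -1), "growth")
})

test_that("genealogy simulation obeys Kingman and winner-take-all laws", {
  set.seed(61)
  # n = 2 Kingman: E[tmrca] = 1
  tm <- replicate(4000, simulate_genealogy(2, coal_model("kingman"))$tmrca)
  expect_lt(abs(mean(tm) - 1), 3 * sd(tm) / sqrt(length(tm)))

  # dirac psi = 1: single merger of all lineages at the first event
  g <- simulate_genealogy(8, coal_model("dirac", 1), seed = 9)
  expect_equal(nrow(g$event_log), 1)
  expect_equal(g$event_log$k, 8)
  expect_equal(g$branch_lengths_by_class[2:6], rep(0, 5))

  # bookkeeping invariants
  g2 <- simulate_genealogy(10, coal_model("beta", 1.3), seed = 4)
  expect_equal(g2$total_length, sum(g2$branch_lengths_by_class))
  expect_gte(g2$tmrca, g2$event_log$wait[1])
  expect_error(simulate_genealogy(1, coal_model("kingman")), "n >= 2")

  # identical seed gives identical genealogy
  g3 <- simulate_genealogy(10, coal_model("beta", 1.3), seed = 4)
  expect_identical(g2$branch_lengths_by_class, g3$branch_lengths_by_class)
})

test_that("expected spectra: Kingman closed form and model limits", {
  k4 <- expected_normalized_sfs(4, coal_model("kingman"))
  expect_equal(k4$phi, c(6, 3, 2) / 11)
  expect_equal(k4$method, "closed_form")

  # beta alpha = 2 and zero-growth models are routed to exact Kingman
  expect_equal(expected_normalized_sfs(20, coal_model("beta", 2))$phi,
               expected_normalized_sfs(20, coal_model("kingman"))$phi)
  expect_equal(expected_normalized_sfs(20, coal_model("exp_growth", 0))$method,
               "closed_form")
  expect_equal(expected_normalized_sfs(20, coal_model("alg_growth", 0))$method,
               "closed_form")

  # normalization holds for Monte-Carlo spectra
  e <- expected_normalized_sfs(15, coal_model("dirac", 0.3), reps = 2000,
                               seed = 3)
  expect_equal(sum(e$phi), 1, tolerance = 1e-9)
  expect_true(all(e$se >= 0))

  # caching: same key returns the identical object, bit for bit
  e2 <- expected_normalized_sfs(15, coal_model("dirac", 0.3), reps = 2000,
                                seed = 3)
  expect_identical(e$phi, e2$phi)
})

test_that("Monte-Carlo engine agrees with closed-form oracles at n = 3", {
  for (m in list(coal_model("beta", 1.2), coal_model("dirac", 0.4))) {
    e <- expected_normalized_sfs(3, m, reps = 5e4, seed = 17)
    truth <- oracle_phi_n3(m)
    expect_lt(max(abs(e$phi - truth)), 3.5 * max(e$se))
  }
})

test_that("engine agrees with a brute-force subset-enumeration simulator", {
  set.seed(71)
  for (m in list(coal_model("beta", 1.1), coal_model("dirac", 0.5))) {
    brute <- oracle_sim_phi(6, m, reps = 4000)
    e <- expected_normalized_sfs(6, m, reps = 4e4, seed = 19)
    # both are Monte Carlo; allow combined error of the cruder oracle
    expect_lt(max(abs(e$phi - brute)), 0.02)
  }
})

test_that("R and C++ simulation paths agree on the expected spectrum", {
  m <- coal_model("beta", 1.4)
  set.seed(77)
  L <- rowsum(
    do.call(rbind, lapply(1:3000, function(i)
      simulate_genealogy(8, m)$branch_lengths_by_class)),
    rep(1, 3000))
  phi_r <- as.numeric(L / sum(L))
  e <- expected_normalized_sfs(8, m, reps = 3e4, seed = 23)
  expect_lt(max(abs(phi_r - e$phi)), 0.015)
})

test_that("singleton weight is monotone in alpha and psi", {
  phi1 <- vapply(c(1, 1.5), function(a)
    expected_normalized_sfs(50, coal_model("beta", a), reps = 2e4,
                            seed = 29)$phi[1], numeric(1))
  expect_gt(phi1[1], phi1[2])
  phi1d <- vapply(c(0.05, 0.6), function(p)
    expected_normalized_sfs(50, coal_model("dirac", p), reps = 2e4,
                            seed = 29)$phi[1], numeric(1))
  expect_lt(phi1d[1], phi1d[2])
})

test_that("expected total branch length recursion matches known values", {
  # Kingman: 2 * harmonic(n-1)
  expect_equal(expected_total_length(10, coal_model("kingman")),
               2 * sum(1 / (1:9)), tolerance = 1e-12)
  # dirac psi = 1: two-phase argument by hand: all n merge at rate 1,
  # so E[T] = n * 1
  expect_equal(expected_total_length(7, coal_model("dirac", 1)), 7)
  # Monte-Carlo agreement for beta
  m <- coal_model("beta", 1.2)
  set.seed(83)
  tl <- replicate(4000, simulate_genealogy(12, m)$total_length)
  expect_lt(abs(mean(tl) - expected_total_length(12, m)),
            3 * sd(tl) / sqrt(length(tl)))
})

test_that("growth spectra skew toward singletons as growth strengthens", {
  e0 <- expected_normalized_sfs(30, coal_model("kingman"))
  eb <- expected_normalized_sfs(30, coal_model("exp_growth", 10),
                                reps = 2e4, seed = 31)
  ea <- expected_normalized_sfs(30, coal_model("alg_growth", 10),
                                reps = 2e4, seed = 31)
  expect_gt(eb$phi[1], e0$phi[1])
  expect_gt(ea$phi[1], e0$phi[1])
})
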