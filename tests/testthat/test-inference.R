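test_that("l2 distance and its root match hand arithmetic", {
  obs <- sfs_from_counts(c(5, 3, 2), 4)  # normalized (0.5, 0.3, 0.2)
  expect_equal(l2_distance(obs, c(0.4, 0.4, 0.2)), 0.02, tolerance = 1e-12)
  expect_equal(l2_root(obs, c(0.4, 0.4, 0.2)), sqrt(0.02), tolerance = 1e-12)
  expect_equal(l2_distance(obs, c(0.5, 0.3, 0.2)), 0)
  expect_error(l2_distance(obs, c(0.5, 0.5)), "mismatch")
  expect_error(l2_distance(sfs_from_counts(c(0, 0, 0), 4), c(1, 0, 0)),
               "S = 0")
})

test_that("G test: toy value, perfect fit, pooling conservation", {
  # printed toy: O = (10, 0, 6), E = (8, 4, 4), no pooling at threshold 1
  obs <- sfs_from_counts(c(10, 0, 6), 4)
  g <- g_test(obs, c(8, 4, 4) / 16, fitted_params = 0, pool_min = 1)
  expect_equal(g$g_stat, 2 * (10 * log(10 / 8) + 6 * log(6 / 4)),
               tolerance = 1e-12)
  expect_lt(abs(g$g_stat - 9.329), 1e-3)
  expect_equal(g$df, 2)

  # observed exactly S * phi: G = 0
  phi <- expected_normalized_sfs(5, coal_model("kingman"))$phi
  perfect <- sfs_from_counts(round(phi * 100), 5)
  # use its own normalized counts as phi so E = O exactly
  g0 <- g_test(perfect, perfect$counts / perfect$S, pool_min = 1)
  expect_equal(g0$g_stat, 0)

  # pooling a sparse right tail preserves totals and shrinks class count
  kphi <- expected_normalized_sfs(122, coal_model("kingman"))$phi
  set.seed(97)
  o122 <- sfs_from_counts(as.integer(rmultinom(1, 90, kphi)), 122)
  gp <- g_test(o122, kphi)
  expect_lt(gp$n_pooled, 121)
  expect_equal(sum(gp$pooled_E), o122$S, tolerance = 1e-9)
  expect_equal(sum(gp$pooled_O), o122$S)
  expect_true(all(gp$pooled_E >= 5))

  # df <= 0: G reported, p flagged unavailable
  tiny <- sfs_from_counts(c(3, 2), 3)
  gt <- g_test(tiny, c(0.6, 0.4), fitted_params = 1, pool_min = 5)
  expect_true(is.finite(gt$g_stat))
  expect_true(is.na(gt$p))
})

test_that("approximate log-likelihood matches the multinomial form", {
  obs <- sfs_from_counts(c(2, 1), 3)
  ll <- approx_loglik(obs, c(2 / 3, 1 / 3))
  expect_equal(as.numeric(ll), 2 * log(2 / 3) + log(1 / 3), tolerance = 1e-12)
  expect_equal(round(as.numeric(ll), 4), -1.9095)

  # maximized on the simplex at phi = xi / S
  phis <- list(c(0.5, 0.5), c(0.8, 0.2), c(2 / 3, 1 / 3), c(0.6, 0.4))
  lls <- vapply(phis, function(p) as.numeric(approx_loglik(obs, p)),
                numeric(1))
  expect_equal(which.max(lls), 3)

  # zero-phi cells are floored and logged
  obs2 <- sfs_from_counts(c(1, 1, 1), 4)
  ll2 <- approx_loglik(obs2, c(0.5, 0.5, 0))
  expect_equal(attr(ll2, "floored"), 1)
  expect_true(is.finite(ll2))
  expect_error(approx_loglik(sfs_from_counts(c(0, 0), 3), c(0.5, 0.5)),
               "S = 0")
})

test_that("model ranking by approximate likelihood matches delta-G ordering", {
  set.seed(101)
  e <- expected_normalized_sfs(20, coal_model("dirac", 0.4), reps = 2e4,
                               seed = 37)
  obs <- sfs_from_counts(as.integer(rmultinom(1, 80, e$phi)), 20)
  kphi <- expected_normalized_sfs(20, coal_model("kingman"))
  ll_d <- as.numeric(approx_loglik(obs, e))
  ll_k <- as.numeric(approx_loglik(obs, kphi))
  g_d <- g_test(obs, e, pool_min = 1)$g_stat
  g_k <- g_test(obs, kphi, pool_min = 1)$g_stat
  expect_equal(ll_d > ll_k, g_d < g_k)
})

test_that("fit_model recovers truth placed on the grid boundary and interior", {
  # observed set exactly to the Kingman closed form on a coarse beta grid:
  # alpha_hat lands at the boundary 2 where the expectation is exact
  kphi <- expected_normalized_sfs(25, coal_model("kingman"))$phi
  obs <- sfs_from_counts(as.integer(round(kphi * 400)), 25)
  fit <- fit_model(obs, "beta", grid = seq(1, 2, by = 0.1), reps = 3000,
                   seed = 7)
  expect_equal(fit$best_param, 2)
  expect_equal(fit$l2_min, fit$l2_kingman, tolerance = 1e-9)
  expect_lte(fit$l2_min, min(fit$l2_curve))

  # dirac family on the same Kingman-true data: psi_hat near the smallest
  # grid value (the near-Kingman limit)
  fitd <- fit_model(obs, "dirac", grid = seq(0.005, 0.5, by = 0.045),
                    reps = 3000, seed = 7)
  expect_lte(fitd$best_param, 0.05)

  # kingman "fit" is just the null evaluation
  fitk <- fit_model(obs, "kingman")
  expect_equal(fitk$l2_min, fitk$l2_kingman)

  expect_error(fit_model(obs, "beta", grid = numeric(0)), "empty")
  expect_error(fit_model(fold(obs), "beta"), "unfolded")
})

test_that("l2 curves are reproducible and tighten with more replicates", {
  set.seed(107)
  e <- expected_normalized_sfs(20, coal_model("beta", 1.4), reps = 2e4,
                               seed = 41)
  obs <- sfs_from_counts(as.integer(rmultinom(1, 70, e$phi)), 20)
  grid <- seq(1, 2, by = 0.05)
  f1 <- fit_model(obs, "beta", grid = grid, reps = 2000, seed = 13)
  f2 <- fit_model(obs, "beta", grid = grid, reps = 2000, seed = 13)
  expect_identical(f1$l2_curve, f2$l2_curve)

  # spread of best_param across re-seeded fits shrinks as reps grows
  spread <- function(reps) {
    best <- vapply(1:8, function(s)
      fit_model(obs, "beta", grid = grid, reps = reps,
                seed = 1000 + s)$best_param, numeric(1))
    diff(range(best))
  }
  expect_lte(spread(4000), spread(200) + 1e-12)
})

test_that("fit results serialize to JSON with the l2 curve", {
  obs <- sfs_from_counts(c(12, 5, 3, 1), 5)
  fit <- fit_model(obs, "beta", grid = c(1, 1.5, 2), reps = 500, seed = 3)
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".tsv")
  write_fit_result(fit, jp, cp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$best_param, fit$best_param)
  expect_equal(back$l2_curve, fit$l2_curve, tolerance = 1e-12)
  curve <- read.delim(cp)
  expect_equal(nrow(curve), 3)
})
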