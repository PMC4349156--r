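#' Specify a coalescent model
#'
#' A model is a family tag plus its single parameter: the Kingman coalescent
#' (no parameter), the Beta(2-alpha, alpha) Lambda-coalescent (`alpha` in
#' `[1, 2]`; `alpha = 2` is exactly Kingman), the point-mass (Dirac)
#' coalescent (`psi` in `(0, 1]`; `psi -> 0` approaches Kingman), and two
#' growth-time-changed Kingman models with backwards relative population
#' size `nu(t) = exp(-beta t)` (exponential) or `nu(t) = (1 + t)^(-gamma)`
#' (algebraic); pair-coalescence intensity scales as `1/nu(t)`, and
#' `beta = 0` / `gamma = 0` reduce exactly to Kingman.
#'
#' @param family one of `"kingman"`, `"beta"`, `"dirac"`, `"exp_growth"`,
#'   `"alg_growth"`.
#' @param param the family's parameter (`alpha`, `psi`, `beta` or `gamma`);
#'   omitted for Kingman.
#' @return an object of class `coal_model`.
#' @export
coal_model <- function(family = c("kingman", "beta", "dirac", "exp_growth",
                                  "alg_growth"),
                       param = NULL) {
  family <- match.arg(family)
  if (family == "kingman") {
    if (!is.null(param)) stop_input("kingman takes no parameter")
  } else {
    if (is.null(param) || length(param) != 1 || !is.finite(param))
      stop_input("family '", family, "' needs a single finite parameter")
    if (family == "beta" && (param < 1 || param > 2))
      stop_input("parameter error: alpha must be in [1, 2]")
    if (family == "dirac" && (param <= 0 || param > 1))
      stop_input("parameter error: psi must be in (0, 1]")
    if (family %in% c("exp_growth", "alg_growth") && param < 0)
      stop_input("parameter error: growth rate must be >= 0")
  }
  structure(list(family = family, param = param), class = "coal_model")
}

#' @export
print.coal_model <- function(x, ...) {
  cat("coal_model:", x$family,
      if (!is.null(x$param)) sprintf("(param = %g)", x$param), "\n")
  invisible(x)
}

# does the model collapse to the exact Kingman coalescent?
is_kingman_like <- function(model) {
  switch(model$family,
         kingman = TRUE,
         beta = model$param == 2,
         exp_growth = model$param == 0,
         alg_growth = model$param == 0,
         FALSE)
}

#' Lambda-coalescent merger rate
#'
#' Rate `lambda_{b,k}` at which a *given* set of `k` of `b` active lineages
#' merges: Kingman has `lambda_{b,2} = 1` and no larger mergers; the
#' Beta(2-alpha, alpha) coalescent has
#' `lambda_{b,k} = B(k - alpha, b - k + alpha) / B(2 - alpha, alpha)`;
#' the Dirac coalescent has `lambda_{b,k} = psi^(k-2) (1-psi)^(b-k)`.
#' The total rate of `k`-mergers is `choose(b, k) * lambda_{b,k}`.
#'
#' @param b active lineage count.
#' @param k merger size, `2 <= k <= b` (vectorized).
#' @param model a `coal_model` of family kingman, beta or dirac (growth
#'   families are time-changed Kingman and use pair mergers only).
#' @return numeric vector of rates, one per `k`.
#' @export
merger_rate <- function(b, k, model) {
  if (any(k < 2 | k > b))
    stop_input("domain error: merger size k must satisfy 2 <= k <= b")
  if (is_kingman_like(model)) return(as.numeric(k == 2))
  switch(model$family,
    beta = {
      a <- model$param
      exp(lbeta(k - a, b - k + a) - lbeta(2 - a, a))
    },
    dirac = {
      psi <- model$param
      psi^(k - 2) * (1 - psi)^(b - k)
    },
    exp_growth = ,
    alg_growth = as.numeric(k == 2),
    stop_input("no merger rate for family ", model$family)
  )
}

# matrix of total k-merger rates choose(b,k) * lambda_{b,k};
# rows/cols indexed directly by b and k (entries with k<2 or k>b are 0)
merger_rate_table <- function(n, model) {
  rates <- matrix(0, n, n)
  for (b in 2:n) {
    k <- 2:b
    rates[b, k] <- choose(b, k) * merger_rate(b, k, model)
  }
  rates
}

#' Simulate one genealogy under a coalescent model
#'
#' Block-counting simulation: at `b` lineages draw an exponential waiting
#' time with the total merger rate, pick the merger size `k` proportional to
#' `choose(b, k) * lambda_{b,k}`, and merge `k` uniformly chosen blocks,
#' accumulating the branch length subtending `i` leaves into class `i`.
#' Growth families use Kingman pair mergers with the waiting time obtained
#' by (analytic) inversion of the cumulative pair-coalescence intensity.
#'
#' @param n number of leaves (`>= 2`).
#' @param model a `coal_model`.
#' @param seed optional RNG seed (caller's RNG state is restored).
#' @param keep_lineages if `TRUE`, record for every inter-event interval the
#'   leaf sets of all active blocks (needed to drop mutations onto branches).
#' @return an object of class `genealogy`: list with
#'   `branch_lengths_by_class` (`L_1 .. L_{n-1}`), `total_length`, `tmrca`,
#'   `event_log` (data frame `wait`, `k`, `b_before`) and, when requested,
#'   `intervals` (list of `list(wait, blocks)`).
#' @export
simulate_genealogy <- function(n, model, seed = NULL, keep_lineages = FALSE) {
  if (!is.numeric(n) || n < 2) stop_input("input error: need n >= 2 leaves")
  n <- as.integer(n)
  with_seed(seed, {
    growth <- model$family %in% c("exp_growth", "alg_growth") &&
      !is_kingman_like(model)
    rates <- if (!growth) merger_rate_table(n, model)
    blocks <- lapply(seq_len(n), identity)
    L <- numeric(n - 1)
    tmrca <- 0
    waits <- numeric(0); ks <- integer(0); bs <- integer(0)
    intervals <- if (keep_lineages) vector("list", 0)
    while (length(blocks) > 1) {
      b <- length(blocks)
      if (growth) {
        wait <- growth_wait(b, tmrca, model)
        k <- 2L
      } else {
        tot <- sum(rates[b, 2:b])
        wait <- rexp(1, tot)
        k <- if (b == 2) 2L else
          sample(2:b, 1, prob = rates[b, 2:b])
      }
      sizes <- lengths(blocks)
      for (s in sizes) L[s] <- L[s] + wait
      if (keep_lineages)
        intervals[[length(intervals) + 1L]] <-
          list(wait = wait, blocks = blocks)
      tmrca <- tmrca + wait
      waits <- c(waits, wait); ks <- c(ks, k); bs <- c(bs, b)
      merge_idx <- sample.int(b, k)
      merged <- unlist(blocks[merge_idx])
      blocks <- c(blocks[-merge_idx], list(merged))
    }
    structure(list(branch_lengths_by_class = L, total_length = sum(L),
                   tmrca = tmrca,
                   event_log = data.frame(wait = waits, k = ks,
                                          b_before = bs),
                   intervals = intervals, n = n, model = model),
              class = "genealogy")
  })
}

# waiting time to the next pair merger for a growth model, starting at
# backwards time t with b lineages; analytic inversion of the cumulative
# intensity C(b,2) * integral of 1/nu(u) du
growth_wait <- function(b, t, model) {
  C <- choose(b, 2)
  E <- rexp(1)
  if (model$family == "exp_growth") {
    beta <- model$param
    log(exp(beta * t) + beta * E / C) / beta - t
  } else {
    g <- model$param
    ((1 + t)^(g + 1) + (g + 1) * E / C)^(1 / (g + 1)) - (1 + t)
  }
}

#' Exact expected total branch length under a Lambda-coalescent
#'
#' First-step recursion on the block-counting chain:
#' `g(b) = b / rate(b) + sum_k P(b -> b - k + 1) g(b - k + 1)`, `g(1) = 0`,
#' where `rate(b)` is the total merger rate at `b` lineages. Used, e.g., to
#' calibrate a mutation rate to a target number of segregating sites, since
#' `E[S] = (theta / 2) E[total length]`. Not available for growth families.
#'
#' @param n sample size.
#' @param model a `coal_model` of family kingman, beta or dirac.
#' @return expected total branch length in coalescent units.
#' @export
expected_total_length <- function(n, model) {
  if (model$family %in% c("exp_growth", "alg_growth") &&
      !is_kingman_like(model))
    stop_input("no closed recursion for growth families; use Monte Carlo")
  if (is_kingman_like(model)) return(2 * harmonic(n - 1))
  rates <- merger_rate_table(n, model)
  g <- numeric(n)
  for (b in 2:n) {
    k <- 2:b
    tot <- sum(rates[b, k])
    g[b] <- b / tot + sum(rates[b, k] / tot * g[b - k + 1])
  }
  g[n]
}

#' Expected normalized site frequency spectrum of a coalescent model
#'
#' Returns `phi_i = E[L_i] / E[total length]`, the probability that a
#' segregating site falls in derived-allele-count class `i` under the
#' infinite-sites model. The Kingman coalescent (and families at their
#' Kingman limit) uses the closed form `phi_i` proportional to `1/i`; all
#' other families use Monte-Carlo means over simulated genealogies, with
#' per-class delta-method standard errors. Monte-Carlo results are cached
#' per session, keyed by `(n, family, param, reps, seed)`.
#'
#' @param n sample size.
#' @param model a `coal_model`.
#' @param reps Monte-Carlo replicates (ignored for closed-form cases).
#' @param seed RNG seed for the Monte-Carlo draw (mandatory provenance).
#' @param force_monte_carlo simulate even when a closed form exists (used to
#'   validate the Monte-Carlo engine against the Kingman closed form).
#' @return an object of class `expected_sfs`: list with `n`, `family`,
#'   `param`, `phi` (length `n-1`, sums to 1), `se`, `method`
#'   (`"closed_form"` or `"monte_carlo"`), `reps`, `seed`.
#' @export
expected_normalized_sfs <- function(n, model, reps = 1e5, seed = 1L,
                                    force_monte_carlo = FALSE) {
  n <- as.integer(n)
  if (n < 2) stop_input("need n >= 2")
  if (is_kingman_like(model) && !force_monte_carlo) {
    i <- seq_len(n - 1)
    phi <- (1 / i) / harmonic(n - 1)
    return(structure(list(n = n, family = model$family,
                          param = model$param, phi = phi,
                          se = numeric(n - 1), method = "closed_form",
                          reps = NA_integer_, seed = NA_integer_),
                     class = "expected_sfs"))
  }
  if (reps < 1) stop_input("need reps >= 1 for Monte Carlo")
  key <- sprintf("%d|%s|%.12g|%d|%d", n, model$family,
                 model$param %||% NA_real_,
                 as.integer(reps), as.integer(seed))
  hit <- the$sfs_cache[[key]]
  if (!is.null(hit)) return(hit)
  acc <- with_seed(seed, {
    if (model$family %in% c("exp_growth", "alg_growth")) {
      type <- if (model$family == "exp_growth") 1L else 2L
      sim_growth_sfs_cpp(n, as.integer(reps), type, model$param)
    } else {
      sim_lambda_sfs_cpp(n, as.integer(reps), merger_rate_table(n, model))
    }
  })
  reps <- as.integer(reps)
  meanL <- acc$sum_L / reps
  meanT <- acc$sum_T / reps
  phi <- meanL / meanT
  varL <- acc$sum_L2 / reps - meanL^2
  varT <- acc$sum_T2 / reps - meanT^2
  covLT <- acc$sum_LT / reps - meanL * meanT
  se <- sqrt(pmax(varL - 2 * phi * covLT + phi^2 * varT, 0) / reps) / meanT
  out <- structure(list(n = n, family = model$family, param = model$param,
                        phi = phi, se = se, method = "monte_carlo",
                        reps = reps, seed = as.integer(seed)),
                   class = "expected_sfs")
  the$sfs_cache[[key]] <- out
  out
}

#' @export
print.expected_sfs <- function(x, ...) {
  cat(sprintf("expected_sfs: %s%s, n=%d, %s%s\n", x$family,
              if (!is.null(x$param)) sprintf("(%g)", x$param) else "",
              x$n, x$method,
              if (x$method == "monte_carlo")
                sprintf(" (reps=%d, seed=%d)", x$reps, x$seed) else ""))
  invisible(x)
}

#' Write an expected spectrum as TSV with provenance header
#'
#' @param x an `expected_sfs`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expected_sfs <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n=%d family=%s param=%s method=%s reps=%s seed=%s",
                     x$n, x$family,
                     if (is.null(x$param)) "NA" else format(x$param),
                     x$method, x$reps, x$seed), con)
  writeLines("class\tphi\tse", con)
  writeLines(sprintf("%d\t%.10g\t%.3g", seq_along(x$phi), x$phi, x$se), con)
  invisible(path)
}
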