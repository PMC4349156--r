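#' Classical polymorphism summary statistics
#'
#' Computes, for a set of ingroup sequences, the segregating-site count `S`,
#' number of distinct haplotypes `H`, haplotype diversity
#' `h = (n/(n-1)) (1 - sum p_i^2)`, mean pairwise difference `K`, Watterson's
#' estimator `theta_S = S / (a1 * effective_length)` with
#' `a1 = sum_{i=1}^{n-1} 1/i`, nucleotide diversity `pi = K /
#' effective_length`, and Tajima's D with the standard variance constants.
#'
#' `S`, `H` and `theta_S` use complete-case columns: any column with a gap or
#' `N` in a retained sequence is dropped (and dropped from
#' `effective_length`). Pairwise differences (`K`, hence `pi`) use pairwise
#' deletion: a column is compared for a pair whenever both members have a
#' called base there. On gap-free data the two rules coincide.
#'
#' @param aln a `labeled_alignment`.
#' @param subset optional character vector of ingroup sample ids.
#' @return a list of class `summary_stats` with fields `n`, `S`, `H`, `h`,
#'   `K`, `theta_S`, `pi`, `tajima_d` (NA when `S = 0`) and
#'   `effective_length`.
#' @export
summary_stats <- function(aln, subset = NULL) {
  m <- ingroup_matrix(aln, subset)
  n <- nrow(m)
  if (n < 2) stop_input("need at least 2 ingroup samples")
  cols <- effective_columns(aln, subset)
  L <- length(cols)
  mc <- m[, cols, drop = FALSE]

  S <- sum(apply(mc, 2, function(x) length(unique(x))) > 1)

  hap <- apply(mc, 1, paste, collapse = "")
  H <- length(unique(hap))
  p <- as.numeric(table(hap)) / n
  h <- (n / (n - 1)) * (1 - sum(p^2))

  D <- pairwise_diff_matrix(m)
  K <- mean(D[upper.tri(D)])

  a1 <- harmonic(n - 1)
  theta_S <- if (L > 0) S / (a1 * L) else NA_real_
  pi <- if (L > 0) K / L else NA_real_

  tajima_d <- if (S > 0) tajima_d_stat(n, S, K) else NA_real_

  structure(list(n = n, S = S, H = H, h = h, K = K, theta_S = theta_S,
                 pi = pi, tajima_d = tajima_d, effective_length = L),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(
    "n=%d S=%d H=%d h=%.3f K=%.3f theta_S=%.5g pi=%.5g D=%s (L_eff=%d)\n",
    x$n, x$S, x$H, x$h, x$K, x$theta_S, x$pi,
    ifelse(is.na(x$tajima_d), "NA", sprintf("%.3f", x$tajima_d)),
    x$effective_length))
  invisible(x)
}

# Tajima's (1989) D from n, S and mean pairwise difference K
tajima_d_stat <- function(n, S, K) {
  a1 <- harmonic(n - 1)
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (K - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# pairwise difference counts with pairwise deletion of gap/N columns
pairwise_diff_matrix <- function(m) {
  n <- nrow(m)
  ok <- m != "-" & m != "N"
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      d <- sum(m[i, comp] != m[j, comp])
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Jukes-Cantor distance correction
#'
#' Converts an observed proportion of differing sites into an estimated
#' number of substitutions per site under the one-parameter equal-rates
#' model: `d = -(3/4) log(1 - 4p/3)`.
#'
#' @param p proportion of differing sites, `0 <= p < 3/4`.
#' @return corrected distance per site.
#' @export
jc_correct <- function(p) {
  if (any(p < 0 | p >= 3 / 4))
    stop_input("domain error: Jukes-Cantor correction requires 0 <= p < 3/4")
  -(3 / 4) * log(1 - 4 * p / 3)
}

#' Gross and net between-group nucleotide divergence
#'
#' Computes Jukes-Cantor corrected gross divergence per site `Dxy` (mean
#' between-group difference) and net divergence `Da = Dxy - (pi_x + pi_y)/2`
#' with within-group diversities also Jukes-Cantor corrected, plus the
#' delta-method standard deviation of the Jukes-Cantor estimate,
#' `sd = sqrt(p (1-p) / L) / (1 - 4p/3)`.
#'
#' @param aln a `labeled_alignment`.
#' @param group_x,group_y disjoint character vectors of sample ids (may
#'   include outgroup samples, e.g. for interspecific divergence).
#' @return a list of class `divergence_result` with fields `dxy`, `da`, `sd`.
#' @export
divergence <- function(aln, group_x, group_y) {
  if (length(group_x) == 0 || length(group_y) == 0)
    stop_input("both groups must be non-empty")
  if (length(intersect(group_x, group_y)))
    stop_input("input error: groups overlap")
  unknown <- setdiff(c(group_x, group_y), aln$samples$id)
  if (length(unknown))
    stop_input("unknown sample id(s): ", paste(unknown, collapse = ", "))
  m <- aln$matrix[aln$samples$id %in% c(group_x, group_y), , drop = FALSE]
  keep_cols <- which(colSums(m == "-" | m == "N") == 0L)
  L <- length(keep_cols)
  if (L == 0) stop_input("no comparable columns between the groups")
  m <- m[, keep_cols, drop = FALSE]
  mx <- m[rownames(m) %in% group_x, , drop = FALSE]
  my <- m[rownames(m) %in% group_y, , drop = FALSE]

  between <- outer(seq_len(nrow(mx)), seq_len(nrow(my)),
                   Vectorize(function(i, j) sum(mx[i, ] != my[j, ])))
  p_between <- mean(between) / L
  dxy <- jc_correct(p_between)

  within_pi <- function(g) {
    if (nrow(g) < 2) return(0)
    D <- pairwise_diff_matrix(g)
    jc_correct(mean(D[upper.tri(D)]) / L)
  }
  da <- dxy - (within_pi(mx) + within_pi(my)) / 2

  sd_jc <- sqrt(p_between * (1 - p_between) / L) / (1 - 4 * p_between / 3)

  structure(list(dxy = dxy, da = da, sd = sd_jc),
            class = "divergence_result")
}

#' Hudson's FST with permutation test
#'
#' Estimates `FST = 1 - Hw/Hb` from nucleotide differences, where `Hw` is the
#' group-size-weighted mean of per-group mean pairwise differences and `Hb`
#' the mean pairwise difference between samples in different groups. The
#' permutation P-value randomly reassigns samples to groups preserving group
#' sizes: `P = (# permuted estimates >= observed + 1) / (n_perm + 1)`.
#'
#' @param aln a `labeled_alignment`.
#' @param partition named character vector mapping sample id to group label;
#'   every group must have at least 2 samples.
#' @param n_perm number of permutations (default 1000); `0` skips the test.
#' @param seed RNG seed for the permutations, recorded in the result.
#' @return a list of class `fst_result` with fields `estimate`, `p_perm`
#'   (NA when `n_perm = 0`), `n_perm`, `seed`, `groups`.
#' @export
hudson_fst <- function(aln, partition, n_perm = 1000, seed = 1L) {
  ids <- names(partition)
  unknown <- setdiff(ids, aln$samples$id)
  if (length(unknown))
    stop_input("unknown sample id(s): ", paste(unknown, collapse = ", "))
  groups <- factor(unname(partition))
  if (nlevels(groups) < 2) stop_input("need at least 2 groups")
  if (any(table(groups) < 2))
    stop_input("input error: every group needs at least 2 samples")
  m <- aln$matrix[match(ids, aln$samples$id), , drop = FALSE]
  D <- pairwise_diff_matrix(m)
  est <- fst_from_distmat(D, groups)
  p_perm <- NA_real_
  if (n_perm > 0) {
    perm_est <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      fst_from_distmat(D, sample(groups))
    }, numeric(1)))
    p_perm <- (sum(perm_est >= est) + 1) / (n_perm + 1)
  }
  structure(list(estimate = est, p_perm = p_perm, n_perm = n_perm,
                 seed = seed, groups = levels(groups)),
            class = "fst_result")
}

# Hudson FST from a pairwise difference matrix and a group factor
fst_from_distmat <- function(D, groups) {
  n <- length(groups)
  same <- outer(groups, groups, "==")
  ut <- upper.tri(D)
  hw_parts <- tapply(seq_len(n), groups, function(idx) {
    sub <- D[idx, idx, drop = FALSE]
    mean(sub[upper.tri(sub)])
  })
  sizes <- as.numeric(table(groups))
  Hw <- sum(sizes * hw_parts) / sum(sizes)
  Hb <- mean(D[ut & !same])
  if (Hb == 0) return(0)
  1 - Hw / Hb
}

#' Pairwise linkage disequilibrium (D-prime) matrix
#'
#' Computes `|D'|` for every pair of retained biallelic sites on haploid
#' sequences (gametic phase known). `D = p_AB - p_A p_B` and `D' = D / Dmax`
#' with the standard frequency-constrained bounds. Singleton sites always
#' show `|D'| = 1` and can be excluded; a minor-allele-frequency filter
#' (strictly greater than `maf_min`) removes low-frequency noise.
#'
#' @param aln a `labeled_alignment`.
#' @param subset optional ingroup sample ids.
#' @param exclude_singletons drop sites whose minor allele count is 1.
#' @param maf_min retain only sites with minor allele frequency `> maf_min`.
#' @return a list of class `ld_matrix` with fields `dprime` (symmetric
#'   matrix of `|D'|`, site indices as dimnames), `retained_sites`, `filter`.
#' @export
ld_dprime <- function(aln, subset = NULL, exclude_singletons = FALSE,
                      maf_min = 0) {
  m <- ingroup_matrix(aln, subset)
  n <- nrow(m)
  cols <- effective_columns(aln, subset)
  keep <- integer(0)
  allele1 <- character(0)
  for (j in cols) {
    tab <- sort(table(m[, j]), decreasing = TRUE)
    if (length(tab) != 2) next
    minor <- as.integer(tab[2])
    if (exclude_singletons && minor <= 1) next
    if (minor / n <= maf_min) next
    keep <- c(keep, j)
    allele1 <- c(allele1, names(tab)[1])
  }
  if (length(keep) < 2) {
    warning("fewer than 2 retained sites after filtering; empty LD matrix")
    dp <- matrix(numeric(0), 0, 0)
  } else {
    x <- m[, keep, drop = FALSE] ==
      matrix(allele1, n, length(keep), byrow = TRUE)
    k <- length(keep)
    dp <- matrix(NA_real_, k, k, dimnames = list(keep, keep))
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        pA <- mean(x[, a]); pB <- mean(x[, b])
        pAB <- mean(x[, a] & x[, b])
        D <- pAB - pA * pB
        dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
                else min(pA * pB, (1 - pA) * (1 - pB))
        dp[a, b] <- dp[b, a] <- if (dmax == 0) 0 else abs(D) / dmax
      }
    }
    diag(dp) <- 1
  }
  structure(list(dprime = dp, retained_sites = keep,
                 filter = list(exclude_singletons = exclude_singletons,
                               maf_min = maf_min)),
            class = "ld_matrix")
}

#' Haplogroup frequencies per locality and region
#'
#' Cross-tabulates per-sample haplogroup labels against localities, with
#' relative frequencies, and appends regional aggregates when a region
#' vector is supplied.
#'
#' @param labels per-sample haplogroup labels (e.g. from
#'   [classify_haplogroup()]).
#' @param localities per-sample locality codes, aligned with `labels`.
#' @param regions optional per-sample region labels for aggregate rows.
#' @return a data frame with columns `unit` (locality or region), `level`
#'   (`"locality"` or `"region"`), one count column per haplogroup label,
#'   `n`, and one `freq_<label>` column per label.
#' @export
haplogroup_frequencies <- function(labels, localities, regions = NULL) {
  if (length(labels) != length(localities))
    stop_input("labels and localities must be aligned per sample")
  make_rows <- function(units, level) {
    tab <- table(units, labels)
    lev <- colnames(tab)
    out <- data.frame(unit = rownames(tab), level = level,
                      stringsAsFactors = FALSE)
    for (l in lev) out[[l]] <- as.integer(tab[, l])
    out$n <- as.integer(rowSums(tab))
    for (l in lev) out[[paste0("freq_", l)]] <- out[[l]] / out$n
    out[out$n > 0, , drop = FALSE]
  }
  res <- make_rows(localities, "locality")
  if (!is.null(regions)) res <- rbind(res, make_rows(regions, "region"))
  rownames(res) <- NULL
  res
}
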