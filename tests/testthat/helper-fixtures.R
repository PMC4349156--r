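# in-code fixtures and independent oracles shared across test files

# the 4 x 10 toy alignment with hand-verified summary statistics
toy_aln <- function() {
  labeled_alignment(c(s1 = "AAAAAAAAAA", s2 = "AAAAAAAAAT",
                      s3 = "AAAAAAAATT", s4 = "AAAAAAATTT"))
}

# alignment with one outgroup sequence appended
aln_with_outgroup <- function(ingroup, outgroup) {
  seqs <- c(ingroup, outgroup_1 = outgroup)
  meta <- data.frame(
    id = names(seqs), locality = "Sy1", region = "none",
    role = c(rep("ingroup", length(ingroup)), "outgroup"),
    taxon = "synthetic", stringsAsFactors = FALSE)
  labeled_alignment(seqs, meta)
}

# random ingroup+outgroup alignment for property-style checks
random_aln <- function(n = 8, L = 60, p_var = 0.2) {
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  mat <- matrix(rep(anc, each = n), nrow = n)
  nvar <- rbinom(1, L, p_var)
  if (nvar > 0) {
    cols <- sample.int(L, nvar)
    for (j in cols) {
      carriers <- sample.int(n, sample.int(n - 1, 1))
      mat[carriers, j] <- sample(setdiff(bases, anc[j]), 1)
    }
  }
  seqs <- apply(mat, 1, paste, collapse = "")
  names(seqs) <- sprintf("r%02d", seq_len(n))
  aln_with_outgroup(seqs, paste(anc, collapse = ""))
}

# ---- independent coalescent oracles ----------------------------------------

# closed-form expected branch lengths by class at n = 3 for any
# Lambda-coalescent, from the block-counting chain by hand:
#   E[L_1] = 3 / R + p2,  E[L_2] = p2,
# with R = 3*lambda_32 + lambda_33 and p2 = 3*lambda_32 / R
# (after a pair merger the two remaining blocks wait Exp(1)).
oracle_phi_n3 <- function(model) {
  l32 <- merger_rate(3, 2, model)
  l33 <- merger_rate(3, 3, model)
  R <- 3 * l32 + l33
  p2 <- 3 * l32 / R
  L1 <- 3 / R + p2
  L2 <- p2
  c(L1, L2) / (L1 + L2)
}

# brute-force Lambda-coalescent simulator over explicitly enumerated merger
# subsets (structurally different from the package's size-then-choice path);
# returns the mean normalized spectrum over reps
oracle_sim_phi <- function(n, model, reps) {
  sumL <- numeric(n - 1)
  sumT <- 0
  for (r in seq_len(reps)) {
    sizes <- rep(1L, n)
    L <- numeric(n - 1)
    while (length(sizes) > 1) {
      b <- length(sizes)
      subsets <- unlist(lapply(2:b, function(k)
        combn(b, k, simplify = FALSE)), recursive = FALSE)
      rates <- vapply(subsets, function(s) merger_rate(b, length(s), model),
                      numeric(1))
      wait <- rexp(1, sum(rates))
      for (s in sizes) L[s] <- L[s] + wait
      pick <- subsets[[sample.int(length(subsets), 1, prob = rates)]]
      sizes <- c(sizes[-pick], sum(sizes[pick]))
    }
    sumL <- sumL + L
    sumT <- sumT + sum(L)
  }
  sumL / sumT
}

# hand implementation of Tajima's D from first principles (variance
# constants written out independently of the package code path)
oracle_tajima_d <- function(n, S, K) {
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (K - S / a1) /
    sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}
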