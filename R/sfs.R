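#' Unfolded site frequency spectrum by outgroup polarization
#'
#' Builds the unfolded site frequency spectrum `xi_1 .. xi_{n-1}` of the
#' ingroup, polarized by a single designated outgroup sequence. For each
#' ingroup-biallelic retained column whose outgroup base equals one of the
#' two ingroup alleles, the derived allele is the non-outgroup allele and
#' the class equal to its carrier count is incremented. Columns where the
#' outgroup carries a gap, `N` or a third state cannot be polarized and are
#' dropped; ingroup sites with three or more alleles are dropped (the
#' infinite-sites spectrum has no class for them). All drops are tallied in
#' `polarization_log`.
#'
#' @param aln a `labeled_alignment` containing the outgroup sample.
#' @param outgroup_id sample id with `role = "outgroup"`.
#' @param subset optional ingroup sample ids.
#' @return an object of class `sfs`: list with `n`, `counts` (length `n-1`),
#'   `folded = FALSE`, `S = sum(counts)` and `polarization_log` (named
#'   counts: `used`, `monomorphic`, `multiallelic`, `outgroup_missing`,
#'   `outgroup_third_allele`).
#' @export
unfolded_sfs <- function(aln, outgroup_id, subset = NULL) {
  i_out <- which(aln$samples$id == outgroup_id)
  if (length(i_out) != 1 || aln$samples$role[i_out] != "outgroup")
    stop_input("input error: outgroup sample '", outgroup_id,
               "' not present with role = outgroup")
  m <- ingroup_matrix(aln, subset)
  n <- nrow(m)
  if (n < 2) stop_input("need at least 2 ingroup samples")
  cols <- effective_columns(aln, subset)
  outg <- aln$matrix[i_out, ]
  counts <- integer(n - 1)
  log <- c(used = 0L, monomorphic = 0L, multiallelic = 0L,
           outgroup_missing = 0L, outgroup_third_allele = 0L)
  for (j in cols) {
    tab <- table(m[, j])
    if (length(tab) == 1) { log["monomorphic"] <- log["monomorphic"] + 1L; next }
    if (length(tab) > 2) { log["multiallelic"] <- log["multiallelic"] + 1L; next }
    ob <- outg[j]
    if (ob %in% c("-", "N")) {
      log["outgroup_missing"] <- log["outgroup_missing"] + 1L; next
    }
    alleles <- names(tab)
    if (!(ob %in% alleles)) {
      log["outgroup_third_allele"] <- log["outgroup_third_allele"] + 1L; next
    }
    derived <- setdiff(alleles, ob)
    i <- as.integer(tab[derived])
    counts[i] <- counts[i] + 1L
    log["used"] <- log["used"] + 1L
  }
  new_sfs(n, counts, folded = FALSE, polarization_log = log)
}

new_sfs <- function(n, counts, folded, polarization_log = NULL) {
  expected_len <- if (folded) floor(n / 2) else n - 1L
  if (length(counts) != expected_len)
    stop_input("counts must have length ", expected_len)
  if (any(counts < 0)) stop_input("counts must be non-negative")
  structure(list(n = as.integer(n), counts = as.integer(counts),
                 folded = folded, S = sum(counts),
                 polarization_log = polarization_log),
            class = "sfs")
}

#' Construct a site frequency spectrum from counts
#'
#' @param counts class counts `xi_1 .. xi_{n-1}` (unfolded) or
#'   `eta_1 .. eta_{floor(n/2)}` (folded).
#' @param n ingroup sample size.
#' @param folded logical flag.
#' @return an `sfs` object.
#' @export
sfs_from_counts <- function(counts, n, folded = FALSE) {
  new_sfs(n, counts, folded)
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("%s sfs: n=%d, S=%d, %d classes\n",
              if (x$folded) "folded" else "unfolded", x$n, x$S,
              length(x$counts)))
  invisible(x)
}

#' Fold an unfolded site frequency spectrum
#'
#' `eta_i = xi_i + xi_{n-i}` for `i < n/2`, and `eta_{n/2} = xi_{n/2}` for
#' even `n`. Two high-frequency modes at complementary classes (the
#' signature of a balanced polymorphism) fold into a single mode.
#'
#' @param sfs an unfolded `sfs`.
#' @return a folded `sfs` preserving `S`.
#' @export
fold <- function(sfs) {
  stopifnot(inherits(sfs, "sfs"))
  if (sfs$folded) stop_input("input error: spectrum is already folded")
  n <- sfs$n
  half <- floor(n / 2)
  eta <- integer(half)
  for (i in seq_len(half)) {
    eta[i] <- if (i == n - i) sfs$counts[i]
              else sfs$counts[i] + sfs$counts[n - i]
  }
  new_sfs(n, eta, folded = TRUE, polarization_log = sfs$polarization_log)
}

#' Normalize a site frequency spectrum
#'
#' Returns the relative spectrum `xi_i / S`, which sums to 1.
#'
#' @param sfs an `sfs` with `S > 0`.
#' @return numeric vector of relative class frequencies.
#' @export
normalize_sfs <- function(sfs) {
  stopifnot(inherits(sfs, "sfs"))
  if (sfs$S == 0) stop_input("cannot normalize a spectrum with S = 0")
  sfs$counts / sfs$S
}

#' Find modes of a site frequency spectrum
#'
#' Identifies local maxima of the count vector. Plateaus (ties) are merged
#' and reported at their leftmost class; boundary classes count as maxima
#' when they exceed their single neighbour. Modes closer than
#' `min_separation` classes to a higher mode are suppressed. Results are
#' ranked by height.
#'
#' @param sfs an `sfs`.
#' @param min_separation minimum class distance between reported modes.
#' @return data frame with columns `class` and `count`, ordered by
#'   decreasing count; zero rows for an all-zero spectrum.
#' @export
find_modes <- function(sfs, min_separation = 2) {
  stopifnot(inherits(sfs, "sfs"))
  x <- sfs$counts
  empty <- data.frame(class = integer(), count = integer())
  if (all(x == 0)) return(empty)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  is_max <- vapply(seq_len(k), function(i) {
    left <- if (i > 1) r$values[i - 1] else -Inf
    right <- if (i < k) r$values[i + 1] else -Inf
    r$values[i] > left && r$values[i] > right && r$values[i] > 0
  }, logical(1))
  cand <- data.frame(class = starts[is_max], count = r$values[is_max])
  if (nrow(cand) == 0) return(empty)
  cand <- cand[order(-cand$count, cand$class), , drop = FALSE]
  kept <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    if (nrow(kept) == 0 ||
        all(abs(kept$class - cand$class[i]) >= min_separation))
      kept <- rbind(kept, cand[i, ])
  }
  rownames(kept) <- NULL
  kept
}

#' Write a site frequency spectrum as TSV
#'
#' Two columns (`class`, `count`) with a header comment recording `n`, the
#' folded flag, `S` and the polarization log; read back by [read_sfs()].
#'
#' @param sfs an `sfs`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sfs <- function(sfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n=%d folded=%s S=%d", sfs$n,
                     tolower(as.character(sfs$folded)), sfs$S), con)
  if (!is.null(sfs$polarization_log))
    writeLines(paste0("# polarization: ",
                      paste(names(sfs$polarization_log),
                            sfs$polarization_log,
                            sep = "=", collapse = " ")), con)
  writeLines("class\tcount", con)
  writeLines(sprintf("%d\t%d", seq_along(sfs$counts), sfs$counts), con)
  invisible(path)
}

#' Read a site frequency spectrum written by [write_sfs()]
#'
#' @param path TSV path.
#' @return an `sfs` object.
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta <- regmatches(hdr[1], regexec("n=(\\d+) folded=(true|false)", hdr[1]))[[1]]
  if (length(meta) != 3) stop_input("malformed SFS header in ", path)
  n <- as.integer(meta[2])
  folded <- meta[3] == "true"
  body <- read.delim(text = lines[!startsWith(lines, "#")])
  counts <- integer(if (folded) floor(n / 2) else n - 1L)
  counts[body$class] <- body$count
  new_sfs(n, counts, folded)
}
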