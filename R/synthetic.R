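#' Configure a synthetic-data scenario
#'
#' Describes a coalescent simulation of aligned haploid sequences under the
#' infinite-sites model. The expected number of mutations on a genealogy is
#' `(theta / 2) * total branch length` in coalescent units. An outgroup
#' sequence is generated from the ancestral sequence with Jukes-Cantor
#' substitutions whose rate is chosen so that the *expected observed*
#' per-site divergence equals `outgroup_divergence` (multiple hits are
#' allowed only on the outgroup lineage).
#'
#' The optional `balanced` block describes a two-haplogroup balanced locus:
#' two independent within-haplogroup genealogies (sizes `n_a`, `n_b`) under
#' the same model with per-haplogroup mutation rate `theta_within`,
#' `d_fixed` diagnostic columns fixed-different between the haplogroups
#' (derived alternately in one or the other group relative to the
#' outgroup), and a per-sample probability `swap_rate` of exchanging a
#' contiguous block of diagnostic columns for the other haplogroup's
#' alleles, emulating rare recombinants.
#'
#' @param n ingroup sample size.
#' @param L alignment length in sites.
#' @param theta scaled mutation rate per locus (single-population scenario).
#' @param model a `coal_model`.
#' @param seed integer seed; the same seed yields byte-identical output.
#' @param balanced optional list with elements `n_a`, `n_b`, `d_fixed`,
#'   `theta_within`, `swap_rate`.
#' @param outgroup_divergence expected per-site divergence of the outgroup.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(n, L, theta = 0, model = coal_model("kingman"),
                            seed = 1L, balanced = NULL,
                            outgroup_divergence = 0.02) {
  stopifnot(inherits(model, "coal_model"))
  if (n < 2 || L < 1) stop_input("need n >= 2 and L >= 1")
  if (theta < 0 || outgroup_divergence < 0) stop_input("rates must be >= 0")
  if (!is.null(balanced)) {
    need <- c("n_a", "n_b", "d_fixed", "theta_within", "swap_rate")
    if (!all(need %in% names(balanced)))
      stop_input("balanced block needs: ", paste(need, collapse = ", "))
    if (balanced$n_a + balanced$n_b != n)
      stop_input("n_a + n_b must equal n")
    if (balanced$n_a < 2 || balanced$n_b < 2)
      stop_input("input error: each haplogroup needs at least 2 samples")
    if (balanced$d_fixed > L) stop_input("d_fixed must be <= L")
    if (balanced$theta_within < 0 || balanced$swap_rate < 0)
      stop_input("rates must be >= 0")
  }
  structure(list(n = as.integer(n), L = as.integer(L), theta = theta,
                 model = model, seed = as.integer(seed),
                 balanced = balanced,
                 outgroup_divergence = outgroup_divergence),
            class = "scenario_config")
}

# drop Poisson((theta/2) * total length) mutations onto a genealogy's
# branches; returns a list of leaf-index vectors (carriers), one per mutation
drop_mutations <- function(gen, theta) {
  if (theta == 0) return(list())
  waits <- vapply(gen$intervals, `[[`, numeric(1), "wait")
  nblocks <- vapply(gen$intervals, function(iv) length(iv$blocks), integer(1))
  weights <- waits * nblocks  # total branch length in each interval
  M <- rpois(1, theta / 2 * sum(weights))
  if (M == 0) return(list())
  iv_idx <- sample.int(length(weights), M, replace = TRUE, prob = weights)
  lapply(iv_idx, function(i) {
    blocks <- gen$intervals[[i]]$blocks
    blocks[[sample.int(length(blocks), 1)]]
  })
}

# JC outgroup lineage: per-site Poisson substitution chain at a hit rate
# chosen so the expected observed divergence matches `div`
mutate_outgroup <- function(anc, div) {
  if (div == 0) return(anc)
  bases <- c("A", "C", "G", "T")
  rate <- jc_correct(div)
  hits <- rpois(length(anc), rate)
  out <- anc
  for (j in which(hits > 0)) {
    b <- out[j]
    for (h in seq_len(hits[j])) b <- sample(setdiff(bases, b), 1)
    out[j] <- b
  }
  out
}

new_simulated_dataset <- function(alignment, truth, site_map) {
  structure(list(alignment = alignment, truth = truth, site_map = site_map),
            class = "simulated_dataset")
}

#' Simulate a neutral single-population alignment
#'
#' One genealogy under the configured coalescent model; mutation count
#' Poisson with mean `(theta / 2) * total branch length`; each mutation is
#' placed on a branch with probability proportional to branch length and
#' assigned a fresh alignment column (infinite sites: at most one mutation
#' per column), the derived base differing from the ancestral one. A single
#' outgroup sequence diverges from the ancestral sequence by Jukes-Cantor
#' substitutions.
#'
#' @param config a `scenario_config` without a `balanced` block.
#' @return a `simulated_dataset`: list with `alignment`
#'   (`labeled_alignment`, ingroup + one outgroup), `truth` (the config) and
#'   `site_map` (data frame `column`, `kind`).
#' @export
simulate_neutral <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(config$balanced))
    stop_input("config has a balanced block; use simulate_balanced_locus()")
  with_seed(config$seed, {
    n <- config$n; L <- config$L
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, L, replace = TRUE)
    gen <- simulate_genealogy(n, config$model, keep_lineages = TRUE)
    carriers <- drop_mutations(gen, config$theta)
    free_cols <- sample.int(L)
    if (length(carriers) > length(free_cols))
      stop_input("alignment too short for the realized mutation count")
    mat <- matrix(rep(anc, each = n), nrow = n)
    site_map <- data.frame(column = integer(), kind = character())
    for (m in seq_along(carriers)) {
      col <- free_cols[m]
      mat[carriers[[m]], col] <- sample(setdiff(bases, anc[col]), 1)
      site_map <- rbind(site_map,
                        data.frame(column = col, kind = "ingroup_mutation"))
    }
    outg <- mutate_outgroup(anc, config$outgroup_divergence)
    full <- rbind(mat, outg)
    ids <- c(sprintf("sim_%03d", seq_len(n)), "outgroup_1")
    rownames(full) <- ids
    meta <- data.frame(
      id = ids,
      locality = c(rep("Sy1", n), "Out"),
      region = c(rep("none", n), "none"),
      role = c(rep("ingroup", n), "outgroup"),
      taxon = c(rep("synthetic ingroup", n), "synthetic outgroup"),
      stringsAsFactors = FALSE)
    aln <- new_labeled_alignment(meta, full)
    new_simulated_dataset(aln, config,
                          site_map[order(site_map$column), , drop = FALSE])
  })
}

#' Simulate a two-haplogroup balanced locus
#'
#' Emulates the genealogical footprint of long-standing balancing
#' selection: the two balanced allelic classes behave like separate
#' populations, each with its own coalescent genealogy, separated by a set
#' of diagnostic columns fixed-different between them. The resulting
#' unfolded spectrum has a singleton mode from the within-group genealogies
#' plus two high-frequency modes at the complementary haplogroup sizes.
#'
#' @param config a `scenario_config` with a `balanced` block.
#' @return a `simulated_dataset`. The `truth` element additionally records
#'   `diagnostic_columns` and the first diagnostic column's allele map, so
#'   [classify_haplogroup()] can be applied to the output.
#' @export
simulate_balanced_locus <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  bal <- config$balanced
  if (is.null(bal))
    stop_input("config lacks a balanced block; use simulate_neutral()")
  with_seed(config$seed, {
    n <- config$n; L <- config$L
    n_a <- bal$n_a; n_b <- bal$n_b
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, L, replace = TRUE)
    mat <- matrix(rep(anc, each = n), nrow = n)
    idx_a <- seq_len(n_a)
    idx_b <- n_a + seq_len(n_b)

    cols <- sample.int(L)
    diag_cols <- sort(cols[seq_len(bal$d_fixed)])
    free_cols <- cols[-seq_len(bal$d_fixed)]

    # diagnostic columns: derived alternately in group A and group B
    derived_base <- character(bal$d_fixed)
    derived_in_a <- rep(c(TRUE, FALSE), length.out = bal$d_fixed)
    for (d in seq_len(bal$d_fixed)) {
      col <- diag_cols[d]
      derived_base[d] <- sample(setdiff(bases, anc[col]), 1)
      mat[if (derived_in_a[d]) idx_a else idx_b, col] <- derived_base[d]
    }

    # within-haplogroup genealogies and mutations
    site_rows <- list()
    used <- 0
    for (g in 1:2) {
      idx <- if (g == 1) idx_a else idx_b
      gen <- simulate_genealogy(length(idx), config$model,
                                keep_lineages = TRUE)
      carriers <- drop_mutations(gen, bal$theta_within)
      for (m in seq_along(carriers)) {
        used <- used + 1
        if (used > length(free_cols))
          stop_input("alignment too short for the realized mutation count")
        col <- free_cols[used]
        mat[idx[carriers[[m]]], col] <- sample(setdiff(bases, anc[col]), 1)
        site_rows[[length(site_rows) + 1]] <-
          data.frame(column = col,
                     kind = if (g == 1) "within_a" else "within_b")
      }
    }

    # recombination-like swaps of a contiguous diagnostic block
    swapped <- which(runif(n) < bal$swap_rate)
    for (s in swapped) {
      from <- sample.int(bal$d_fixed, 1)
      to <- sample(from:bal$d_fixed, 1)
      for (d in from:to) {
        col <- diag_cols[d]
        own_derived <- if (s <= n_a) derived_in_a[d] else !derived_in_a[d]
        mat[s, col] <- if (own_derived) anc[col] else derived_base[d]
      }
    }

    outg <- mutate_outgroup(anc, config$outgroup_divergence)
    outg[diag_cols] <- anc[diag_cols]  # outgroup ancestral at diagnostics
    full <- rbind(mat, outg)
    ids <- c(sprintf("A_%03d", seq_len(n_a)), sprintf("B_%03d", seq_len(n_b)),
             "outgroup_1")
    rownames(full) <- ids

    meta <- balanced_metadata(ids, n_a, n_b)
    aln <- new_labeled_alignment(meta, full)

    truth <- config
    truth$diagnostic_columns <- diag_cols
    truth$derived_in_a <- derived_in_a
    first <- diag_cols[1]
    map <- c("A-group", "B-group")
    names(map) <- if (derived_in_a[1]) c(derived_base[1], anc[first])
                  else c(anc[first], derived_base[1])
    truth$diagnostic_column <- first
    truth$allele_map <- map

    site_map <- rbind(
      data.frame(column = diag_cols, kind = "diagnostic"),
      if (length(site_rows)) do.call(rbind, site_rows))
    new_simulated_dataset(aln, truth,
                          site_map[order(site_map$column), , drop = FALSE])
  })
}

# locality / region labels for the balanced scenario: haplogroup A
# concentrated in a southern region, B in a northern one, with a small
# admixed fraction, mirroring a strong but imperfect geographic sorting
balanced_metadata <- function(ids, n_a, n_b) {
  north <- c("Can", "Gre", "Ice", "Nor", "Bar", "Whi")
  south <- c("Far", "Nse", "Bal", "Cel", "Iri")
  n_a_south <- round(n_a * 35 / 43)
  n_b_north <- n_b - max(1, round(n_b * 1 / 79))
  region <- c(rep(c("South", "North"), c(n_a_south, n_a - n_a_south)),
              rep(c("North", "South"), c(n_b_north, n_b - n_b_north)),
              "none")
  locality <- vapply(seq_along(region), function(i) {
    if (region[i] == "North") north[(i %% length(north)) + 1]
    else if (region[i] == "South") south[(i %% length(south)) + 1]
    else "Out"
  }, character(1))
  data.frame(id = ids, locality = locality, region = region,
             role = c(rep("ingroup", n_a + n_b), "outgroup"),
             taxon = c(rep("synthetic ingroup", n_a + n_b),
                       "synthetic outgroup"),
             stringsAsFactors = FALSE)
}

#' Default balanced-locus emulation scenario
#'
#' The documented default two-haplogroup scenario: 122 haploid sequences of
#' 2,500 aligned sites split into haplogroups of 43 and 79, 20 diagnostic
#' columns fixed-different between them, within-haplogroup genealogies under
#' a Beta(2-alpha, alpha) coalescent with `alpha = 1.1` (a strong singleton
#' excess), a per-sample diagnostic-block swap probability of 0.03, and an
#' outgroup at 2% expected divergence. The within-haplogroup mutation rate
#' is calibrated deterministically, via the exact expected total branch
#' length of the within-group genealogies, so that the expected total
#' number of segregating sites is about 87 (20 diagnostic + about 67
#' within-group).
#'
#' @param seed scenario seed (fixed default 1732).
#' @return a `scenario_config`.
#' @export
preset_ckma_like <- function(seed = 1732L) {
  model <- coal_model("beta", 1.1)
  target_within <- 87 - 20
  etl <- expected_total_length(43, model) + expected_total_length(79, model)
  theta_within <- 2 * target_within / etl
  scenario_config(
    n = 122, L = 2500, theta = 0, model = model, seed = seed,
    balanced = list(n_a = 43, n_b = 79, d_fixed = 20,
                    theta_within = theta_within, swap_rate = 0.03),
    outgroup_divergence = 0.02)
}
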