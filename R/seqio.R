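#' Read an aligned FASTA file with per-sample metadata
#'
#' Reads a multi-sequence alignment (one consensus allele sequence per
#' individual) together with a tab-separated metadata table and returns a
#' labelled alignment object. Sequences are upper-cased on read; any symbol
#' other than `A`, `C`, `G`, `T` or `-` is treated as missing (`N`).
#'
#' The metadata table must have header columns `id`, `locality`, `region`,
#' `role` and `taxon`; extra columns are preserved but ignored. Every FASTA
#' record id must appear exactly once in the metadata and vice versa.
#'
#' @param fasta_path path to an aligned FASTA file.
#' @param metadata_path path to a tab-separated metadata table.
#' @return an object of class `labeled_alignment`: a list with elements
#'   `samples` (the metadata data frame, in FASTA order), `matrix` (character
#'   matrix, samples x columns), `length` (aligned columns) and
#'   `effective_length` (columns free of gaps and `N` in every ingroup
#'   sequence).
#' @export
read_alignment <- function(fasta_path, metadata_path) {
  if (!file.exists(fasta_path)) stop_input("FASTA file not found: ", fasta_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0) stop_input("empty FASTA file: ", fasta_path)
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE,
                     colClasses = "character")
  needed <- c("id", "locality", "region", "role", "taxon")
  if (!all(needed %in% names(meta)))
    stop_input("metadata must have columns: ", paste(needed, collapse = ", "))
  ids <- names(seqs)
  if (anyDuplicated(ids)) stop_input("duplicated FASTA record ids")
  if (anyDuplicated(meta$id)) stop_input("duplicated metadata ids")
  missing_meta <- setdiff(ids, meta$id)
  if (length(missing_meta))
    stop_input("metadata error: no metadata for record(s) ",
               paste(missing_meta, collapse = ", "))
  missing_seq <- setdiff(meta$id, ids)
  if (length(missing_seq))
    stop_input("metadata error: no sequence for metadata id(s) ",
               paste(missing_seq, collapse = ", "))
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) > 1) {
    bad <- ids[widths != widths[1]][1]
    stop_input("alignment error: record ", bad,
               " has length ", widths[ids == bad][1],
               " but expected ", widths[1])
  }
  meta <- meta[match(ids, meta$id), , drop = FALSE]
  rownames(meta) <- NULL
  mat <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(mat) <- ids
  mat[!(mat %in% c("A", "C", "G", "T", "-"))] <- "N"
  new_labeled_alignment(meta, mat)
}

#' Construct a labelled alignment from sequences in memory
#'
#' Convenience constructor for programmatic fixtures and simulations: takes
#' a named character vector of equal-length sequences and optional
#' metadata. Without metadata, all samples are ingroup with a synthetic
#' locality code.
#'
#' @param sequences named character vector of aligned sequences.
#' @param metadata optional data frame with columns `id`, `locality`,
#'   `region`, `role`, `taxon` (one row per sequence, matched by `id`).
#' @return a `labeled_alignment`.
#' @export
labeled_alignment <- function(sequences, metadata = NULL) {
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq_%03d", seq_along(sequences))
  widths <- nchar(sequences)
  if (length(unique(widths)) > 1)
    stop_input("alignment error: sequences differ in length")
  if (is.null(metadata)) {
    metadata <- data.frame(id = names(sequences), locality = "Sy1",
                           region = "none", role = "ingroup",
                           taxon = "synthetic", stringsAsFactors = FALSE)
  } else {
    metadata <- metadata[match(names(sequences), metadata$id), , drop = FALSE]
    if (anyNA(metadata$id)) stop_input("metadata error: ids do not match")
    rownames(metadata) <- NULL
  }
  mat <- do.call(rbind, strsplit(toupper(unname(sequences)), ""))
  rownames(mat) <- names(sequences)
  mat[!(mat %in% c("A", "C", "G", "T", "-"))] <- "N"
  new_labeled_alignment(metadata, mat)
}

# construct + validate a labeled_alignment from metadata and character matrix
new_labeled_alignment <- function(samples, matrix) {
  stopifnot(nrow(samples) == nrow(matrix))
  if (!all(samples$role %in% c("ingroup", "outgroup")))
    stop_input("role must be 'ingroup' or 'outgroup'")
  aln <- structure(
    list(samples = samples, matrix = matrix, length = ncol(matrix),
         effective_length = NA_integer_),
    class = "labeled_alignment"
  )
  aln$effective_length <- length(effective_columns(aln))
  aln
}

#' @export
print.labeled_alignment <- function(x, ...) {
  n_in <- sum(x$samples$role == "ingroup")
  cat("labeled_alignment:", nrow(x$matrix), "sequences (", n_in, "ingroup ),",
      x$length, "columns,", x$effective_length, "effective\n")
  invisible(x)
}

# indices of columns with no gap/N in any retained ingroup sequence;
# `subset` (sample ids) restricts which ingroup sequences count as retained
effective_columns <- function(aln, subset = NULL) {
  m <- ingroup_matrix(aln, subset)
  which(colSums(m == "-" | m == "N") == 0L)
}

ingroup_matrix <- function(aln, subset = NULL) {
  keep <- aln$samples$role == "ingroup"
  if (!is.null(subset)) {
    unknown <- setdiff(subset, aln$samples$id)
    if (length(unknown))
      stop_input("unknown sample id(s): ", paste(unknown, collapse = ", "))
    keep <- keep & aln$samples$id %in% subset
  }
  aln$matrix[keep, , drop = FALSE]
}

#' Write an alignment back to FASTA and metadata files
#'
#' Inverse of [read_alignment()]: sequences and ids round-trip
#' byte-identically.
#'
#' @param aln a `labeled_alignment`.
#' @param fasta_path output FASTA path.
#' @param metadata_path optional output path for the metadata TSV.
#' @return `fasta_path`, invisibly.
#' @export
write_alignment <- function(aln, fasta_path, metadata_path = NULL) {
  seqs <- Biostrings::DNAStringSet(apply(aln$matrix, 1, paste, collapse = ""))
  names(seqs) <- aln$samples$id
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(metadata_path))
    write.table(aln$samples, metadata_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(fasta_path)
}

#' Classify samples into haplogroups by a diagnostic site
#'
#' Labels every ingroup sample by its base at a single diagnostic alignment
#' column via an allele-to-label map (e.g. a fixed C/T difference separating
#' two divergent allelic classes). Bases not covered by the map (including
#' gaps and `N`) are labelled `"unassigned"`.
#'
#' @param aln a `labeled_alignment`.
#' @param diagnostic_column 1-based alignment column index.
#' @param allele_map named character vector, names = bases, values = labels.
#' @return named character vector of labels, one per ingroup sample.
#' @export
classify_haplogroup <- function(aln, diagnostic_column, allele_map) {
  if (diagnostic_column < 1 || diagnostic_column > aln$length)
    stop_input("index error: diagnostic_column ", diagnostic_column,
               " outside [1, ", aln$length, "]")
  if (length(allele_map) < 2)
    stop_input("allele_map must cover at least 2 bases")
  keep <- aln$samples$role == "ingroup"
  base <- aln$matrix[keep, diagnostic_column]
  lab <- unname(allele_map[base])
  lab[is.na(lab)] <- "unassigned"
  setNames(lab, aln$samples$id[keep])
}

#' Tabulate segregating sites among ingroup samples
#'
#' One row per alignment column that is polymorphic among the retained
#' ingroup sequences. Columns carrying a gap or `N` in any retained ingroup
#' sequence are excluded entirely (the same complete-case rule used for the
#' segregating-site count `S`), so the row count equals `S` from
#' [summary_stats()] on the same alignment.
#'
#' @param aln a `labeled_alignment`.
#' @param subset optional character vector of ingroup sample ids to retain.
#' @return a data frame of class `site_table` with columns `site` (1-based
#'   column index), `major`, `minor` (most/second-most frequent allele),
#'   `major_count`, `minor_count`, `n_alleles`, and `pattern` (the per-sample
#'   alleles at the site concatenated in sample order).
#' @export
segregating_site_table <- function(aln, subset = NULL) {
  m <- ingroup_matrix(aln, subset)
  if (nrow(m) < 2) stop_input("need at least 2 ingroup samples")
  cols <- effective_columns(aln, subset)
  rows <- lapply(cols, function(j) {
    tab <- sort(table(m[, j]), decreasing = TRUE)
    if (length(tab) < 2) return(NULL)
    data.frame(site = j,
               major = names(tab)[1], minor = names(tab)[2],
               major_count = as.integer(tab[1]),
               minor_count = as.integer(tab[2]),
               n_alleles = length(tab),
               pattern = paste(m[, j], collapse = ""),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(site = integer(), major = character(),
                      minor = character(), major_count = integer(),
                      minor_count = integer(), n_alleles = integer(),
                      pattern = character(), stringsAsFactors = FALSE)
  class(out) <- c("site_table", "data.frame")
  out
}

#' Write a segregating-site table as TSV
#'
#' @param x a `site_table` from [segregating_site_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
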