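# Summary statistics on a given pairwise protein alignment: identities,
# positives (substitution score > 0) and gaps, each as a count over the
# alignment length and as an integer percentage. Producing the alignment
# (database search) is out of scope; the module consumes two gapped strings.

.load_matrix <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  env <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = env)
  get(matrix, envir = env)
}

#' Construct a validated pairwise alignment
#'
#' @param aligned_x,aligned_y equal-length gapped sequences over the
#'   20-letter alphabet plus `-`. A column gapped in both rows is invalid.
#' @param matrix substitution matrix name (a Biostrings data set, default
#'   `"BLOSUM62"`) or a residue-by-residue numeric matrix; used for the
#'   positives count.
#' @return an object of class `PairwiseAlignment`.
#' @export
pairwise_alignment <- function(aligned_x, aligned_y, matrix = "BLOSUM62") {
  for (s in list(aligned_x, aligned_y)) {
    if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s)) {
      pep_stop("aligned sequences must be non-empty strings",
               "pepsilico_validation_error")
    }
  }
  if (nchar(aligned_x) != nchar(aligned_y)) {
    pep_stop(sprintf("aligned length mismatch: %d vs %d",
                     nchar(aligned_x), nchar(aligned_y)),
             "pepsilico_validation_error")
  }
  allowed <- c(AA_ALPHABET, "-")
  for (s in list(x = aligned_x, y = aligned_y)) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% allowed)
    if (length(bad) > 0L) {
      pep_stop(sprintf("disallowed character '%s' at alignment column %d",
                       chars[bad[1L]], bad[1L]),
               "pepsilico_validation_error")
    }
  }
  cx <- strsplit(aligned_x, "", fixed = TRUE)[[1L]]
  cy <- strsplit(aligned_y, "", fixed = TRUE)[[1L]]
  if (any(cx == "-" & cy == "-")) {
    pep_stop("alignment has a column gapped in both rows",
             "pepsilico_validation_error")
  }
  structure(list(aligned_x = aligned_x, aligned_y = aligned_y,
                 matrix = matrix),
            class = "PairwiseAlignment")
}

#' Read a 2-record aligned FASTA into a pairwise alignment
#' @param path FASTA file with exactly two equal-length gapped records.
#' @param matrix passed to [pairwise_alignment()].
#' @return a `PairwiseAlignment`.
#' @export
read_aligned_fasta <- function(path, matrix = "BLOSUM62") {
  lines <- readLines(path, warn = FALSE)
  heads <- grep("^>", lines)
  if (length(heads) != 2L) {
    pep_stop(sprintf("aligned FASTA must contain exactly 2 records, found %d",
                     length(heads)), "pepsilico_validation_error")
  }
  take <- function(from, to) {
    paste(gsub("\\s", "", lines[seq(from, to)]), collapse = "")
  }
  x <- take(heads[1L] + 1L, heads[2L] - 1L)
  y <- if (heads[2L] == length(lines)) "" else
    take(heads[2L] + 1L, length(lines))
  pairwise_alignment(x, y, matrix = matrix)
}

#' Identities, positives and gaps of a pairwise alignment
#'
#' Per-column classification over the alignment length L: an identity is a
#' column with equal non-gap residues; a positive is a column whose
#' substitution score is > 0 (identities are positives under BLOSUM62,
#' where every diagonal entry is positive); a gap column contains `-` in
#' either row. Percentages are `round(100 * count / L)` half away from
#' zero, the display convention of alignment summary lines.
#'
#' @param alignment a `PairwiseAlignment`, or a gapped string (then `y` must
#'   be given).
#' @param y optional second gapped string.
#' @param matrix substitution matrix, see [pairwise_alignment()].
#' @return an object of class `AlignmentStats`: list with `L`, counts
#'   `identities`, `positives`, `gaps`, and integer percentages
#'   `pct_identity`, `pct_positive`, `pct_gaps`.
#' @examples
#' alignment_stats(pairwise_alignment("MKVL", "MKIL"))
#' @export
alignment_stats <- function(alignment, y = NULL, matrix = "BLOSUM62") {
  if (!inherits(alignment, "PairwiseAlignment")) {
    alignment <- pairwise_alignment(alignment, y, matrix = matrix)
  }
  mat <- .load_matrix(alignment$matrix)
  cx <- strsplit(alignment$aligned_x, "", fixed = TRUE)[[1L]]
  cy <- strsplit(alignment$aligned_y, "", fixed = TRUE)[[1L]]
  L <- length(cx)
  gap <- cx == "-" | cy == "-"
  ident <- !gap & cx == cy
  score <- rep(-Inf, L)
  ng <- which(!gap)
  score[ng] <- mat[cbind(cx[ng], cy[ng])]
  pos <- !gap & score > 0
  pct <- function(k) as.integer(round_half_away(100 * k / L, 0))
  structure(list(L = L,
                 identities = sum(ident), positives = sum(pos),
                 gaps = sum(gap),
                 pct_identity = pct(sum(ident)),
                 pct_positive = pct(sum(pos)),
                 pct_gaps = pct(sum(gap))),
            class = "AlignmentStats")
}

#' @export
print.AlignmentStats <- function(x, ...) {
  cat(sprintf("Identities: %d/%d (%d%%), Positives: %d/%d (%d%%), Gaps: %d/%d (%d%%)\n",
              x$identities, x$L, x$pct_identity,
              x$positives, x$L, x$pct_positive,
              x$gaps, x$L, x$pct_gaps))
  invisible(x)
}
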