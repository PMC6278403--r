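# Shared constants and small numeric helpers.

#: the 20 canonical one-letter amino-acid codes, alphabetical
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# ambiguity / non-standard codes tolerated only in permissive mode
AA_AMBIGUOUS <- c("B", "Z", "X", "U", "O")

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even (banker's rounding). Reports in this
#' package follow the convention common in the bioactive-peptide literature:
#' halves are rounded away from zero, so `0.4085` at 3 decimals becomes
#' `0.409`, not `0.408`.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_away(0.4085, 3)
#' round_half_away(100 * 429 / 614, 0)
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# internal: stop with a classed condition so callers/tests can be specific
pep_stop <- function(msg, class) {
  stop(structure(class = c(class, "pepsilico_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# internal: validate a raw amino-acid string; returns invisibly or errors.
# `permissive` lets ambiguity codes (B, Z, X, U, O) pass; they never match
# reference peptides or cleavage clauses downstream.
check_aa_sequence <- function(sequence, id = "<unnamed>", permissive = FALSE) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    pep_stop(sprintf("record '%s': sequence must be a non-empty string", id),
             "pepsilico_validation_error")
  }
  allowed <- if (permissive) c(AA_ALPHABET, AA_AMBIGUOUS) else AA_ALPHABET
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% allowed)
  if (length(bad) > 0L) {
    pep_stop(sprintf(
      "record '%s': disallowed character '%s' at position %d",
      id, chars[bad[1L]], bad[1L]), "pepsilico_validation_error")
  }
  invisible(TRUE)
}
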