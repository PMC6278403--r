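# Protein sequence records and FASTA input/output.
#
# Coordinate convention: all user-facing positions are 1-based inclusive
# (the convention of bioactive-peptide location reports); internal substring
# arithmetic uses base R's 1-based inclusive indexing throughout, so no
# conversion layer is needed.

#' Construct a validated protein record
#'
#' A `ProteinRecord` holds a named amino-acid sequence over the 20 canonical
#' one-letter codes, uppercase. The residue count `N` is the denominator of
#' the frequency-of-occurrence statistic A = a/N.
#'
#' @param id accession-like identifier (non-empty string).
#' @param sequence amino-acid sequence; lowercase letters are upcased with a
#'   warning.
#' @param description free-text description (default `""`).
#' @param permissive if `TRUE`, ambiguity codes (B, Z, X, U, O) are allowed
#'   in the sequence; they never match any reference peptide or cleavage
#'   rule. Default `FALSE`: the profiling and digestion semantics are
#'   undefined on ambiguous residues, so they are rejected.
#' @return an object of class `ProteinRecord` with fields `id`,
#'   `description`, `sequence` and `N` (residue count).
#' @examples
#' p <- protein_record("p1", "MKV", "demo")
#' p$N
#' @export
protein_record <- function(id, sequence, description = "",
                           permissive = FALSE) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    pep_stop("id must be a non-empty string", "pepsilico_validation_error")
  }
  if (is.character(sequence) && length(sequence) == 1L && !is.na(sequence) &&
      grepl("[a-z]", sequence)) {
    warning(sprintf("record '%s': lowercase residues upcased", id),
            call. = FALSE)
    sequence <- toupper(sequence)
  }
  check_aa_sequence(sequence, id = id, permissive = permissive)
  structure(list(id = id, description = description, sequence = sequence,
                 N = nchar(sequence)),
            class = "ProteinRecord")
}

#' @export
print.ProteinRecord <- function(x, ...) {
  cat(sprintf("<ProteinRecord> %s (%d aa)%s\n", x$id, x$N,
              if (nzchar(x$description)) paste0(" - ", x$description) else ""))
  seq <- x$sequence
  if (nchar(seq) > 60) seq <- paste0(substr(seq, 1, 57), "...")
  cat(" ", seq, "\n")
  invisible(x)
}

#' Read protein records from a FASTA file
#'
#' Plain multi-record FASTA, wrapped or unwrapped sequence lines. The header
#' is split at the first whitespace into `id` and `description`. Records are
#' validated (see [protein_record()]) and returned in file order.
#'
#' @param path path to a FASTA file, or a connection.
#' @param permissive passed to [protein_record()].
#' @return a list of `ProteinRecord` objects (possibly empty).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "MKV"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, permissive = FALSE) {
  lines <- readLines(path, warn = FALSE)
  records <- list()
  cur_id <- NULL
  cur_desc <- ""
  cur_seq <- character()
  flush <- function() {
    if (is.null(cur_id)) return(invisible(NULL))
    records[[length(records) + 1L]] <<- protein_record(
      cur_id, paste(cur_seq, collapse = ""), cur_desc,
      permissive = permissive)
  }
  for (i in seq_along(lines)) {
    line <- sub("[\r\n]+$", "", lines[[i]])
    if (!nzchar(trimws(line))) next
    if (startsWith(line, ">")) {
      flush()
      header <- sub("^>", "", line)
      if (!nzchar(trimws(header))) {
        pep_stop(sprintf("malformed FASTA header at line %d: empty id", i),
                 "pepsilico_parse_error")
      }
      sp <- regexpr("\\s", header)
      if (sp > 0) {
        cur_id <- substr(header, 1L, sp - 1L)
        cur_desc <- trimws(substr(header, sp + 1L, nchar(header)))
      } else {
        cur_id <- header
        cur_desc <- ""
      }
      cur_seq <- character()
    } else {
      if (is.null(cur_id)) {
        pep_stop(sprintf(
          "malformed FASTA: sequence data before any header at line %d", i),
          "pepsilico_parse_error")
      }
      cur_seq <- c(cur_seq, gsub("\\s", "", line))
    }
  }
  flush()
  records
}

#' Write protein records to a FASTA file
#'
#' Round-trip stable: `read_fasta()` on the output reproduces ids and
#' sequences exactly.
#'
#' @param records a list of `ProteinRecord` objects (or a single record).
#' @param path destination path or connection.
#' @param line_width sequence-line wrap width (default 60).
#' @return invisibly, the path.
#' @export
write_fasta <- function(records, path, line_width = 60) {
  if (inherits(records, "ProteinRecord")) records <- list(records)
  stopifnot(line_width >= 1)
  out <- character()
  for (rec in records) {
    stopifnot(inherits(rec, "ProteinRecord"))
    header <- if (nzchar(rec$description)) {
      paste0(">", rec$id, " ", rec$description)
    } else {
      paste0(">", rec$id)
    }
    starts <- seq(1L, rec$N, by = line_width)
    chunks <- substring(rec$sequence, starts,
                        pmin(starts + line_width - 1L, rec$N))
    out <- c(out, header, chunks)
  }
  writeLines(out, path)
  invisible(path)
}
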