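# Reference sets of bioactive peptides: the local stand-in for a public
# bioactive-peptide database snapshot. Matching downstream is exact lookup;
# no activity prediction is attempted.

# canonical activity spellings; keys are lowercased, punctuation-squashed
.activity_aliases <- c(
  "dpp-iv inhibitor"                        = "DPP-IV inhibitor",
  "dpp iv inhibitor"                        = "DPP-IV inhibitor",
  "dppiv inhibitor"                         = "DPP-IV inhibitor",
  "dipeptidyl peptidase-iv inhibitor"       = "DPP-IV inhibitor",
  "dipeptidyl peptidase iv inhibitor"       = "DPP-IV inhibitor",
  "ace inhibitor"                           = "ACE inhibitor",
  "ace-i inhibitor"                         = "ACE inhibitor",
  "ace i inhibitor"                         = "ACE inhibitor",
  "angiotensin-i converting enzyme inhibitor" = "ACE inhibitor",
  "angiotensin i converting enzyme inhibitor" = "ACE inhibitor",
  "antioxidant"                             = "antioxidative",
  "antioxidative"                           = "antioxidative",
  "antihypertensive"                        = "antihypertensive",
  "hypotensive"                             = "hypotensive"
)

#' Normalize an activity label
#'
#' Labels are matched case-insensitively against an alias map so that the
#' spellings "DPP IV inhibitor", "dpp-iv inhibitor" and "DPP-IV inhibitor"
#' all collapse to one canonical form. Unknown labels are kept verbatim
#' (trimmed), so user vocabularies pass through unchanged.
#'
#' @param activity character vector of labels.
#' @return character vector of canonical labels.
#' @export
normalize_activity <- function(activity) {
  act <- trimws(activity)
  key <- tolower(act)
  hit <- .activity_aliases[key]
  unname(ifelse(is.na(hit), act, hit))
}

#' Construct a reference set of bioactive peptides
#'
#' @param entries a data.frame with columns `sequence`, `activity`, `ref_id`,
#'   `source`. Sequences are validated like protein sequences; activities are
#'   normalized via [normalize_activity()]; duplicate (sequence, activity)
#'   rows are collapsed with a warning.
#' @param version_tag free text recording provenance/date of the table; the
#'   source database is revised continuously, so counts are only meaningful
#'   relative to an explicit snapshot.
#' @return an object of class `ReferenceSet`.
#' @export
reference_set <- function(entries, version_tag = "unversioned") {
  required <- c("sequence", "activity", "ref_id", "source")
  missing <- setdiff(required, names(entries))
  if (length(missing) > 0L) {
    pep_stop(paste0("reference table is missing column(s): ",
                    paste(missing, collapse = ", ")),
             "pepsilico_schema_error")
  }
  entries <- as.data.frame(entries)[required]
  for (col in required) entries[[col]] <- as.character(entries[[col]])
  for (i in seq_len(nrow(entries))) {
    ok <- tryCatch({
      check_aa_sequence(entries$sequence[i], id = sprintf("row %d", i))
      TRUE
    }, pepsilico_validation_error = function(e) e)
    if (!isTRUE(ok)) {
      pep_stop(sprintf("invalid peptide sequence in row %d: %s",
                       i, conditionMessage(ok)),
               "pepsilico_validation_error")
    }
    if (!nzchar(trimws(entries$activity[i]))) {
      pep_stop(sprintf("empty activity label in row %d", i),
               "pepsilico_validation_error")
    }
  }
  entries$activity <- normalize_activity(entries$activity)
  key <- paste(entries$sequence, entries$activity, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("collapsed %d duplicate (sequence, activity) row(s)",
                    sum(duplicated(key))), call. = FALSE)
    entries <- entries[!duplicated(key), , drop = FALSE]
  }
  rownames(entries) <- NULL
  structure(list(entries = entries, version_tag = version_tag),
            class = "ReferenceSet")
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat(sprintf("<ReferenceSet> %d peptides, %d activities [%s]\n",
              nrow(x$entries), length(unique(x$entries$activity)),
              x$version_tag))
  tab <- sort(table(x$entries$activity), decreasing = TRUE)
  for (a in names(tab)) cat(sprintf("  %-24s %d\n", a, tab[[a]]))
  invisible(x)
}

#' Activities present in a reference set
#' @param refset a `ReferenceSet`.
#' @return sorted character vector of canonical activity labels.
#' @export
activities <- function(refset) {
  stopifnot(inherits(refset, "ReferenceSet"))
  sort(unique(refset$entries$activity))
}

#' Load a reference table of bioactive peptides
#'
#' Reads a delimited text file with header columns `sequence`, `activity`,
#' `ref_id`, `source` into a validated [reference_set()].
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @param version_tag provenance tag; defaults to the file name.
#' @return a `ReferenceSet`.
#' @export
load_reference_table <- function(path, format = c("tsv", "csv"),
                                 version_tag = basename(path)) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          colClasses = "character", quote = "\"",
                          comment.char = "#")
  reference_set(df, version_tag = version_tag)
}

#' Save a reference table
#'
#' Inverse of [load_reference_table()]; the version tag is stored in a
#' comment line and restored on load via [load_reference_table()] when
#' present.
#'
#' @param refset a `ReferenceSet`.
#' @param path destination path.
#' @param format `"tsv"` or `"csv"`.
#' @return invisibly, the path.
#' @export
save_reference_table <- function(refset, path, format = c("tsv", "csv")) {
  stopifnot(inherits(refset, "ReferenceSet"))
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# version_tag: %s", refset$version_tag), con)
  utils::write.table(refset$entries, con, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Built-in curated fixture set of bioactive peptides
#'
#' A small, documented set of literature dipeptides and tripeptides across
#' DPP-IV-inhibitory, ACE-inhibitory, antioxidative, antihypertensive and
#' other activities, shipped with the package so that every analysis stage
#' runs without a download. It includes KF with multiple activity labels and
#' many Xaa-Pro dipeptides (proline in the second N-terminal position is the
#' classic DPP-IV-inhibitory motif). This is a curated fixture, not a
#' snapshot of any public database: absolute counts computed against it are
#' not comparable to counts against such a database.
#'
#' @return a `ReferenceSet`.
#' @examples
#' fx <- builtin_fixture_set()
#' activities(fx)
#' @export
builtin_fixture_set <- function() {
  path <- system.file("extdata", "bioactive_peptides_fixture.tsv",
                      package = "pepsilico", mustWork = TRUE)
  load_reference_table(path, format = "tsv",
                       version_tag = "pepsilico-fixture-v1 (curated, 2026)")
}
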