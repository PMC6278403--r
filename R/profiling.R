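# Profiling a protein for known bioactive fragments.
#
# Counting semantics: `a` counts occurrence *positions*, with multiplicity
# and overlap — "AA" occurs 3 times in "AAAA" — and a peptide carrying k
# activity labels contributes one occurrence to each of the k activities per
# position. The statistic A = a/N is the per-activity occurrence count over
# the protein's residue count.

#' Frequency of occurrence of bioactive fragments
#'
#' Computes A = a/N, where `a` is the number of bioactive-fragment
#' occurrences of one activity found in the protein and `N` is the protein's
#' residue count. The value is returned at full precision; reports round it
#' half away from zero to 3 decimals (see [format_A()]).
#'
#' @param a non-negative occurrence count.
#' @param N residue count, at least 1.
#' @return the dimensionless ratio a/N.
#' @examples
#' frequency_of_occurrence(251, 615)  # 0.408 at 3 decimals
#' frequency_of_occurrence(162, 275)  # 0.589 at 3 decimals
#' @export
frequency_of_occurrence <- function(a, N) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1) {
    pep_stop("N must be a residue count >= 1", "pepsilico_domain_error")
  }
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0) {
    pep_stop("a must be a non-negative count", "pepsilico_domain_error")
  }
  a / N
}

#' Format an A value for reports
#' @param A numeric frequency-of-occurrence value(s).
#' @return character, 3 decimals, rounded half away from zero.
#' @export
format_A <- function(A) {
  sprintf("%.3f", round_half_away(A, 3))
}

#' Find all occurrences of reference peptides in a protein
#'
#' Scans the protein for every peptide in the reference set and reports each
#' occurrence position (1-based inclusive start/end). Overlapping
#' occurrences and repeated occurrences of the same peptide all count.
#' Peptides longer than the protein contribute zero occurrences. Activities
#' present in the reference set but absent from the protein are reported
#' with count 0.
#'
#' @param protein a `ProteinRecord`.
#' @param refset a non-empty `ReferenceSet`.
#' @return an object of class `ActivityProfile`: list with `protein_id`,
#'   `N`, and `activities`, a named list whose elements hold `occurrences`
#'   (data.frame sequence/start/end/ref_id), count `a`, and statistic `A`.
#' @examples
#' p <- protein_record("demo", "GPGPG")
#' rs <- reference_set(data.frame(sequence = "GP", activity = "ACE inhibitor",
#'                                ref_id = "x1", source = "demo"))
#' find_occurrences(p, rs)
#' @export
find_occurrences <- function(protein, refset) {
  stopifnot(inherits(protein, "ProteinRecord"))
  if (!inherits(refset, "ReferenceSet") || nrow(refset$entries) == 0L) {
    pep_stop("refset must be a non-empty ReferenceSet",
             "pepsilico_usage_error")
  }
  seq <- protein$sequence
  N <- protein$N
  entries <- refset$entries

  # one substring table per distinct peptide length, shared by all peptides
  # of that length
  pep_len <- nchar(entries$sequence)
  hits <- vector("list", nrow(entries))
  for (L in unique(pep_len)) {
    if (L > N) next
    starts <- seq_len(N - L + 1L)
    subs <- substring(seq, starts, starts + L - 1L)
    for (i in which(pep_len == L)) {
      at <- starts[subs == entries$sequence[i]]
      if (length(at) > 0L) {
        hits[[i]] <- data.frame(sequence = entries$sequence[i],
                                start = at, end = at + L - 1L,
                                ref_id = entries$ref_id[i],
                                stringsAsFactors = FALSE)
      }
    }
  }

  acts <- activities(refset)
  profile <- stats::setNames(vector("list", length(acts)), acts)
  for (act in acts) {
    idx <- which(entries$activity == act)
    occ <- do.call(rbind, hits[idx])
    if (is.null(occ)) {
      occ <- data.frame(sequence = character(), start = integer(),
                        end = integer(), ref_id = character(),
                        stringsAsFactors = FALSE)
    } else {
      occ <- occ[order(occ$start, occ$end, occ$sequence), , drop = FALSE]
      rownames(occ) <- NULL
    }
    a <- nrow(occ)
    profile[[act]] <- list(occurrences = occ, a = a,
                           A = frequency_of_occurrence(a, N))
  }
  structure(list(protein_id = protein$id, N = N, activities = profile),
            class = "ActivityProfile")
}

#' @export
print.ActivityProfile <- function(x, ...) {
  cat(sprintf("<ActivityProfile> %s (N = %d)\n", x$protein_id, x$N))
  for (act in names(x$activities)) {
    e <- x$activities[[act]]
    cat(sprintf("  %-24s a = %3d  A = %s\n", act, e$a, format_A(e$A)))
  }
  invisible(x)
}

#' Tabulate activity profiles across proteins
#'
#' One row per protein, in input order; one column per requested activity
#' showing "a (A)" with A at 3 decimals, plus an aggregated count of all
#' remaining ("other") activities.
#'
#' @param profiles a list of `ActivityProfile` objects (or a single one).
#' @param top_activities character vector of activity labels to break out as
#'   columns; defaults to all activities seen, ordered by total count
#'   (decreasing, ties alphabetical). Unknown labels are an error.
#' @return a data.frame with columns `protein`, `N`, one per activity, and
#'   `other_activities`.
#' @export
profile_report <- function(profiles, top_activities = NULL) {
  if (inherits(profiles, "ActivityProfile")) profiles <- list(profiles)
  if (length(profiles) == 0L) {
    pep_stop("at least one profile is required", "pepsilico_usage_error")
  }
  known <- sort(unique(unlist(lapply(profiles,
                                     function(p) names(p$activities)))))
  if (is.null(top_activities)) {
    totals <- sapply(known, function(act) {
      sum(sapply(profiles, function(p) {
        if (act %in% names(p$activities)) p$activities[[act]]$a else 0L
      }))
    })
    top_activities <- known[order(-totals, known)]
  } else {
    top_activities <- normalize_activity(top_activities)
    unknown <- setdiff(top_activities, known)
    if (length(unknown) > 0L) {
      pep_stop(sprintf("unknown activity label(s): %s; known labels: %s",
                       paste(unknown, collapse = ", "),
                       paste(known, collapse = ", ")),
               "pepsilico_usage_error")
    }
  }
  rows <- lapply(profiles, function(p) {
    cells <- lapply(top_activities, function(act) {
      e <- p$activities[[act]]
      a <- if (is.null(e)) 0L else e$a
      sprintf("%d (%s)", a, format_A(frequency_of_occurrence(a, p$N)))
    })
    other <- setdiff(names(p$activities), top_activities)
    other_a <- sum(vapply(p$activities[other], function(e) e$a, integer(1)))
    out <- c(list(protein = p$protein_id, N = p$N), cells,
             list(other_activities = other_a))
    names(out) <- c("protein", "N", top_activities, "other_activities")
    as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
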