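# Rule-based in silico proteolysis.
#
# A cleavage rule is a set of declarative site clauses over the
# P2-P1-P1'-P2' window around a peptide bond (the bond between P1 and P1'),
# plus exception clauses of the same shape that veto a proposed cut.
# Combined digestion by up to three proteases is simultaneous: the union of
# the individual cut-site sets.

.parse_residue_set <- function(txt, where) {
  txt <- trimws(txt)
  if (txt == "." || txt == "") return(NULL)
  set <- strsplit(txt, "", fixed = TRUE)[[1L]]
  bad <- setdiff(set, AA_ALPHABET)
  if (length(bad) > 0L) {
    pep_stop(sprintf("%s: residue set '%s' contains non-standard code(s) %s",
                     where, txt, paste(bad, collapse = ", ")),
             "pepsilico_validation_error")
  }
  unique(set)
}

#' Construct a protease with a declarative cleavage rule
#'
#' @param name unique protease name.
#' @param ec EC number string, or `"-"` when unassigned.
#' @param clauses list of site clauses; each clause is a list with optional
#'   elements `p2`, `p1`, `p1p`, `p2p`, each a character vector of allowed
#'   residues (absent = unconstrained).
#' @param exceptions list of exception clauses, same shape; an exception
#'   vetoes any proposed cut whose window it matches.
#' @return an object of class `Protease`.
#' @export
protease <- function(name, ec = "-", clauses, exceptions = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(clauses) == 0L) {
    pep_stop(sprintf("protease '%s': at least one site clause is required",
                     name), "pepsilico_validation_error")
  }
  norm <- function(cl, what) {
    lapply(cl, function(x) {
      x <- x[c("p2", "p1", "p1p", "p2p")]
      names(x) <- c("p2", "p1", "p1p", "p2p")
      lapply(x, function(set) {
        if (is.null(set)) NULL else {
          set <- as.character(set)
          if (length(set) == 1L && nchar(set) > 1L) {
            set <- strsplit(set, "", fixed = TRUE)[[1L]]
          }
          bad <- setdiff(set, AA_ALPHABET)
          if (length(bad) > 0L) {
            pep_stop(sprintf("protease '%s': invalid residue(s) %s in %s",
                             name, paste(bad, collapse = ","), what),
                     "pepsilico_validation_error")
          }
          unique(set)
        }
      })
    })
  }
  structure(list(name = name, ec = ec,
                 clauses = norm(clauses, "site clause"),
                 exceptions = norm(exceptions, "exception clause")),
            class = "Protease")
}

#' @export
print.Protease <- function(x, ...) {
  fmt <- function(cl) paste(vapply(c("p2", "p1", "p1p", "p2p"), function(p) {
    s <- cl[[p]]
    if (is.null(s)) "." else paste(s, collapse = "")
  }, character(1)), collapse = "-")
  cat(sprintf("<Protease> %s (EC %s)\n", x$name, x$ec))
  for (cl in x$clauses) cat("  site:      ", fmt(cl), "\n")
  for (cl in x$exceptions) cat("  exception: ", fmt(cl), "\n")
  invisible(x)
}

#' Load a cleavage rulebook
#'
#' Reads the TSV rule grammar (columns `enzyme`, `ec`, `kind`, `p2`, `p1`,
#' `p1p`, `p2p`; `kind` is `site` or `exception`; `"."` means
#' unconstrained) into a named list of [protease()] objects. With no
#' arguments, loads the bundled rulebook covering pepsin (pH > 2), trypsin,
#' chymotrypsin A and C, papain, bromelain, ficin, thermolysin, proteinase K
#' and pancreatic elastase.
#'
#' @param path rulebook file; default the bundled one.
#' @return named list of `Protease` objects, class `Rulebook`.
#' @export
load_rulebook <- function(path = system.file("extdata", "cleavage_rules.tsv",
                                             package = "pepsilico",
                                             mustWork = TRUE)) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", comment.char = "#")
  required <- c("enzyme", "ec", "kind", "p2", "p1", "p1p", "p2p")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    pep_stop(paste0("rulebook is missing column(s): ",
                    paste(missing, collapse = ", ")),
             "pepsilico_schema_error")
  }
  out <- list()
  for (nm in unique(df$enzyme)) {
    rows <- df[df$enzyme == nm, , drop = FALSE]
    mk <- function(kind) {
      sub <- rows[rows$kind == kind, , drop = FALSE]
      lapply(seq_len(nrow(sub)), function(i) {
        list(p2 = .parse_residue_set(sub$p2[i], nm),
             p1 = .parse_residue_set(sub$p1[i], nm),
             p1p = .parse_residue_set(sub$p1p[i], nm),
             p2p = .parse_residue_set(sub$p2p[i], nm))
      })
    }
    out[[nm]] <- protease(nm, ec = rows$ec[1L], clauses = mk("site"),
                          exceptions = mk("exception"))
  }
  structure(out, class = c("Rulebook", "list"))
}

# internal: logical vector over bonds 1..N-1, TRUE where `clause` matches.
# chars: character vector of the sequence. Positions beyond the termini
# satisfy unconstrained clause positions and fail constrained ones;
# ambiguity codes never belong to a residue set, so they fail constrained
# positions too.
.clause_matches <- function(chars, clause) {
  n_bonds <- length(chars) - 1L
  if (n_bonds < 1L) return(logical(0))
  ok <- rep(TRUE, n_bonds)
  window <- list(p2 = c(NA_character_, chars[seq_len(n_bonds - 1L)]),
                 p1 = chars[seq_len(n_bonds)],
                 p1p = chars[1L + seq_len(n_bonds)],
                 p2p = c(chars[2L + seq_len(max(0L, n_bonds - 1L))],
                         NA_character_))
  for (pos in c("p2", "p1", "p1p", "p2p")) {
    set <- clause[[pos]]
    if (is.null(set)) next
    res <- window[[pos]]
    ok <- ok & !is.na(res) & res %in% set
  }
  ok
}

#' Predict cleavage sites of one protease on a protein
#'
#' A bond index `i` (1-based, the bond between residues `i` and `i+1`) is
#' returned iff at least one site clause matches its P2..P2' window and no
#' exception clause vetoes it. There is no bond before position 1 or after
#' position N.
#'
#' @param protein a `ProteinRecord`.
#' @param protease a `Protease`.
#' @return increasing integer vector of cut bond indices (possibly empty).
#' @examples
#' rb <- load_rulebook()
#' cut_sites(protein_record("x", "AKRPSTK"), rb$trypsin)  # 2
#' @export
cut_sites <- function(protein, protease) {
  stopifnot(inherits(protein, "ProteinRecord"),
            inherits(protease, "Protease"))
  chars <- strsplit(protein$sequence, "", fixed = TRUE)[[1L]]
  if (length(chars) < 2L) return(integer(0))
  site <- Reduce(`|`, lapply(protease$clauses, .clause_matches,
                             chars = chars))
  if (length(protease$exceptions) > 0L) {
    veto <- Reduce(`|`, lapply(protease$exceptions, .clause_matches,
                               chars = chars))
    site <- site & !veto
  }
  which(site)
}

#' Simulate enzymatic hydrolysis by 1-3 proteases
#'
#' Combined digestion is simultaneous co-digestion: fragments are the
#' maximal segments uncut by the union of all proteases' cut sites. With
#' `missed_cleavages = m > 0`, every concatenation of up to `m + 1`
#' consecutive segments is additionally emitted as a non-covering fragment
#' flagged `partial` (the convention of tryptic MS workflows); the covering
#' digest itself is unaffected.
#'
#' @param protein a `ProteinRecord`.
#' @param proteases a single `Protease` or list of 1-3 of them.
#' @param missed_cleavages non-negative integer, default 0.
#' @return an object of class `DigestResult` with the protease names, the
#'   union cut-site vector, and a fragment table (`start`, `end`,
#'   `sequence`, `missed`, `partial`), covering fragments first in
#'   N-to-C order.
#' @export
digest <- function(protein, proteases, missed_cleavages = 0) {
  stopifnot(inherits(protein, "ProteinRecord"))
  if (inherits(proteases, "Protease")) proteases <- list(proteases)
  if (length(proteases) < 1L || length(proteases) > 3L) {
    pep_stop("between 1 and 3 proteases are required (the simulation's stated maximum is three enzymes)",
             "pepsilico_usage_error")
  }
  stopifnot(all(vapply(proteases, inherits, logical(1), "Protease")),
            missed_cleavages >= 0)
  sites <- sort(unique(unlist(lapply(proteases, cut_sites,
                                     protein = protein))))
  bounds <- c(0L, sites, protein$N)
  n_seg <- length(bounds) - 1L
  seg_start <- bounds[seq_len(n_seg)] + 1L
  seg_end <- bounds[1L + seq_len(n_seg)]
  frags <- data.frame(start = seg_start, end = seg_end,
                      missed = 0L, partial = FALSE)
  m <- as.integer(missed_cleavages)
  if (m > 0L && n_seg > 1L) {
    for (j in seq(2L, min(m + 1L, n_seg))) {
      first <- seq_len(n_seg - j + 1L)
      frags <- rbind(frags, data.frame(start = seg_start[first],
                                       end = seg_end[first + j - 1L],
                                       missed = j - 1L, partial = TRUE))
    }
  }
  frags$sequence <- substring(protein$sequence, frags$start, frags$end)
  frags <- frags[c("start", "end", "sequence", "missed", "partial")]
  rownames(frags) <- NULL
  structure(list(protein_id = protein$id, N = protein$N,
                 proteases = vapply(proteases, `[[`, character(1), "name"),
                 missed_cleavages = m, sites = sites, fragments = frags,
                 matches = NULL),
            class = "DigestResult")
}

#' @export
print.DigestResult <- function(x, ...) {
  cat(sprintf("<DigestResult> %s by %s: %d site(s), %d fragment(s)\n",
              x$protein_id, paste(x$proteases, collapse = " + "),
              length(x$sites), sum(!x$fragments$partial)))
  if (!is.null(x$matches)) {
    for (act in names(x$matches)) {
      cat(sprintf("  released %-24s %d\n", act, x$matches[[act]]$count))
    }
  }
  invisible(x)
}

#' Match released fragments against a reference set
#'
#' A fragment matches a reference peptide iff its full sequence is
#' identical to the peptide sequence (whole-fragment exact match, not
#' substring: the simulation reports peptides as released, and substring
#' matching would duplicate the profiling semantics). A fragment equal to a
#' peptide carrying k activity labels counts once per activity.
#'
#' @param result a `DigestResult`.
#' @param refset a non-empty `ReferenceSet`.
#' @return the `DigestResult` with `matches` populated: per activity, a
#'   data.frame of (start, end, sequence, ref_id, missed) and a `count`.
#' @export
search_active_fragments <- function(result, refset) {
  stopifnot(inherits(result, "DigestResult"))
  if (!inherits(refset, "ReferenceSet") || nrow(refset$entries) == 0L) {
    pep_stop("refset must be a non-empty ReferenceSet",
             "pepsilico_usage_error")
  }
  entries <- refset$entries
  frags <- result$fragments
  acts <- activities(refset)
  matches <- stats::setNames(vector("list", length(acts)), acts)
  for (act in acts) {
    sub <- entries[entries$activity == act, , drop = FALSE]
    idx <- match(frags$sequence, sub$sequence)
    hit <- which(!is.na(idx))
    pairs <- data.frame(start = frags$start[hit], end = frags$end[hit],
                        sequence = frags$sequence[hit],
                        ref_id = sub$ref_id[idx[hit]],
                        missed = frags$missed[hit],
                        stringsAsFactors = FALSE)
    rownames(pairs) <- NULL
    matches[[act]] <- list(pairs = pairs, count = nrow(pairs))
  }
  result$matches <- matches
  result$refset_tag <- refset$version_tag
  result
}

#' Rank proteases by released bioactive peptides
#'
#' Digests the protein with every protease in the rulebook (and any
#' requested combinations of up to three), matches released fragments
#' against the reference set, and ranks by the released count for one
#' activity (descending, ties broken by protease name). Proteases releasing
#' nothing are kept as zero rows; report renderers display such cells as
#' "ND" (not detected).
#'
#' @param protein a `ProteinRecord`.
#' @param rulebook named list of `Protease` objects ([load_rulebook()]).
#' @param refset a non-empty `ReferenceSet`.
#' @param activity the activity to sort by (normalized; must exist in the
#'   refset).
#' @param combinations optional list of character vectors of 2-3 rulebook
#'   names, e.g. `list(c("trypsin", "chymotrypsin_A"))`.
#' @param missed_cleavages passed to [digest()].
#' @return data.frame with one row per protease/combination and one count
#'   column per activity, sorted by the requested activity.
#' @export
rank_proteases <- function(protein, rulebook, refset, activity,
                           combinations = list(), missed_cleavages = 0) {
  if (length(rulebook) == 0L) {
    pep_stop("rulebook must be non-empty", "pepsilico_usage_error")
  }
  if (!inherits(refset, "ReferenceSet") || nrow(refset$entries) == 0L) {
    pep_stop("refset must be a non-empty ReferenceSet",
             "pepsilico_usage_error")
  }
  activity <- normalize_activity(activity)
  acts <- activities(refset)
  if (!activity %in% acts) {
    pep_stop(sprintf("unknown activity '%s'; known labels: %s",
                     activity, paste(acts, collapse = ", ")),
             "pepsilico_usage_error")
  }
  jobs <- c(as.list(names(rulebook)), combinations)
  rows <- lapply(jobs, function(nms) {
    unknown <- setdiff(nms, names(rulebook))
    if (length(unknown) > 0L) {
      pep_stop(sprintf("unknown protease(s): %s",
                       paste(unknown, collapse = ", ")),
               "pepsilico_usage_error")
    }
    res <- search_active_fragments(
      digest(protein, rulebook[nms], missed_cleavages = missed_cleavages),
      refset)
    counts <- vapply(res$matches, `[[`, numeric(1), "count")
    cbind(data.frame(protease = paste(nms, collapse = " + "),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(counts), check.names = FALSE))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab[[activity]], tab$protease), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
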