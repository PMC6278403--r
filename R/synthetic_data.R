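# Seeded synthetic inputs with known ground truth: random proteins, planted
# bioactive motifs, planted cleavage sites. One integer seed drives a named
# pseudo-random stream per generator, so adding a generator never perturbs
# the draws of another, and the global RNG state of the session is left
# untouched.

.stream_ids <- c(protein = 1L, motifs = 2L, cleavage = 3L)

# run `expr` under a seed derived from (seed, stream), restoring the
# caller's RNG state afterwards
.with_stream <- function(seed, stream, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  id <- .stream_ids[[stream]]
  derived <- as.integer((abs(as.numeric(seed)) * 7919 + id * 104729) %%
                          2147483647)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derived)
  force(expr)
}

#' Vertebrate-like amino-acid composition preset
#'
#' Approximate background residue frequencies of vertebrate proteins
#' (Swiss-Prot-style averages), normalized to sum to 1. Useful when the
#' dependence of the frequency-of-occurrence statistic on residue
#' composition matters: real proteins are not uniform over the alphabet.
#'
#' @return named numeric vector over the 20 residues summing to 1.
#' @export
vertebrate_composition <- function() {
  f <- c(A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025,
         Q = 0.034, E = 0.054, G = 0.074, H = 0.026, I = 0.068,
         L = 0.099, K = 0.058, M = 0.025, F = 0.047, P = 0.039,
         S = 0.057, T = 0.051, W = 0.013, Y = 0.032, V = 0.073)
  f / sum(f)
}

.check_composition <- function(composition) {
  if (identical(composition, "uniform")) {
    return(stats::setNames(rep(1 / 20, 20), AA_ALPHABET))
  }
  if (!is.numeric(composition) || is.null(names(composition)) ||
      !setequal(names(composition), AA_ALPHABET)) {
    pep_stop("composition must be \"uniform\" or a named frequency vector over the 20 residues",
             "pepsilico_domain_error")
  }
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9) {
    pep_stop("composition frequencies must be non-negative and sum to 1 (within 1e-9)",
             "pepsilico_domain_error")
  }
  composition[AA_ALPHABET]
}

#' Generate a random protein record
#'
#' Residues are drawn i.i.d. from the given composition; deterministic for
#' a fixed seed.
#'
#' @param length residue count, at least 1.
#' @param composition `"uniform"` (default) or a named frequency vector
#'   over the 20 residues (non-negative, summing to 1 within 1e-9), e.g.
#'   [vertebrate_composition()].
#' @param seed integer seed.
#' @param id record id; default derived from the seed.
#' @return a `ProteinRecord`.
#' @examples
#' generate_protein(30, seed = 1)
#' @export
generate_protein <- function(length, composition = "uniform", seed,
                             id = sprintf("synth_protein_s%d", seed)) {
  if (!is.numeric(length) || length < 1) {
    pep_stop("length must be >= 1", "pepsilico_domain_error")
  }
  comp <- .check_composition(composition)
  seq <- .with_stream(seed, "protein", {
    paste(sample(AA_ALPHABET, size = length, replace = TRUE, prob = comp),
          collapse = "")
  })
  protein_record(id, seq)
}

# internal: all (start, end) occurrences of `motif` in `seq`, overlapping
.scan_motif <- function(seq, motif) {
  L <- nchar(motif)
  N <- nchar(seq)
  if (L > N) return(integer(0))
  starts <- seq_len(N - L + 1L)
  starts[substring(seq, starts, starts + L - 1L) == motif]
}

#' Plant bioactive motifs into a protein at known positions
#'
#' Overwrites residues of the protein with copies of each motif at
#' positions chosen at random (non-overlapping by default) and returns the
#' exact ground truth. With `motif_free_background = TRUE`, accidental
#' occurrences of any motif in the background are scrubbed by resampling
#' the offending background residues (bounded retries), so that the planted
#' copies are provably the only occurrences.
#'
#' @param protein a `ProteinRecord` to plant into.
#' @param motifs a `ReferenceSet`, or a data.frame with columns `sequence`
#'   and `activity`. Each distinct motif sequence is planted
#'   `copies_per_motif` times; its truth rows carry every activity label it
#'   holds.
#' @param copies_per_motif non-negative integer.
#' @param seed integer seed.
#' @param non_overlapping keep planted copies disjoint (default `TRUE`).
#' @param motif_free_background scrub accidental background occurrences
#'   (default `FALSE`).
#' @param max_retries bound on placement and scrubbing attempts.
#' @return an object of class `SyntheticTruth`: list with `protein` (the
#'   modified record), `planted` (data.frame sequence/start/end/activity),
#'   `seed` and `params`.
#' @export
plant_motifs <- function(protein, motifs, copies_per_motif, seed,
                         non_overlapping = TRUE,
                         motif_free_background = FALSE,
                         max_retries = 200) {
  stopifnot(inherits(protein, "ProteinRecord"))
  tab <- if (inherits(motifs, "ReferenceSet")) motifs$entries else
    as.data.frame(motifs)
  stopifnot(all(c("sequence", "activity") %in% names(tab)))
  motif_seqs <- unique(tab$sequence)
  for (m in motif_seqs) check_aa_sequence(m, id = m)
  copies <- as.integer(copies_per_motif)
  stopifnot(copies >= 0)
  if (sum(nchar(motif_seqs)) * copies > protein$N) {
    pep_stop("total planted length exceeds protein length",
             "pepsilico_placement_error")
  }

  res <- .with_stream(seed, "motifs", {
    chars <- strsplit(protein$sequence, "", fixed = TRUE)[[1L]]
    N <- length(chars)
    occupied <- rep(FALSE, N)
    planted <- list()
    for (m in motif_seqs) {
      L <- nchar(m)
      for (k in seq_len(copies)) {
        placed <- FALSE
        for (try in seq_len(max_retries)) {
          s <- sample.int(N - L + 1L, 1L)
          span <- s:(s + L - 1L)
          if (non_overlapping && any(occupied[span])) next
          chars[span] <- strsplit(m, "", fixed = TRUE)[[1L]]
          occupied[span] <- TRUE
          planted[[length(planted) + 1L]] <-
            data.frame(sequence = m, start = s, end = s + L - 1L,
                       stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed) {
          pep_stop(sprintf(
            "could not place copy %d of motif '%s' without overlap after %d retries",
            k, m, max_retries), "pepsilico_placement_error")
        }
      }
    }
    planted <- if (length(planted) > 0L) do.call(rbind, planted) else
      data.frame(sequence = character(), start = integer(),
                 end = integer(), stringsAsFactors = FALSE)

    if (motif_free_background) {
      planted_key <- paste(planted$sequence, planted$start)
      for (try in seq_len(max_retries)) {
        seq_now <- paste(chars, collapse = "")
        stray <- integer(0)
        for (m in motif_seqs) {
          hits <- .scan_motif(seq_now, m)
          hits <- hits[!paste(m, hits) %in% planted_key]
          for (s in hits) stray <- c(stray, s:(s + nchar(m) - 1L))
        }
        stray <- setdiff(unique(stray), which(occupied))
        if (length(stray) == 0L) break
        chars[stray] <- sample(AA_ALPHABET, length(stray), replace = TRUE)
        if (try == max_retries) {
          pep_stop("could not scrub accidental motif occurrences from the background",
                   "pepsilico_placement_error")
        }
      }
    }
    list(chars = chars, planted = planted)
  })

  new_protein <- protein_record(protein$id, paste(res$chars, collapse = ""),
                                protein$description)
  # expand truth rows to one per activity label of each motif
  planted <- res$planted
  truth <- do.call(rbind, lapply(seq_len(nrow(planted)), function(i) {
    acts <- unique(tab$activity[tab$sequence == planted$sequence[i]])
    data.frame(sequence = planted$sequence[i], start = planted$start[i],
               end = planted$end[i], activity = acts,
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth)) {
    truth <- data.frame(sequence = character(), start = integer(),
                        end = integer(), activity = character(),
                        stringsAsFactors = FALSE)
  }
  structure(list(protein = new_protein, planted = truth,
                 cut_sites = NULL, seed = seed,
                 params = list(copies_per_motif = copies,
                               non_overlapping = non_overlapping,
                               motif_free_background = motif_free_background)),
            class = "SyntheticTruth")
}

#' Construct a protein with planted cleavage sites for one protease
#'
#' Alternates inert spacer runs (drawn from `spacer_alphabet`) with
#' site-matching windows so that the protease must cut exactly at the
#' planted bonds. The spacer alphabet must be inert for the rule: no spacer
#' residue may satisfy a constrained position of any site clause. The
#' construction is verified against the rule after assembly; rules for
#' which inert construction is impossible (e.g. cleavage on either side of
#' a residue class covering the whole alphabet) raise a construction error.
#'
#' @param protease a `Protease`.
#' @param n_sites number of cleavage sites to plant (>= 0).
#' @param spacer_alphabet character vector of inert residues.
#' @param seed integer seed.
#' @param spacer_len integer range (min, max) of each spacer run length.
#' @return a `SyntheticTruth` with `protein`, planted `cut_sites` (named
#'   list holding the bond indices for this protease), `seed`, `params`.
#' @examples
#' rb <- load_rulebook()
#' tr <- generate_cleavage_fixture(rb$trypsin, 4,
#'                                 spacer_alphabet = c("A", "G", "S", "T", "V"),
#'                                 seed = 1)
#' tr$cut_sites
#' @export
generate_cleavage_fixture <- function(protease, n_sites, spacer_alphabet,
                                      seed, spacer_len = c(3L, 8L)) {
  stopifnot(inherits(protease, "Protease"), n_sites >= 0,
            length(spacer_alphabet) >= 1)
  spacer_alphabet <- unique(as.character(spacer_alphabet))
  stopifnot(all(spacer_alphabet %in% AA_ALPHABET))

  # inertness: no spacer residue may satisfy any constrained site-clause
  # position, so windows made purely of spacers can never match
  for (cl in protease$clauses) {
    for (pos in c("p2", "p1", "p1p", "p2p")) {
      clash <- intersect(spacer_alphabet, cl[[pos]])
      if (length(clash) > 0L) {
        pep_stop(sprintf(
          "protease rule incompatible with spacer alphabet: spacer residue(s) %s satisfy a constrained %s position",
          paste(clash, collapse = ","), toupper(pos)),
          "pepsilico_construction_error")
      }
    }
  }

  # choose a concrete residue window for the first site clause that no
  # exception clause vetoes; unconstrained positions stay NA (spacer)
  clause <- protease$clauses[[1L]]
  choices <- lapply(c("p2", "p1", "p1p", "p2p"), function(pos) {
    if (is.null(clause[[pos]])) NA_character_ else clause[[pos]]
  })
  grid <- expand.grid(choices, stringsAsFactors = FALSE)
  names(grid) <- c("p2", "p1", "p1p", "p2p")
  vetoed <- function(w) {
    any(vapply(protease$exceptions, function(ex) {
      all(vapply(c("p2", "p1", "p1p", "p2p"), function(pos) {
        is.null(ex[[pos]]) ||
          (!is.na(w[[pos]]) && w[[pos]] %in% ex[[pos]])
      }, logical(1)))
    }, logical(1)))
  }
  win <- NULL
  for (i in seq_len(nrow(grid))) {
    if (!vetoed(as.list(grid[i, ]))) {
      win <- as.list(grid[i, ])
      break
    }
  }
  if (is.null(win)) {
    pep_stop("every residue choice for the site window is vetoed by an exception clause",
             "pepsilico_construction_error")
  }

  fixture <- .with_stream(seed, "cleavage", {
    spacer <- function() {
      paste(sample(spacer_alphabet,
                   sample(seq(spacer_len[1L], spacer_len[2L]), 1L),
                   replace = TRUE), collapse = "")
    }
    pick <- function(x) if (is.na(x)) sample(spacer_alphabet, 1L) else x
    chunks <- character(0)
    bonds <- integer(0)
    pos <- 0L
    add <- function(txt) {
      chunks <<- c(chunks, txt)
      pos <<- pos + nchar(txt)
    }
    add(spacer())
    for (k in seq_len(n_sites)) {
      add(paste0(pick(win$p2), pick(win$p1)))
      bonds <- c(bonds, pos)  # scissile bond after the P1 residue
      add(paste0(pick(win$p1p), pick(win$p2p)))
      add(spacer())
    }
    list(sequence = paste(chunks, collapse = ""), bonds = bonds)
  })

  rec <- protein_record(sprintf("synth_cleavage_%s_s%d", protease$name, seed),
                        fixture$sequence)
  got <- cut_sites(rec, protease)
  if (!identical(as.integer(got), as.integer(fixture$bonds))) {
    pep_stop(sprintf(
      "construction self-check failed for '%s': planted bonds [%s], rule cuts [%s]; the rule is incompatible with inert-spacer construction",
      protease$name, paste(fixture$bonds, collapse = ","),
      paste(got, collapse = ",")), "pepsilico_construction_error")
  }
  structure(list(protein = rec, planted = NULL,
                 cut_sites = stats::setNames(list(as.integer(fixture$bonds)),
                                             protease$name),
                 seed = seed,
                 params = list(n_sites = n_sites,
                               spacer_alphabet = spacer_alphabet,
                               spacer_len = spacer_len)),
            class = "SyntheticTruth")
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf("<SyntheticTruth> %s (seed %s)\n", x$protein$id,
              format(x$seed)))
  if (!is.null(x$planted) && nrow(x$planted) > 0L) {
    cat(sprintf("  planted motif occurrences: %d\n", nrow(x$planted)))
  }
  if (!is.null(x$cut_sites)) {
    for (nm in names(x$cut_sites)) {
      cat(sprintf("  planted cut sites (%s): %s\n", nm,
                  paste(x$cut_sites[[nm]], collapse = ", ")))
    }
  }
  invisible(x)
}

#' Write a synthetic truth bundle to disk
#'
#' FASTA for the sequence plus a JSON truth file (planted occurrences, cut
#' sites, seed, parameters) for exact replay.
#'
#' @param truth a `SyntheticTruth`.
#' @param fasta_path,truth_path output paths.
#' @return invisibly, `truth_path`.
#' @export
write_synthetic_truth <- function(truth, fasta_path, truth_path) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  write_fasta(truth$protein, fasta_path)
  jsonlite::write_json(
    list(protein_id = truth$protein$id, N = truth$protein$N,
         planted = truth$planted, cut_sites = truth$cut_sites,
         seed = truth$seed, params = truth$params),
    truth_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(truth_path)
}
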