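# Independent brute-force oracles and small random-instance generators.
# These deliberately re-derive results by the dumbest possible method and
# share no code with the implementation paths they check.

# every occurrence of every refset peptide, by scanning every substring of
# every length present in the refset
oracle_occurrences <- function(sequence, entries) {
  N <- nchar(sequence)
  out <- list()
  for (i in seq_len(nrow(entries))) {
    pep <- entries$sequence[i]
    L <- nchar(pep)
    if (L > N) next
    for (s in seq_len(N - L + 1L)) {
      if (substr(sequence, s, s + L - 1L) == pep) {
        out[[length(out) + 1L]] <- data.frame(
          activity = entries$activity[i], sequence = pep,
          start = s, end = s + L - 1L, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(activity = character(), sequence = character(),
                      start = integer(), end = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$activity, res$start, res$end, res$sequence), , drop = FALSE]
}

# per-bond window evaluation of a cleavage rule, one bond at a time
oracle_cut_sites <- function(sequence, prot) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  N <- length(chars)
  if (N < 2L) return(integer(0))
  at <- function(i) if (i >= 1L && i <= N) chars[[i]] else NA_character_
  clause_ok <- function(cl, i) {
    win <- list(p2 = at(i - 1L), p1 = at(i), p1p = at(i + 1L),
                p2p = at(i + 2L))
    for (pos in names(win)) {
      set <- cl[[pos]]
      if (is.null(set)) next
      if (is.na(win[[pos]]) || !(win[[pos]] %in% set)) return(FALSE)
    }
    TRUE
  }
  sites <- integer(0)
  for (i in seq_len(N - 1L)) {
    hit <- FALSE
    for (cl in prot$clauses) if (clause_ok(cl, i)) { hit <- TRUE; break }
    if (hit) {
      for (ex in prot$exceptions) if (clause_ok(ex, i)) { hit <- FALSE; break }
    }
    if (hit) sites <- c(sites, i)
  }
  sites
}

# random reference set of unique short peptides across a few activities
random_refset <- function(n_entries, max_len = 3L, seed = 1L,
                          labels = c("ACE inhibitor", "DPP-IV inhibitor",
                                     "antioxidative")) {
  withr::with_seed(seed, {
    seqs <- character(0)
    while (length(seqs) < n_entries) {
      L <- sample.int(max_len, 1L)
      seqs <- unique(c(seqs, paste(
        sample(pepsilico:::AA_ALPHABET, L, replace = TRUE), collapse = "")))
    }
    seqs <- seqs[seq_len(n_entries)]
    suppressWarnings(reference_set(data.frame(
      sequence = seqs,
      activity = sample(labels, n_entries, replace = TRUE),
      ref_id = sprintf("R%04d", seq_len(n_entries)),
      source = "random test refset", stringsAsFactors = FALSE)))
  })
}

flatten_profile <- function(profile) {
  out <- list()
  for (act in names(profile$activities)) {
    occ <- profile$activities[[act]]$occurrences
    if (nrow(occ) > 0L) {
      out[[act]] <- data.frame(activity = act, sequence = occ$sequence,
                               start = occ$start, end = occ$end,
                               stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(activity = character(), sequence = character(),
                      start = integer(), end = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$activity, res$start, res$end, res$sequence), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
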