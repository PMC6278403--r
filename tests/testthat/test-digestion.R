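rb <- load_rulebook()

test_that("bundled rulebook covers the documented protease subset", {
  expect_true(all(c("pepsin_ph2", "trypsin", "chymotrypsin_A",
                    "chymotrypsin_C", "papain", "bromelain", "ficin",
                    "thermolysin", "proteinase_K", "pancreatic_elastase")
                  %in% names(rb)))
  expect_equal(rb$trypsin$ec, "3.4.21.4")
})

test_that("trypsin worked example: cut after K/R but not before P", {
  p <- protein_record("p", "AKRPSTK")
  expect_equal(cut_sites(p, rb$trypsin), 2L)  # R3 blocked by P4; K7 terminal
  res <- digest(p, rb$trypsin)
  expect_equal(res$fragments$sequence, c("AK", "RPSTK"))
})

test_that("single-residue proteins have no bonds, exceptions only remove sites", {
  expect_equal(cut_sites(protein_record("p", "K"), rb$trypsin), integer(0))
  no_exc <- protease("trypsin_no_exc", clauses = list(list(p1 = c("K", "R"))))
  set.seed(5)
  for (i in 1:20) {
    p <- generate_protein(60, seed = 500 + i)
    expect_true(all(cut_sites(p, rb$trypsin) %in% cut_sites(p, no_exc)))
  }
})

test_that("cut_sites matches the per-bond brute-force oracle on all bundled rules", {
  for (i in 1:40) {
    p <- generate_protein(sample(30:120, 1), seed = 700 + i)
    for (nm in names(rb)) {
      expect_equal(cut_sites(p, rb[[nm]]),
                   oracle_cut_sites(p$sequence, rb[[nm]]),
                   info = sprintf("protein %d, %s", i, nm))
    }
  }
})

test_that("fragments conserve the parent and combined digestion is the site union", {
  set.seed(11)
  for (i in 1:60) {
    p <- generate_protein(sample(30:150, 1), seed = 900 + i)
    for (nm in names(rb)) {
      frags <- digest(p, rb[[nm]])$fragments
      expect_equal(paste(frags$sequence[!frags$partial], collapse = ""),
                   p$sequence)
    }
    pair <- sample(names(rb), 2)
    both <- digest(p, rb[pair])
    expect_equal(both$sites,
                 sort(union(cut_sites(p, rb[[pair[1]]]),
                            cut_sites(p, rb[[pair[2]]]))))
    # determinism
    expect_identical(both, digest(p, rb[pair]))
  }
})

test_that("no matching sites leaves the whole protein as one fragment", {
  p <- protein_record("p", "GGGGGG")
  res <- digest(p, rb$trypsin)
  expect_equal(res$fragments$sequence, "GGGGGG")
  expect_equal(res$sites, integer(0))
})

test_that("at most three proteases are accepted", {
  p <- generate_protein(50, seed = 1)
  expect_error(digest(p, rb[1:4]), "1 and 3",
               class = "pepsilico_usage_error")
  expect_error(digest(p, list()), class = "pepsilico_usage_error")
})

test_that("missed_cleavages emits every run of <= m+1 consecutive segments", {
  p <- generate_protein(200, seed = 77)
  for (m in 0:3) {
    res <- digest(p, rb$trypsin, missed_cleavages = m)
    s <- length(res$sites)
    n_seg <- s + 1L
    expected_partials <- sum(vapply(seq(2L, m + 1L), function(j) {
      max(0L, n_seg - j + 1L)
    }, integer(1))[seq_len(max(0L, m))])
    expect_equal(sum(res$fragments$partial), expected_partials)
    # covering digest unaffected by m
    expect_equal(res$fragments[!res$fragments$partial, ],
                 digest(p, rb$trypsin)$fragments)
    # every emitted fragment is the parent subsequence at its coordinates
    expect_true(all(res$fragments$sequence ==
                      substring(p$sequence, res$fragments$start,
                                res$fragments$end)))
  }
})

test_that("search_active_fragments does whole-fragment exact matching", {
  rs <- reference_set(data.frame(
    sequence = c("AK", "AK", "GAK"),
    activity = c("ACE inhibitor", "DPP-IV inhibitor", "antioxidative"),
    ref_id = c("r1", "r2", "r3"), source = "t"))
  p <- protein_record("p", "AKRPSTK")
  res <- search_active_fragments(digest(p, rb$trypsin), rs)
  expect_equal(res$matches[["ACE inhibitor"]]$count, 1L)
  # fragment "AK" equals a 2-activity peptide: counts once per activity
  expect_equal(res$matches[["DPP-IV inhibitor"]]$count, 1L)
  # "AK" is a substring of fragment "RPSTK"? no - and "GAK" reference never
  # matches fragment "AK" by substring either direction
  expect_equal(res$matches[["antioxidative"]]$count, 0L)
  expect_true(all(vapply(res$matches, function(m) {
    m$count == nrow(m$pairs)
  }, logical(1))))
})

test_that("planted cleavage sites release the planted dipeptides", {
  # engineer tryptic release of 5 copies of reference dipeptide "GK":
  # ...spacer-G-K|... with trypsin cutting after every K
  seqs <- paste(rep("GK", 5), collapse = "")
  p <- protein_record("p", paste0(seqs, "GG"))
  rs <- reference_set(data.frame(sequence = "GK", activity = "ACE inhibitor",
                                 ref_id = "r", source = "t"))
  res <- search_active_fragments(digest(p, rb$trypsin), rs)
  expect_equal(res$matches[["ACE inhibitor"]]$count, 5L)
})

test_that("rank_proteases sorts by released count with name tie-break", {
  p <- read_fasta(system.file("extdata", "synthetic_vitellogenin_615aa.fasta",
                              package = "pepsilico"))[[1]]
  fx <- builtin_fixture_set()
  tab <- rank_proteases(p, rb, fx, "DPP-IV inhibitor",
                        combinations = list(c("trypsin", "chymotrypsin_A")))
  expect_equal(nrow(tab), length(rb) + 1L)
  cnt <- tab[["DPP-IV inhibitor"]]
  expect_true(all(diff(cnt) <= 0))
  ties <- split(tab$protease, cnt)
  expect_true(all(vapply(ties, function(x) !is.unsorted(x), logical(1))))
  expect_error(rank_proteases(p, rb, fx, "no such activity"),
               "known labels", class = "pepsilico_usage_error")
  expect_error(rank_proteases(p, list(), fx, "ACE inhibitor"),
               class = "pepsilico_usage_error")
})

test_that("more cut sites need not release more bioactive fragments", {
  # coarse enzyme releases the tripeptide reference; a finer enzyme (site
  # superset) destroys it: ranking must reflect released counts, not site
  # numbers
  coarse <- protease("coarse", clauses = list(list(p1 = c("K", "P"))))
  fine <- protease("fine", clauses = list(list(p1 = c("K", "P", "G"))))
  p <- protein_record("p", "KGPKGPK")
  rs <- reference_set(data.frame(sequence = "GP", activity = "ACE inhibitor",
                                 ref_id = "r", source = "t"))
  stopifnot(all(cut_sites(p, coarse) %in% cut_sites(p, fine)))
  n_coarse <- search_active_fragments(digest(p, coarse),
                                      rs)$matches[[1]]$count
  n_fine <- search_active_fragments(digest(p, fine), rs)$matches[[1]]$count
  expect_gt(n_coarse, n_fine)
  tab <- rank_proteases(p, list(coarse = coarse, fine = fine), rs,
                        "ACE inhibitor")
  expect_equal(tab$protease[1], "coarse")
})
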