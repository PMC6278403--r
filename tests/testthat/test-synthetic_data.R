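test_that("generate_protein is deterministic, seeded per stream, leaves RNG alone", {
  a <- generate_protein(615, seed = 1)
  b <- generate_protein(615, seed = 1)
  expect_identical(a$sequence, b$sequence)
  expect_false(identical(a$sequence, generate_protein(615, seed = 2)$sequence))
  # global RNG state is untouched
  set.seed(123); before <- .Random.seed
  invisible(generate_protein(100, seed = 9))
  expect_identical(.Random.seed, before)
  expect_equal(generate_protein(1, seed = 1)$N, 1L)
})

test_that("uniform composition is uniform within 5 binomial standard errors", {
  p <- generate_protein(10000, seed = 4)
  freq <- table(factor(strsplit(p$sequence, "")[[1]],
                       levels = pepsilico:::AA_ALPHABET)) / p$N
  se <- sqrt((1 / 20) * (19 / 20) / p$N)
  expect_true(all(abs(freq - 1 / 20) <= 5 * se))
})

test_that("composition vectors are validated and honoured", {
  expect_error(generate_protein(10, composition = c(A = 1), seed = 1),
               class = "pepsilico_domain_error")
  bad <- vertebrate_composition(); bad["A"] <- bad["A"] + 0.5
  expect_error(generate_protein(10, composition = bad, seed = 1),
               class = "pepsilico_domain_error")
  only_gp <- setNames(rep(0, 20), pepsilico:::AA_ALPHABET)
  only_gp[c("G", "P")] <- 0.5
  p <- generate_protein(500, composition = only_gp, seed = 5)
  expect_true(all(strsplit(p$sequence, "")[[1]] %in% c("G", "P")))
  expect_equal(sum(vertebrate_composition()), 1)
})

test_that("plant_motifs returns sound ground truth and replays exactly", {
  base <- generate_protein(300, seed = 21)
  motifs <- data.frame(sequence = c("WCW", "HMH"),
                       activity = c("ACE inhibitor", "antioxidative"))
  t1 <- plant_motifs(base, motifs, copies_per_motif = 3, seed = 22)
  t2 <- plant_motifs(base, motifs, copies_per_motif = 3, seed = 22)
  expect_identical(t1$protein$sequence, t2$protein$sequence)
  expect_identical(t1$planted, t2$planted)
  # every planted occurrence verifies against the sequence by inspection
  for (i in seq_len(nrow(t1$planted))) {
    expect_equal(substr(t1$protein$sequence, t1$planted$start[i],
                        t1$planted$end[i]),
                 t1$planted$sequence[i])
  }
  # non-overlapping placements are disjoint
  spans <- unlist(lapply(unique(paste(t1$planted$start, t1$planted$end)),
                         function(k) {
    se <- as.integer(strsplit(k, " ")[[1]])
    se[1]:se[2]
  }))
  expect_false(anyDuplicated(spans) > 0)
})

test_that("plant_motifs edge cases: zero copies, impossible placement", {
  base <- generate_protein(50, seed = 31)
  motifs <- data.frame(sequence = "WCW", activity = "ACE inhibitor")
  t0 <- plant_motifs(base, motifs, copies_per_motif = 0, seed = 1)
  expect_equal(nrow(t0$planted), 0L)
  expect_identical(t0$protein$sequence, base$sequence)
  expect_error(plant_motifs(generate_protein(10, seed = 1), motifs,
                            copies_per_motif = 5, seed = 1),
               class = "pepsilico_placement_error")
})

test_that("motif-free background makes planted counts exact", {
  motifs <- data.frame(sequence = "GP", activity = "ACE inhibitor")
  only_gp <- setNames(rep(0, 20), pepsilico:::AA_ALPHABET)
  only_gp[c("G", "P")] <- 0.5  # worst-case background, dense in G/P
  base <- generate_protein(200, composition = only_gp, seed = 41)
  truth <- plant_motifs(base, motifs, copies_per_motif = 3, seed = 42,
                        motif_free_background = TRUE)
  hits <- integer(0)
  s <- truth$protein$sequence
  for (i in seq_len(nchar(s) - 1L)) {
    if (substr(s, i, i + 1L) == "GP") hits <- c(hits, i)
  }
  expect_setequal(hits, truth$planted$start)
  expect_equal(length(hits), 3L)
})

test_that("cleavage fixtures plant exactly the promised sites", {
  rb <- load_rulebook()
  tr <- generate_cleavage_fixture(rb$trypsin, n_sites = 4,
                                  spacer_alphabet = c("A", "G", "S", "T", "V"),
                                  seed = 51)
  expect_equal(cut_sites(tr$protein, rb$trypsin),
               tr$cut_sites$trypsin)
  expect_length(tr$cut_sites$trypsin, 4L)
  expect_equal(nrow(digest(tr$protein, rb$trypsin)$fragments), 5L)
  # replay determinism
  tr2 <- generate_cleavage_fixture(rb$trypsin, n_sites = 4,
                                   spacer_alphabet = c("A", "G", "S", "T", "V"),
                                   seed = 51)
  expect_identical(tr$protein$sequence, tr2$protein$sequence)
  # zero sites -> single whole-protein fragment
  t0 <- generate_cleavage_fixture(rb$trypsin, n_sites = 0,
                                  spacer_alphabet = c("A", "G"), seed = 52)
  expect_equal(nrow(digest(t0$protein, rb$trypsin)$fragments), 1L)
})

test_that("incompatible spacer alphabets raise construction errors", {
  rb <- load_rulebook()
  expect_error(generate_cleavage_fixture(rb$trypsin, 3,
                                         spacer_alphabet = c("A", "K"),
                                         seed = 1),
               class = "pepsilico_construction_error")
  # pepsin cuts on either side of F/L/W/Y: the bond next to a planted
  # window also matches, so inert-spacer construction must fail loudly
  expect_error(generate_cleavage_fixture(rb$pepsin_ph2, 2,
                                         spacer_alphabet = c("A", "G"),
                                         seed = 1),
               class = "pepsilico_construction_error")
})

test_that("synthetic truth bundles round-trip through FASTA + JSON", {
  rb <- load_rulebook()
  tr <- generate_cleavage_fixture(rb$trypsin, 3,
                                  spacer_alphabet = c("A", "G"), seed = 61)
  fa <- withr::local_tempfile(fileext = ".fasta")
  js <- withr::local_tempfile(fileext = ".json")
  write_synthetic_truth(tr, fa, js)
  expect_equal(read_fasta(fa)[[1]]$sequence, tr$protein$sequence)
  truth <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(truth$cut_sites$trypsin, tr$cut_sites$trypsin)
  expect_equal(truth$seed, 61)
})
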