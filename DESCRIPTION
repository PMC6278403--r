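Package: pepsilico
Title: In Silico Bioactive Peptide Profiling and Proteolysis Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mines protein sequences for known bioactive peptide fragments
    (exact-lookup profiling against a reference table of peptides with
    activity labels, e.g. ACE-inhibitory and DPP-IV-inhibitory), computes
    the frequency-of-occurrence statistic A = a/N, simulates enzymatic
    hydrolysis with declarative protease cleavage-specificity rules
    (P2-P1-P1'-P2' site windows with exception clauses) to predict which
    bioactive peptides a protease releases and to rank proteases, computes
    peptide monoisotopic masses, multiply-charged m/z values and
    isotopic-spacing-based charge inference, and summarises identities,
    positives and gaps of a given pairwise protein alignment. A seeded
    synthetic-data module generates random proteins with planted motifs and
    planted cleavage sites so every stage is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    digest,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
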