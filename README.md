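# pepsilico

In silico mining of bioactive peptides from protein sequences: profiling,
simulated enzymatic hydrolysis, and peptide mass-spectrometry arithmetic.

## The problem

Food and by-product proteins (fish roe vitellogenin and apolipoproteins are
the motivating example) encrypt short peptides — mostly di- and tripeptides —
that inhibit angiotensin-I converting enzyme (ACE, antihypertensive
candidates) or dipeptidyl peptidase IV (DPP-IV, anti-diabetic candidates),
or scavenge radicals. Before any wet-lab hydrolysis, one can ask two
questions entirely in silico:

1. **Profiling** — which known bioactive fragments occur in a protein, and
   how densely? For each activity the summary statistic is the *frequency
   of occurrence*

   **A = a / N**,

   where *a* is the number of occurrences of known bioactive fragments with
   that activity (counted per position, overlaps and repeats included) and
   *N* is the protein's residue count.

2. **Enzyme screening** — which protease (or combination of up to three,
   acting simultaneously) would actually *release* those fragments?
   Cleavage is predicted by declarative specificity rules over the
   P2–P1–P1′–P2′ window around each peptide bond (e.g. trypsin: cut after
   K/R, never before P); a fragment counts as a released bioactive peptide
   only if it is *exactly* a known peptide (whole-fragment match).

The package also covers the supporting arithmetic of such studies: peptide
monoisotopic masses, multiply-protonated m/z values
(m/z = (M + z·1.007276)/z), charge-state inference from isotopic spacing
(≈ 1.0034/z), and identities/positives/gaps summaries of a given pairwise
alignment.

Matching is exact lookup against an explicit reference table of peptides
(sequence + activity label). The package ships a small curated fixture set
and a PeptideCutter-style cleavage rulebook; absolute counts are always
relative to those inputs — public bioactive-peptide databases are revised
continuously, so counts against different snapshots are not comparable.
A seeded synthetic-data module (random proteins, planted motifs, planted
cleavage sites) makes every stage testable offline with known ground truth.

## Worked example

```r
library(pepsilico)

fx  <- builtin_fixture_set()           # 58 curated short peptides, 6 activities
vit <- read_fasta(system.file("extdata", "synthetic_vitellogenin_615aa.fasta",
                              package = "pepsilico"))[[1]]   # 615-aa stand-in

profile_report(find_occurrences(vit, fx),
               top_activities = c("DPP-IV inhibitor", "ACE inhibitor",
                                  "antioxidative"))
#>                        protein   N DPP-IV inhibitor ACE inhibitor antioxidative other_activities
#> 1 synthetic_vitellogenin_615aa 615       30 (0.049)    24 (0.039)     9 (0.015)               15
```

Each cell is "a (A)": 30 DPP-IV-inhibitory fragment occurrences in 615
residues gives A = 30/615 = 0.049. (The fixture refset is ~60 peptides, so
these A values are far below those computed against a full database
snapshot — they are fixture-relative by design.)

```r
rb <- load_rulebook()
head(rank_proteases(vit, rb, fx, "DPP-IV inhibitor",
     combinations = list(c("pepsin_ph2", "trypsin", "chymotrypsin_A"))), 3)
#>         protease ACE inhibitor antihypertensive antioxidative DPP-IV inhibitor hypotensive other:inhibitor
#> 1   proteinase_K             5                1             0                1           1               1
#> 2      bromelain             4                0             0                0           0               0
#> 3 chymotrypsin_A             3                0             0                0           0               0
```

Rows are sorted by the requested activity's released count (ties broken by
name); a released count demands the exact peptide as a whole fragment, so
it is far smaller than the profiling count *a*. The TSV rendering of this
table writes `ND` (not detected) for zero cells.

```r
M <- monoisotopic_mass("LVEPELFEYSGVYPK")
sprintf("M = %.2f Da, [M+2H]2+ = %.2f Th, spacing(z = 2) = %.2f Th",
        M, mz(M, 2), isotope_spacing(2))
#> "M = 1768.89 Da, [M+2H]2+ = 885.45 Th, spacing(z = 2) = 0.50 Th"
```

A pipeline run (`run_pipeline(run_config(...))`, or the CLI
`Rscript $(Rscript -e 'cat(system.file("cli","pepsilico.R",package="pepsilico"))') run --fasta ...`)
writes `profile_table.{tsv,json}`, `release_table.{tsv,json}` and a
`manifest.json` (inputs, version, seed, config hash); re-runs are
byte-identical apart from the manifest timestamp.

Note on the bundled FASTA: the 615-residue fixture is a *synthetic*
stand-in (random sequence, vertebrate-like composition, fixed seed), not
the real vitellogenin accession — see the methods vignette.

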