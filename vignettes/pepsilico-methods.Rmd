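---
title: "pepsilico: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pepsilico: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepsilico)
```

# Scope and model

`pepsilico` answers two in silico questions about a protein sequence:
*which known bioactive peptides does it contain* (profiling), and *which
protease would release them* (digestion simulation). Both are exact,
deterministic computations on three explicit inputs: the protein sequence,
a reference table of peptides with activity labels, and a cleavage
rulebook. Nothing is predicted from physicochemistry; a peptide is
"bioactive" here exactly when the reference table says so. That makes every
number reproducible from the inputs — and also means absolute counts are
only meaningful relative to a stated reference snapshot, which is why
`ReferenceSet` carries a mandatory `version_tag` and the bundled fixture is
documented as a curated stand-in, not a database mirror.

## Profiling and the statistic A

`find_occurrences()` scans the protein for every reference peptide and
records 1-based inclusive coordinates. The counting semantics are:

* occurrences are counted **per position**, overlaps and repeats included
  ("AA" occurs three times in "AAAA");
* a peptide carrying *k* activity labels contributes one occurrence to
  each of the *k* activities at each position;
* activities with no occurrences are reported explicitly as zero;
* reference peptides longer than the protein contribute zero (no error);
* single-residue reference entries are legal; their count is the residue
  frequency.

Per activity, the frequency of occurrence is **A = a/N** with *a* the
occurrence count and *N* the protein length. `A` is kept at full precision
internally; only the reporting layer rounds. These semantics were a
genuinely open design point (occurrence-based vs distinct-peptide-based
counting is rarely stated explicitly in this literature); the
occurrence-based convention was chosen, documented here, and — crucially —
the brute-force all-substrings oracle in the test suite implements the
same convention independently, so the tests pin the semantics, not just
the implementation.

## Rounding

Reports round **half away from zero**: A to 3 decimals, masses and m/z to
2, alignment percentages to integers. Published tables in this field mix
truncation and rounding from one cell to the next, so no convention can
match every printed digit; half-away-from-zero is fixed once, implemented
in one exported helper (`round_half_away()`, since base `round()` is
half-to-even), and the package's comparisons against printed values use
the explicit tolerances below rather than chasing any one table's habits.

## Digestion simulation

A `CleavageRule` is a set of *site clauses* over the residue window
P2–P1–P1′–P2′ around a peptide bond (the bond sits between P1 and P1′),
plus *exception clauses* of the same shape that veto a proposed cut.
A bond is cut iff some site clause matches and no exception does.
Conventions, each of which a property test enforces:

* there is no bond before residue 1 or after residue N;
* window positions beyond the termini satisfy unconstrained clause
  positions and fail constrained ones;
* ambiguity codes (permissive mode) never satisfy a constrained position;
* exceptions only remove sites, never add them;
* combined digestion (at most **three** enzymes, the tool convention this
  mirrors) is **simultaneous**: the union of the enzymes' cut-site sets.
  Sequential semantics would need an ordering that no source defines; the
  union is order-free and matches the "co-digestion" reading.
* with `missed_cleavages = m > 0`, every concatenation of up to m+1
  consecutive segments is emitted additionally, flagged `partial`; the
  covering digest is never affected. The default for the bioactivity
  workflow is m = 0; m = 2 is the common tryptic-MS setting.

Released-fragment matching (`search_active_fragments()`) is
**whole-fragment exact**: a fragment counts only if it *is* a reference
peptide, not if it merely contains one. Substring matching would collapse
this into profiling; the two semantics are deliberately distinct, which is
why adding cut sites can *decrease* released counts (a documented
counterexample lives in the test suite) and why `rank_proteases()` ranks
by released counts, never by site numbers.

The bundled rulebook (`inst/extdata/cleavage_rules.tsv`, grammar in the
file header) encodes PeptideCutter-style specificities simplified to the
P2..P2′ window for ten classical proteases: pepsin (pH > 2), trypsin,
chymotrypsin A and C, papain, bromelain, ficin, thermolysin, proteinase K
and pancreatic elastase. Specificity encodings differ between public
tools (pepsin variants especially); released counts therefore depend on
this encoding and are qualitative, not portable constants.

## Mass spectrometry arithmetic

Monoisotopic residue masses are the standard IUPAC values at ≥ 5 decimals
(Gly 57.02146 Da the lightest); water is 18.010565 Da, the proton
1.007276 Da, the ¹³C–¹²C spacing 1.0033548 Da. A peptide's neutral
monoisotopic mass is the residue sum plus one water;
`mz(M, z) = (M + z·1.007276)/z`. There is deliberately no average-mass
mode. Optional fixed per-residue deltas (`MOD_CARBAMIDOMETHYL_C`,
`MOD_OXIDATION_M`) model the two ubiquitous variable modifications; they
are off by default. Charge inference from an observed isotopic spacing
takes the argmin over z = 1..`max_z` of |spacing − 1.0034/z|, ties toward
smaller z, and returns a **no-call** (`NA`) when the best residual exceeds
0.1 Th — beyond that the observation is not an isotopic spacing at any
supported charge. Printed literature m/z values are sometimes truncated
rather than rounded (a 2-decimal value can sit 0.007 below the computed
one), so worked-example tests use an absolute tolerance of ±0.01.

## Alignment statistics

`alignment_stats()` consumes an existing pairwise alignment (two gapped
equal-length strings); producing alignments by database search is out of
scope, and no aligner is bundled — the one convenience this module could
offer (a global aligner) was left out to keep its contract honest: column
counting only. Identities are columns with equal non-gap residues;
positives are columns with substitution score > 0 (BLOSUM62 from
Biostrings by default — every diagonal entry is positive, so
identities ≤ positives structurally); gap columns contain `-` in either
row; a column gapped in both rows is invalid input. Percentages are
round-half-away integers of 100·count/L. One known display anomaly in
published summary lines (a positives percentage printed lower than any
rounding of the counts yields) is not reproducible under any single
convention and is excluded from assertions.

## Synthetic data: what a green test establishes

The generators exist so that ground truth is known *by construction*:

* `generate_protein()` draws residues i.i.d. from a stated composition —
  uniform by default, or the shipped `vertebrate_composition()` preset
  (Swiss-Prot-like averages). Real proteins have domain structure,
  repeats, and composition biases that i.i.d. sampling does not emulate;
  a green profiling test on synthetic data establishes correctness of the
  *counting*, not realism of the *A values*. The A statistic depends
  strongly on composition (proline-rich sequences score high for
  DPP-IV-inhibitory dipeptides), which the composition presets let tests
  explore.
* `plant_motifs()` overwrites residues with motif copies at recorded
  positions; with `motif_free_background = TRUE` it rescrubs accidental
  background occurrences (bounded retries), making planted counts exact.
  Scrubbing resamples uniformly over the alphabet, so scrubbed
  backgrounds drift slightly toward uniform composition.
* `generate_cleavage_fixture()` alternates inert spacers with
  site-matching windows and self-checks the construction; rules that cut
  on either side of a residue class (pepsin) cannot be built this way and
  fail with a construction error — for those, correctness is established
  by the independent per-bond oracle instead.
* One integer seed drives a named stream per generator (protein / motifs
  / cleavage), derived arithmetically below 2³¹; adding a generator never
  perturbs another's draws, and the caller's RNG state is saved and
  restored.

The bundled 615-residue FASTA fixture is such a synthetic sequence
(vertebrate-like composition, fixed seed 615), labelled synthetic in its
filename, header and docs. It stands in for a real 615-residue roe
vitellogenin whose sequence is not redistributable here; every end-to-end
regression that only needs *a* 615-residue input (byte-stability, N in
reports) runs on it, and nothing in the package treats it as the real
accession.

## Numerical and degenerate-input choices

* Validation rejects exactly the complement of the 20-letter alphabet;
  lowercase is upcased with a warning; ambiguity codes (B, Z, X, U, O)
  are rejected unless `permissive = TRUE`, and then never match anything.
* Composition vectors must be non-negative and sum to 1 within 1e-9.
* A 1-residue protein has no bonds: every digest is the identity.
* `frequency_of_occurrence()` refuses N = 0; a = 0 gives A = 0 exactly.
* Ties in charge inference break toward smaller z (the conservative
  call); `which.min` makes that explicit.
* Pipeline TSVs render zero released counts as `ND` (the table convention
  for "not detected"); JSON keeps numeric 0 for machine consumption.

## Known limitations

Exact lookup cannot find unreported peptides (no QSAR); cleavage rules are
window-local and ignore kinetics, pH, temperature and structural
accessibility — in vitro hydrolysates routinely differ; released counts
are not comparable across rulebooks or reference snapshots; the homology
module summarises alignments it is given and cannot regenerate a
published alignment whose second sequence is unavailable.
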