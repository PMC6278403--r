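# Peptide monoisotopic mass, charge-state m/z and isotopic-spacing
# arithmetic. Masses are monoisotopic only (no average-mass mode); reports
# round half away from zero to 2 decimals, internals keep full precision.

# IUPAC/CODATA monoisotopic residue masses (Da), >= 5 decimals
.residue_masses <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

MASS_WATER <- 18.010565   # monoisotopic H2O
MASS_PROTON <- 1.007276   # proton
MASS_C13_C12 <- 1.0033548 # 13C - 12C, the isotopic-envelope spacing at z=1

# common fixed modification deltas, usable via `modifications`
MOD_CARBAMIDOMETHYL_C <- c(C = 57.02146)
MOD_OXIDATION_M <- c(M = 15.994915)

#' Monoisotopic residue mass table
#' @return named numeric vector, one entry per canonical residue (Da).
#' @export
residue_mass_table <- function() .residue_masses

#' Monoisotopic mass of a peptide
#'
#' Sum of monoisotopic residue masses plus one water (the peptide's free
#' termini). Optional fixed per-residue mass deltas model covalent
#' modifications such as carbamidomethyl-C (+57.02146) or oxidized-M
#' (+15.994915); off by default.
#'
#' @param sequence peptide sequence over the 20 canonical codes.
#' @param modifications named numeric vector of per-residue mass deltas in
#'   Da, e.g. `c(C = 57.02146)`; applied to every occurrence of the residue.
#' @return neutral monoisotopic mass in Da (full precision).
#' @examples
#' monoisotopic_mass("LVEPELFEYSGVYPK")  # 1768.89 at 2 decimals
#' monoisotopic_mass("G")                # 75.03
#' @export
monoisotopic_mass <- function(sequence, modifications = NULL) {
  check_aa_sequence(sequence, id = "<peptide>")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  mass <- sum(.residue_masses[chars]) + MASS_WATER
  if (!is.null(modifications)) {
    stopifnot(is.numeric(modifications), !is.null(names(modifications)),
              all(names(modifications) %in% AA_ALPHABET))
    for (res in names(modifications)) {
      mass <- mass + modifications[[res]] * sum(chars == res)
    }
  }
  mass
}

#' m/z of a protonated peptide ion
#'
#' @param mass neutral monoisotopic mass (Da), positive.
#' @param z positive integer charge (number of protons).
#' @return (mass + z * 1.007276) / z, in Thomson.
#' @examples
#' mz(monoisotopic_mass("LVEPELFEYSGVYPK"), 2)  # 885.45
#' @export
mz <- function(mass, z) {
  if (!is.numeric(mass) || length(mass) != 1L || is.na(mass) || mass <= 0) {
    pep_stop("mass must be a positive number", "pepsilico_domain_error")
  }
  if (!is.numeric(z) || length(z) != 1L || is.na(z) || z < 1 ||
      z != round(z)) {
    pep_stop("z must be a positive integer charge", "pepsilico_domain_error")
  }
  (mass + z * MASS_PROTON) / z
}

#' Spacing of adjacent isotope peaks for a given charge
#'
#' Adjacent peaks of one ion's isotopic envelope are separated by the
#' 13C-12C mass difference divided by the charge: ~0.5 Th for 2+ ions,
#' ~0.33 Th for 3+ ions, which is how charge states are read off zoomed
#' spectra.
#'
#' @param z positive integer charge.
#' @return 1.0033548 / z, in Thomson.
#' @export
isotope_spacing <- function(z) {
  if (!is.numeric(z) || length(z) != 1L || is.na(z) || z < 1 ||
      z != round(z)) {
    pep_stop("z must be a positive integer charge", "pepsilico_domain_error")
  }
  MASS_C13_C12 / z
}

#' Infer charge state from an observed isotopic spacing
#'
#' Picks the charge in `1..max_z` whose theoretical spacing 1.0033548/z is
#' closest to the observation; ties break toward smaller z. If the best
#' residual exceeds 0.1 Th the spacing is implausible and `NA` is returned
#' (no call).
#'
#' @param observed_spacing positive spacing in Thomson.
#' @param max_z largest charge considered (default 6).
#' @return integer charge, or `NA_integer_` for no call.
#' @examples
#' infer_charge(0.5)   # 2
#' infer_charge(0.33)  # 3
#' @export
infer_charge <- function(observed_spacing, max_z = 6) {
  if (!is.numeric(observed_spacing) || length(observed_spacing) != 1L ||
      is.na(observed_spacing) || observed_spacing <= 0) {
    pep_stop("observed_spacing must be a positive number",
             "pepsilico_domain_error")
  }
  zs <- seq_len(max_z)
  resid <- abs(observed_spacing - MASS_C13_C12 / zs)
  best <- which.min(resid)  # which.min takes the first = smallest z on ties
  if (resid[best] > 0.1) return(NA_integer_)
  as.integer(zs[best])
}
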