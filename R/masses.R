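# Monoisotopic mass bookkeeping. All residue masses are derived from
# elemental composition rather than hard-coded decimals so that every
# downstream m/z can be audited back to atomic masses.

# Monoisotopic atomic masses (IUPAC 2021), Da.
.ATOMIC <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

#' Physical constants used throughout the package
#'
#' `PROTON_MASS` is the mass of a proton in Da (charge carrier for
#' positive-mode m/z), `WATER_MASS` and `AMMONIA_MASS` are the monoisotopic
#' masses of the corresponding neutral losses.
#'
#' @format Length-one numeric values (Da).
#' @export
PROTON_MASS <- 1.007276466621

#' @rdname PROTON_MASS
#' @export
WATER_MASS <- 2 * .ATOMIC[["H"]] + .ATOMIC[["O"]]

#' @rdname PROTON_MASS
#' @export
AMMONIA_MASS <- 3 * .ATOMIC[["H"]] + .ATOMIC[["N"]]

formula_mass <- function(counts) {
  sum(.ATOMIC[names(counts)] * counts)
}

# Residue (dehydrated) elemental formulas of the five monosaccharide classes.
.MONO_FORMULAS <- list(
  Hex    = c(C = 6,  H = 10, O = 5),
  HexNAc = c(C = 8,  H = 13, N = 1, O = 5),
  Fuc    = c(C = 6,  H = 10, O = 4),
  NeuAc  = c(C = 11, H = 17, N = 1, O = 8),
  NeuGc  = c(C = 11, H = 17, N = 1, O = 9)
)

#' Monosaccharide classes
#'
#' The five monosaccharide classes considered by the engine, and their
#' monoisotopic residue masses (mass added to a glycan chain, Da).
#'
#' @format `MONO_CODES` is a character vector of length 5; `MONO_MASS` a
#'   named numeric vector of residue masses in Da.
#' @export
MONO_CODES <- names(.MONO_FORMULAS)

#' @rdname MONO_CODES
#' @export
MONO_MASS <- vapply(.MONO_FORMULAS, formula_mass, numeric(1))

#' Monoisotopic residue mass of a monosaccharide class
#'
#' @param code One of `"Hex"`, `"HexNAc"`, `"Fuc"`, `"NeuAc"`, `"NeuGc"`
#'   (vectorised).
#' @return Residue mass in Da (the mass the residue adds to a chain, i.e.
#'   the dehydrated monosaccharide).
#' @examples
#' residue_mass("HexNAc")  # ~203.079
#' @export
residue_mass <- function(code) {
  bad <- setdiff(code, MONO_CODES)
  if (length(bad) > 0L) {
    stop("unknown monosaccharide code: ", paste(bad, collapse = ", "))
  }
  unname(MONO_MASS[code])
}

# Amino-acid residue elemental formulas (dehydrated).
.AA_FORMULAS <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1),
  A = c(C = 3,  H = 5,  N = 1, O = 1),
  S = c(C = 3,  H = 5,  N = 1, O = 2),
  P = c(C = 5,  H = 7,  N = 1, O = 1),
  V = c(C = 5,  H = 9,  N = 1, O = 1),
  T = c(C = 4,  H = 7,  N = 1, O = 2),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1),
  I = c(C = 6,  H = 11, N = 1, O = 1),
  N = c(C = 4,  H = 6,  N = 2, O = 2),
  D = c(C = 4,  H = 5,  N = 1, O = 3),
  Q = c(C = 5,  H = 8,  N = 2, O = 2),
  K = c(C = 6,  H = 12, N = 2, O = 1),
  E = c(C = 5,  H = 7,  N = 1, O = 3),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1),
  F = c(C = 9,  H = 9,  N = 1, O = 1),
  R = c(C = 6,  H = 12, N = 4, O = 1),
  Y = c(C = 9,  H = 9,  N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

#' Amino-acid monoisotopic residue masses
#' @format Named numeric vector (Da) over the 20 standard residues.
#' @export
AA_MASS <- vapply(.AA_FORMULAS, formula_mass, numeric(1))

#' Monoisotopic mass of a peptide
#'
#' @param sequence Amino-acid sequence (20-letter alphabet; `X` is rejected
#'   as unmatchable).
#' @param mod_deltas Optional numeric vector of modification delta masses
#'   (Da) to add, e.g. `c(57.02146)` for one carbamidomethyl.
#' @return Neutral monoisotopic peptide mass in Da (residues + water +
#'   modification deltas).
#' @export
peptide_mass <- function(sequence, mod_deltas = numeric(0)) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(aa, names(AA_MASS))
  if (length(bad) > 0L) {
    stop("sequence contains non-standard residue(s): ",
         paste(unique(bad), collapse = ", "))
  }
  sum(AA_MASS[aa]) + WATER_MASS + sum(mod_deltas)
}

# Common modification deltas (Da).
MOD_CARBAMIDOMETHYL <- formula_mass(c(C = 2, H = 3, N = 1, O = 1))  # +57.02146
MOD_OXIDATION <- .ATOMIC[["O"]]                                    # +15.99491
MOD_DEAMIDATION <- .ATOMIC[["O"]] - .ATOMIC[["N"]] - .ATOMIC[["H"]] # +0.98402

#' Convert between m/z and neutral mass
#'
#' @param mass Neutral mass (Da).
#' @param mz Observed m/z.
#' @param z Positive charge state.
#' @return `mass_to_mz()` the m/z of `[M + zH]z+`; `mz_to_mass()` the
#'   neutral mass.
#' @export
mass_to_mz <- function(mass, z = 1L) (mass + z * PROTON_MASS) / z

#' @rdname mass_to_mz
#' @export
mz_to_mass <- function(mz, z = 1L) mz * z - z * PROTON_MASS
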