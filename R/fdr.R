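# Two-level FDR control.
#
# Peptide-level FDR uses shuffled-protein decoys:
#   FDR = (# glycoPSMs with decoy peptides) / (# glycoPSMs with target peptides)
# Glycan-level FDR uses decoy spectra made by random mass shifts of all
# fragment peaks:
#   FDR = (# glycoPSMs with decoy spectra) / (# glycoPSMs with target spectra)
# A glycoPSM passes the joint filter only if both levels are at or below
# the configured threshold.

#' Create a decoy spectrum by random fragment mass shifts
#'
#' Every peak m/z is shifted by an independent uniform draw of magnitude in
#' `[3, 30]` m/z with random sign (the sign is flipped where a negative
#' shift would push the peak to or below 0 m/z). Intensities and the
#' precursor are unchanged.
#'
#' @param s A [spectrum()].
#' @param seed Integer seed; the decoy is deterministic given the seed.
#' @param shift_range Magnitude range of the shifts (m/z).
#' @return A [spectrum()] flagged `is_decoy = TRUE`, id suffixed
#'   `"_decoy"`.
#' @export
make_decoy_spectrum <- function(s, seed, shift_range = c(3, 30)) {
  n <- length(s$mz)
  with_seed(seed, {
    mag <- runif(n, shift_range[1L], shift_range[2L])
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    shift <- mag * sgn
    flip <- s$mz + shift <= 0
    shift[flip] <- mag[flip]
    spectrum(
      id = paste0(s$id, "_decoy"),
      precursor_mz = s$precursor_mz,
      precursor_charge = s$precursor_charge,
      mz = s$mz + shift,
      intensity = s$intensity,
      fragmentation = s$fragmentation,
      is_decoy = TRUE
    )
  })
}

# Shared decoy-competition q-value machinery: sort by score descending
# (decoys first at ties, conservative), FDR_i = #decoy/#target above the
# running threshold, q = monotone (cumulative-minimum from the bottom).
decoy_qvalues <- function(score, is_decoy) {
  n <- length(score)
  if (n == 0L) return(numeric(0))
  ord <- order(-score, !is_decoy)
  dec <- cumsum(is_decoy[ord])
  tgt <- cumsum(!is_decoy[ord])
  fdr <- ifelse(tgt == 0, ifelse(dec == 0, 0, 1), dec / tgt)
  q <- rev(cummin(rev(fdr)))
  out <- numeric(n)
  out[ord] <- q
  out
}

#' Peptide-level FDR table
#'
#' @param psms Data.frame of glycoPSMs with columns `peptide_score` and
#'   `is_decoy_peptide`.
#' @return The input with columns `peptide_fdr` (raw running FDR at each
#'   PSM's score) and `peptide_q` (monotone q-value) appended.
#' @export
peptide_fdr <- function(psms) {
  psms$peptide_q <- decoy_qvalues(psms$peptide_score, psms$is_decoy_peptide)
  ord <- order(-psms$peptide_score, !psms$is_decoy_peptide)
  raw <- numeric(nrow(psms))
  dec <- cumsum(psms$is_decoy_peptide[ord])
  tgt <- cumsum(!psms$is_decoy_peptide[ord])
  raw[ord] <- ifelse(tgt == 0, ifelse(dec == 0, 0, 1), dec / tgt)
  psms$peptide_fdr <- raw
  psms
}

#' Glycan-level FDR table
#'
#' @param psms Data.frame of glycoPSMs (targets and their paired
#'   decoy-spectrum matches, searched through the identical code path)
#'   with columns `glycan_score` and `is_decoy_spectrum`.
#' @return The input with `glycan_fdr` and `glycan_q` columns appended.
#' @export
glycan_fdr <- function(psms) {
  psms$glycan_q <- decoy_qvalues(psms$glycan_score, psms$is_decoy_spectrum)
  ord <- order(-psms$glycan_score, !psms$is_decoy_spectrum)
  raw <- numeric(nrow(psms))
  dec <- cumsum(psms$is_decoy_spectrum[ord])
  tgt <- cumsum(!psms$is_decoy_spectrum[ord])
  raw[ord] <- ifelse(tgt == 0, ifelse(dec == 0, 0, 1), dec / tgt)
  psms$glycan_fdr <- raw
  psms
}

#' Joint two-level FDR filter
#'
#' @param psms Data.frame carrying `peptide_q` and `glycan_q` (from
#'   [peptide_fdr()] and [glycan_fdr()]).
#' @param fdr Filter level (default 0.01); a PSM passes only if both
#'   q-values are `<= fdr`.
#' @return The input with a logical `passes_fdr` column appended (decoy
#'   PSMs never pass).
#' @export
joint_fdr_filter <- function(psms, fdr = 0.01) {
  psms$passes_fdr <- psms$peptide_q <= fdr & psms$glycan_q <= fdr &
    !psms$is_decoy_peptide & !psms$is_decoy_spectrum
  psms
}
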