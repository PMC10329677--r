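# Glycopeptide spectrum triage.
#
# A spectrum is flagged as a glycopeptide spectrum when it carries glycan
# signature (oxonium) ions or a Y-ion ladder; otherwise it is treated as a
# native (non-glyco) peptide spectrum:
#   * one signature ion with relative intensity >= 5% of the base peak, or
#   * at least two signature ions at any intensity, or
#   * a run of >= 3 Y-ion peaks spaced by HexNAc/Hex/Fuc residue masses.

#' The glycan signature (oxonium) ion table
#'
#' Nine diagnostic low-mass ions, computed at full precision from residue
#' masses: Hex (163), HexNAc (204), Fuc (147), NeuAc (292), NeuGc (308),
#' HexNAc-H2O (186), HexNAc-2H2O (168), NeuAc-H2O (274), Hex+HexNAc (366).
#'
#' @return A data.frame with columns `ion` and `mz`.
#' @export
signature_ions <- function() {
  data.frame(
    ion = c("Hex", "HexNAc", "Fuc", "NeuAc", "NeuGc",
            "HexNAc-H2O", "HexNAc-2H2O", "NeuAc-H2O", "Hex+HexNAc"),
    mz = c(
      oxonium_mz(glycan_composition(Hex = 1)),
      oxonium_mz(glycan_composition(HexNAc = 1)),
      oxonium_mz(glycan_composition(Fuc = 1)),
      oxonium_mz(glycan_composition(NeuAc = 1)),
      oxonium_mz(glycan_composition(NeuGc = 1)),
      oxonium_mz(glycan_composition(HexNAc = 1), 1L),
      oxonium_mz(glycan_composition(HexNAc = 1), 2L),
      oxonium_mz(glycan_composition(NeuAc = 1), 1L),
      oxonium_mz(glycan_composition(Hex = 1, HexNAc = 1))
    ),
    stringsAsFactors = FALSE
  )
}

#' Detect glycan signature ions in a spectrum
#'
#' @param s A [spectrum()].
#' @param tol Match tolerance in Da (default 0.02).
#' @return A data.frame with one row per matched signature ion: `ion`,
#'   `theo_mz`, `obs_mz`, `intensity`, `rel_intensity` (fraction of the
#'   base peak).
#' @export
detect_signature_ions <- function(s, tol = 0.02) {
  stopifnot(tol > 0)
  sig <- signature_ions()
  empty <- data.frame(ion = character(0), theo_mz = numeric(0),
                      obs_mz = numeric(0), intensity = numeric(0),
                      rel_intensity = numeric(0), stringsAsFactors = FALSE)
  if (length(s$mz) == 0L) return(empty)
  idx <- match_nearest(sig$mz, s$mz, tol)
  hit <- !is.na(idx)
  if (!any(hit)) return(empty)
  base <- max(s$intensity)
  data.frame(
    ion = sig$ion[hit],
    theo_mz = sig$mz[hit],
    obs_mz = s$mz[idx[hit]],
    intensity = s$intensity[idx[hit]],
    rel_intensity = if (base > 0) s$intensity[idx[hit]] / base else 0,
    stringsAsFactors = FALSE
  )
}

#' Detect glycan Y-ion ladders
#'
#' Finds maximal runs of >= 3 peaks in which each consecutive gap equals a
#' HexNAc (203.079), Hex (162.053) or Fuc (146.058) residue mass within
#' `tol`. "Continuous" means consecutive within the run; unrelated peaks
#' may lie in between.
#'
#' @param s A [spectrum()].
#' @param tol Gap tolerance in Da (default 0.02).
#' @param min_run Minimum run length (default 3).
#' @return A list of integer vectors of peak indices (one per run).
#' @export
detect_ion_ladder <- function(s, tol = 0.02, min_run = 3L) {
  stopifnot(tol > 0)
  n <- length(s$mz)
  if (n < min_run) return(list())
  deltas <- unname(MONO_MASS[c("HexNAc", "Hex", "Fuc")])
  # longest chain ending at each peak (gaps are bounded, so the inner scan
  # only visits peaks within max(deltas) + tol)
  len <- rep(1L, n)
  prev <- rep(NA_integer_, n)
  maxd <- max(deltas) + tol
  j0 <- 1L
  for (i in seq_len(n)) {
    while (s$mz[i] - s$mz[j0] > maxd && j0 < i) j0 <- j0 + 1L
    js <- seq.int(j0, i)
    js <- js[js < i]
    for (j in js) {
      gap <- s$mz[i] - s$mz[j]
      if (any(abs(gap - deltas) <= tol) && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  heads <- setdiff(which(len >= min_run), prev[!is.na(prev)])
  lapply(heads, function(i) {
    run <- i
    while (!is.na(prev[i])) {
      i <- prev[i]
      run <- c(i, run)
    }
    run
  })
}

#' Classify a spectrum as glycopeptide or native
#'
#' @param s A [spectrum()].
#' @param tol Match tolerance in Da for signature ions and ladder gaps.
#' @return A list of class `triage_result` with fields `label`
#'   (`"glyco"`/`"native"`), `signature` (matched-ion data.frame) and
#'   `ladders` (list of runs). `label == "glyco"` iff evidence is
#'   non-empty.
#' @export
classify_spectrum <- function(s, tol = 0.02) {
  sig <- detect_signature_ions(s, tol)
  strong <- nrow(sig) >= 1L && any(sig$rel_intensity >= 0.05)
  multi <- nrow(sig) >= 2L
  ladders <- list()
  glyco <- strong || multi
  if (!glyco) {
    ladders <- detect_ion_ladder(s, tol)
    glyco <- length(ladders) > 0L
  }
  structure(list(
    label = if (glyco) "glyco" else "native",
    signature = if (strong || multi) sig else sig[0, ],
    ladders = ladders
  ), class = "triage_result")
}

#' Remove putative glycan peaks from a spectrum
#'
#' Drops signature-ion peaks and peaks belonging to detected Y-ion ladder
#' runs; used before peptide scoring so glycan peaks do not inflate the
#' peptide score. The input spectrum is not modified.
#'
#' @param s A [spectrum()].
#' @param tol Tolerance in Da.
#' @return A new [spectrum()] without the glycan peaks.
#' @export
remove_glycan_peaks <- function(s, tol = 0.02) {
  drop <- integer(0)
  sig <- detect_signature_ions(s, tol)
  if (nrow(sig) > 0L) {
    drop <- c(drop, match_nearest(sig$theo_mz, s$mz, tol))
  }
  for (run in detect_ion_ladder(s, tol)) drop <- c(drop, run)
  drop <- unique(drop[!is.na(drop)])
  if (length(drop) == 0L) return(s)
  keep <- setdiff(seq_along(s$mz), drop)
  out <- s
  out$mz <- s$mz[keep]
  out$intensity <- s$intensity[keep]
  out
}

#' Triage a set of spectra and tabulate the result
#'
#' @param spectra List of [spectrum()]s.
#' @param tol Tolerance in Da.
#' @return A data.frame with columns `id`, `label`, `n_signature`,
#'   `n_ladders` (the triage report).
#' @export
triage_report <- function(spectra, tol = 0.02) {
  rows <- lapply(spectra, function(s) {
    tr <- classify_spectrum(s, tol)
    data.frame(id = s$id, label = tr$label,
               n_signature = nrow(tr$signature),
               n_ladders = length(tr$ladders),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
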