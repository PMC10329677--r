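# Peptide and glycan match scoring.
#
# The vendor engines behind published glycopeptide searches use trained
# scorers (a linear discriminant for peptides, a boosted-tree regressor for
# glycans) whose coefficients are not public. The scores here are documented
# fixed-form surrogates with the same qualitative behaviour: deterministic,
# non-negative, strictly increasing in matched evidence, and invariant to
# global intensity scaling. The glycan scorer's weights can be replaced by
# any function with the same signature.

#' Score a peptide-spectrum match
#'
#' `sum(log2(1 + relative intensity))` over matched theoretical backbone
#' ions plus `0.5 *` the matched fraction of the primary (plain 1+ b/y or
#' c/z) series.
#'
#' @param s A [spectrum()].
#' @param sequence Peptide sequence.
#' @param delta Optional per-residue modification delta vector.
#' @param cfg A [search_config()].
#' @param max_mz Optionally restrict matching to theoretical ions below
#'   this m/z (the "lower end" rule of the peptide-based search stage).
#' @param ions Precomputed [peptide_ions()] table (cache for speed).
#' @return Non-negative score; 0 when nothing matches.
#' @export
peptide_score <- function(s, sequence, delta = NULL, cfg = search_config(),
                          max_mz = Inf, ions = NULL) {
  if (is.null(ions)) {
    ions <- peptide_ions(sequence, delta, fragmentation = s$fragmentation)
  }
  ions <- ions[ions$mz <= max_mz, , drop = FALSE]
  if (nrow(ions) == 0L || length(s$mz) == 0L) return(0)
  matched <- match_nearest(ions$mz, s$mz, cfg$fragment_tol)
  hit <- !is.na(matched)
  if (!any(hit)) return(0)
  rel <- s$intensity[matched[hit]] /
    if (max(s$intensity) > 0) max(s$intensity) else 1
  primary <- ions$primary
  frac_primary <- if (any(primary)) sum(hit & primary) / sum(primary) else 0
  sum(log2(1 + rel)) + 0.5 * frac_primary
}

#' Score a glycan-spectrum match
#'
#' Fixed-weight linear combination of five features of the glycopeptide
#' Y/B ion evidence:
#' 0.4 x fraction of theoretical Y ions observed, 0.2 x min-max-normalised
#' log10 summed matched-Y relative intensity, 0.2 x indicator that the
#' five N-core Y ions are all observed, 0.1 x fraction of theoretical B
#' ions observed, 0.1 x matched-Y count capped at 10.
#'
#' @param s A [spectrum()].
#' @param pep_mass Neutral peptide mass (Da).
#' @param tree Glycan tree (ignored when `frags` is supplied).
#' @param cfg A [search_config()] (glycan fragment tolerance in ppm).
#' @param frags Optional precomputed fragment sets: a list (or
#'   [glycan_record()]) with `y_masses` (retained glycan masses incl. 0),
#'   `b_masses` and `composition`; avoids re-enumerating the tree.
#' @return Score in `[0, 1]`.
#' @export
glycan_score <- function(s, pep_mass, tree, cfg = search_config(),
                         frags = NULL) {
  if (is.null(frags)) {
    frags <- list(
      y_masses = sort(unique(round(enumerate_y_fragments(tree, 0)$glycan_mass,
                                   6))),
      b_masses = sort(unique(round(enumerate_b_fragments(tree)$neutral_mass,
                                   6))),
      composition = tree_composition(tree)
    )
  }
  species <- frags$y_masses
  n_species <- length(species)
  ymz <- c(mass_to_mz(pep_mass + species, 1L),
           mass_to_mz(pep_mass + species, 2L))
  matched <- match_nearest(ymz, s$mz, ppm_tol(ymz, cfg$glycan_tol_ppm))
  hit_y <- !is.na(matched)
  hit_species <- hit_y[seq_len(n_species)] |
    hit_y[n_species + seq_len(n_species)]
  y_frac <- mean(hit_species)

  base <- if (length(s$intensity) > 0L && max(s$intensity) > 0) {
    max(s$intensity)
  } else 1
  sum_rel <- sum(s$intensity[unique(matched[hit_y])]) / base
  log_int <- if (n_species > 0) {
    min(1, log10(1 + sum_rel) / log10(1 + n_species))
  } else 0

  core <- as.numeric(ncore_observed(s, pep_mass, frags$composition, cfg))

  b_frac <- if (length(frags$b_masses) > 0L) {
    bmz <- frags$b_masses + PROTON_MASS
    mean(!is.na(match_nearest(bmz, s$mz, ppm_tol(bmz, cfg$glycan_tol_ppm))))
  } else 0

  y_count <- min(1, sum(hit_species) / 10)

  0.4 * y_frac + 0.2 * log_int + 0.2 * core + 0.1 * b_frac + 0.1 * y_count
}

# TRUE iff the five N-core Y ions (pep + HexNAc1, HexNAc2, HexNAc2Hex1..3)
# are all observed at 1+; only evaluated for glycans that contain the core
# composition.
ncore_observed <- function(s, pep_mass, comp, cfg) {
  if (comp[["HexNAc"]] < 2L || comp[["Hex"]] < 3L) return(FALSE)
  steps <- cumsum(MONO_MASS[c("HexNAc", "HexNAc", "Hex", "Hex", "Hex")])
  mzs <- mass_to_mz(pep_mass + steps, 1L)
  all(!is.na(match_nearest(mzs, s$mz, ppm_tol(mzs, cfg$glycan_tol_ppm))))
}

#' Structure confidence score (S-score)
#'
#' Relative score gap between the best and second-best glycan structures
#' sharing a composition: `(top - second) / top`.
#'
#' @param scores Numeric vector of glycan scores of same-composition
#'   candidates (any order).
#' @return Fraction in `[0, 1]`; 1 when only one candidate exists; `NA`
#'   when the top score is not positive.
#' @export
s_score <- function(scores) {
  if (length(scores) == 0L) stop("no candidates")
  top <- max(scores)
  if (top <= 0) return(NA_real_)
  if (length(scores) == 1L) return(1)
  second <- max(scores[-which.max(scores)])
  (top - second) / top
}
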