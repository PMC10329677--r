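# Glycosylation-site localization (A-score).
#
# When a peptide offers several candidate sites, the assignment is scored
# by site-determining internal fragment ions: backbone ions carrying one
# monosaccharide (the glycan root residue) or the intact glycan. The
# A-score is -10*log10(P) where P is a binomial tail probability that the
# best site's differential evidence arises by chance; a peptide with a
# single candidate site gets the sentinel score 1000.

# Theoretical site-determining ion m/z values for glycan placed at `site`.
# Backbone series per fragmentation scheme, each ion carrying either the
# glycan root residue or the intact glycan, charges 1-2.
site_ions <- function(sequence, delta, site, tree, fragmentation = "HCD") {
  bm <- backbone_masses(sequence, delta)
  n_frag <- length(bm$b)
  if (n_frag == 0L) return(numeric(0))
  root_mass <- MONO_MASS[[tree$code]]
  full_mass <- tree_mass(tree)
  npep <- n_frag + 1L
  idx <- seq_len(n_frag)
  yi <- rev(bm$y)                       # y_i indexed from the C terminus
  prefix_has <- idx >= site             # b_i contains residue `site`
  suffix_has <- idx >= (npep - site + 1L)  # y_i contains residue `site`
  mzs <- numeric(0)
  add <- function(neutral) {
    mzs <<- c(mzs, mass_to_mz(neutral, 1L), mass_to_mz(neutral, 2L))
  }
  for (gmass in unique(c(root_mass, full_mass))) {
    if (fragmentation %in% c("HCD", "EThcD")) {
      add(bm$b[prefix_has] + gmass)
      add(yi[suffix_has] + gmass)
    }
    if (fragmentation %in% c("ETD", "EThcD")) {
      add(bm$b[prefix_has] + AMMONIA_MASS + gmass)
      add(yi[suffix_has] - AMMONIA_MASS + .ATOMIC[["H"]] + gmass)
    }
  }
  sort(unique(round(mzs, 6)))
}

# Chance probability that a random theoretical ion matches a peak:
# local peak density within +/-100 m/z around the ion, times the match
# window 2*tol, capped to [1e-4, 0.5].
chance_match_prob <- function(theo_mz, s, tol) {
  if (length(s$mz) == 0L) return(rep(1e-4, length(theo_mz)))
  lo <- findInterval(theo_mz - 100, s$mz)
  hi <- findInterval(theo_mz + 100, s$mz)
  local_n <- pmax(hi - lo, 0L)
  pmin(pmax(local_n * 2 * tol / 200, 1e-4), 0.5)
}

#' Localize a glycosylation site and compute its A-score
#'
#' @param s A [spectrum()].
#' @param sequence Peptide sequence.
#' @param delta Optional per-residue modification delta vector.
#' @param tree Glycan tree assigned to the peptide.
#' @param sites Integer vector of candidate site positions (non-empty).
#' @param cfg A [search_config()] (fragment tolerance).
#' @return A list of class `site_assignment` with fields `best_site`,
#'   `a_score` (1000 iff exactly one candidate site), `second_site`,
#'   `n_determining`, `n_matched`.
#' @export
a_score <- function(s, sequence, delta = NULL, tree, sites,
                    cfg = search_config()) {
  stopifnot(length(sites) >= 1L)
  if (is.null(delta)) delta <- numeric(nchar(sequence))
  if (length(sites) == 1L) {
    return(structure(list(best_site = sites, a_score = 1000,
                          second_site = NA_integer_, n_determining = 0L,
                          n_matched = 0L), class = "site_assignment"))
  }
  tol <- cfg$fragment_tol
  per_site <- lapply(sites, function(st)
    site_ions(sequence, delta, st, tree, s$fragmentation))
  n_matched <- vapply(per_site, function(mzs) {
    if (length(mzs) == 0L) return(0L)
    sum(!is.na(match_nearest(mzs, s$mz, tol)))
  }, integer(1))
  ord <- order(-n_matched, sites)
  best <- ord[1L]
  second <- ord[2L]
  # differential (site-determining) ions: in the best site's set only
  det <- setdiff(per_site[[best]], per_site[[second]])
  if (length(det) == 0L) {
    p_val <- 1
    k <- 0L
  } else {
    hit <- !is.na(match_nearest(det, s$mz, tol))
    k <- sum(hit)
    p <- mean(chance_match_prob(det, s, tol))
    # P(X >= k) for X ~ Binomial(n, p); k = 0 gives P = 1
    p_val <- if (k == 0L) 1 else pbinom(k - 1L, length(det), p,
                                        lower.tail = FALSE)
  }
  structure(list(
    best_site = sites[best],
    a_score = -10 * log10(max(p_val, 1e-100)),
    second_site = sites[second],
    n_determining = length(det),
    n_matched = k
  ), class = "site_assignment")
}

#' Compare a de novo glycan to a database (target) glycan
#'
#' Three match levels: same composition; shared fragment-ion fraction
#' (shared Y-and-B fragment masses over the target's fragment masses); and
#' exact structural identity (canonical keys).
#'
#' @param denovo,target Glycan trees.
#' @param digits Mass rounding (decimal places) used when intersecting
#'   fragment mass sets.
#' @return A list with `composition_match` (logical), `fragment_fraction`
#'   (in `[0, 1]`) and `structure_match` (logical).
#' @export
glycan_match_levels <- function(denovo, target, digits = 3L) {
  frag_set <- function(tree) {
    y <- round(enumerate_y_fragments(tree, 0)$glycan_mass, digits)
    b <- round(enumerate_b_fragments(tree)$neutral_mass, digits)
    unique(c(y, b))
  }
  f_d <- frag_set(denovo)
  f_t <- frag_set(target)
  list(
    composition_match = identical(tree_composition(denovo),
                                  tree_composition(target)),
    fragment_fraction = length(intersect(f_d, f_t)) / length(f_t),
    structure_match = structure_equal(denovo, target)
  )
}
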