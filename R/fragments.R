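# Theoretical glycopeptide fragment enumeration.
#
# Glycosidic bonds cleave to give Y ions (peptide retaining a
# root-containing subtree of the glycan; Y0 = bare peptide) and B ions
# (the detached subtree, observed as an oxonium ion). Only single-cleavage
# B ions are enumerated: internal (doubly cleaved) glycan fragments are not
# modelled.

#' Enumerate theoretical Y fragments of a glycopeptide
#'
#' One entry per root-containing subtree obtainable by deleting any subset
#' of edges (deleting an edge removes the whole detached subtree), plus the
#' Y0 entry (bare peptide). Entries are deduplicated by retained node-set,
#' so two distinct subtrees with the same composition appear as separate
#' rows; collapse on `glycan_mass` for a theoretical peak list.
#'
#' @param tree Glycan tree root node.
#' @param peptide_mass Neutral peptide mass in Da (>= 0).
#' @return A data.frame with columns `composition` (string), `glycan_mass`
#'   (retained glycan mass, Da) and `neutral_mass`
#'   (`peptide_mass + glycan_mass`). The Y0 row has an empty composition.
#' @export
enumerate_y_fragments <- function(tree, peptide_mass = 0) {
  stopifnot(peptide_mass >= 0)
  # compositions of all root-containing subtrees of the subtree at `node`
  ysets <- function(node) {
    opts <- list(glycan_composition() + 0L)
    opts[[1L]][node$code] <- 1L
    for (ch in node$children) {
      ch_sets <- ysets(ch)
      new <- vector("list", length(opts) * (1L + length(ch_sets)))
      k <- 0L
      for (a in opts) {
        k <- k + 1L
        new[[k]] <- a                     # child subtree fully detached
        for (b in ch_sets) {
          k <- k + 1L
          new[[k]] <- a + b
        }
      }
      opts <- new
    }
    opts
  }
  comps <- c(list(glycan_composition()), ysets(tree))  # Y0 first
  gmass <- vapply(comps, composition_mass, numeric(1))
  data.frame(
    composition = vapply(comps, format_composition, character(1)),
    glycan_mass = gmass,
    neutral_mass = peptide_mass + gmass,
    stringsAsFactors = FALSE
  )
}

#' Enumerate theoretical B fragments of a glycan
#'
#' One entry per edge: the complete subtree below that edge, observed as a
#' (neutral) detached glycan. Entries are deduplicated by composition.
#'
#' @param tree Glycan tree root node.
#' @param include_intact Include the intact glycan (the whole tree, as the
#'   precursor oxonium) as an additional entry.
#' @return A data.frame with columns `composition` and `neutral_mass`
#'   (summed residue mass of the detached subtree, Da). The singly
#'   protonated oxonium m/z is `neutral_mass + PROTON_MASS`.
#' @export
enumerate_b_fragments <- function(tree, include_intact = FALSE) {
  comps <- list()
  walk <- function(node, is_root) {
    if (!is_root) comps[[length(comps) + 1L]] <<- tree_composition(node)
    for (ch in node$children) walk(ch, FALSE)
  }
  walk(tree, TRUE)
  if (include_intact) comps[[length(comps) + 1L]] <- tree_composition(tree)
  if (length(comps) == 0L) {
    return(data.frame(composition = character(0), neutral_mass = numeric(0),
                      n_residues = integer(0), stringsAsFactors = FALSE))
  }
  keys <- vapply(comps, format_composition, character(1))
  keep <- !duplicated(keys)
  comps <- comps[keep]
  data.frame(
    composition = keys[keep],
    neutral_mass = vapply(comps, composition_mass, numeric(1)),
    n_residues = vapply(comps, sum, integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Oxonium (B ion) m/z of a glycan composition
#'
#' @param comp Glycan composition (non-empty).
#' @param water_losses Number of water losses (0, 1 or 2).
#' @return Singly protonated oxonium m/z.
#' @examples
#' oxonium_mz(glycan_composition(HexNAc = 1))           # ~204.087
#' oxonium_mz(glycan_composition(HexNAc = 1), 1)        # ~186.076
#' @export
oxonium_mz <- function(comp, water_losses = 0L) {
  if (sum(comp) == 0L) stop("empty composition has no oxonium ion")
  if (!water_losses %in% 0:2) stop("water_losses must be 0, 1 or 2")
  composition_mass(comp) + PROTON_MASS - water_losses * WATER_MASS
}

# Deduplicated theoretical Y neutral masses (ascending), used by scorers.
y_fragment_masses <- function(tree, peptide_mass = 0) {
  yf <- enumerate_y_fragments(tree, peptide_mass)
  sort(unique(round(yf$neutral_mass, 6)))
}
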