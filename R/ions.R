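# Theoretical peptide-backbone and glycopeptide ion series.

# b/y (or c/z) prefix/suffix neutral masses of a modified peptide.
# Returns list(prefix, suffix) of cumulative neutral fragment masses for
# indices 1..n-1.
backbone_masses <- function(sequence, delta = NULL) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (is.null(delta)) delta <- numeric(length(aa))
  res <- AA_MASS[aa] + delta
  n <- length(res)
  cp <- cumsum(res)
  list(
    b = cp[-n],                                  # b_i neutral
    y = rev(cumsum(rev(res)))[-1L] + WATER_MASS  # y_i neutral, i = n-1..1
  )
}

#' Theoretical peptide-backbone fragment ions
#'
#' Generates the backbone series used for peptide scoring: b/y for HCD,
#' c/z for ETD, both for EThcD; plus ammonia/water losses, the glycan
#' stub series b/y + HexNAc, and charge 1-2 states.
#'
#' @param sequence Peptide sequence.
#' @param delta Optional per-residue modification delta vector.
#' @param fragmentation `"HCD"`, `"ETD"` or `"EThcD"`.
#' @param charges Charge states to emit (default 1:2).
#' @param losses Include -NH3 / -H2O loss series.
#' @param hexnac_stub Include b/y + HexNAc ions.
#' @return A data.frame with columns `ion` (label), `series`, `index`,
#'   `charge`, `mz`, `primary` (TRUE for the plain 1+ backbone series).
#' @export
peptide_ions <- function(sequence, delta = NULL,
                         fragmentation = "HCD", charges = 1:2,
                         losses = TRUE, hexnac_stub = TRUE) {
  bm <- backbone_masses(sequence, delta)
  n <- length(bm$b)
  if (n == 0L) {
    return(data.frame(ion = character(0), series = character(0),
                      index = integer(0), charge = integer(0),
                      mz = numeric(0), primary = logical(0)))
  }
  idx <- seq_len(n)
  series <- list()
  add <- function(name, neutral, primary = FALSE) {
    series[[length(series) + 1L]] <<- data.frame(
      series = name, index = idx, neutral = neutral, primary = primary,
      stringsAsFactors = FALSE)
  }
  # y_i indexes from the C terminus
  yi <- rev(bm$y)
  if (fragmentation %in% c("HCD", "EThcD")) {
    add("b", bm$b, primary = TRUE)
    add("y", yi, primary = TRUE)
    if (losses) {
      add("b-NH3", bm$b - AMMONIA_MASS)
      add("b-H2O", bm$b - WATER_MASS)
      add("y-NH3", yi - AMMONIA_MASS)
      add("y-H2O", yi - WATER_MASS)
    }
    if (hexnac_stub) {
      add("b+HexNAc", bm$b + MONO_MASS[["HexNAc"]])
      add("y+HexNAc", yi + MONO_MASS[["HexNAc"]])
    }
  }
  if (fragmentation %in% c("ETD", "EThcD")) {
    add("c", bm$b + AMMONIA_MASS, primary = TRUE)
    add("z", yi - AMMONIA_MASS + .ATOMIC[["H"]], primary = TRUE)
    if (hexnac_stub) {
      add("c+HexNAc", bm$b + AMMONIA_MASS + MONO_MASS[["HexNAc"]])
      add("z+HexNAc", yi - AMMONIA_MASS + .ATOMIC[["H"]] +
            MONO_MASS[["HexNAc"]])
    }
  }
  df <- do.call(rbind, series)
  out <- do.call(rbind, lapply(charges, function(z) {
    d <- df
    d$charge <- z
    d$mz <- mass_to_mz(d$neutral, z)
    d$primary <- d$primary & z == 1L
    d
  }))
  out$ion <- sprintf("%s%d^%d", out$series, out$index, out$charge)
  out$neutral <- NULL
  rownames(out) <- NULL
  out[, c("ion", "series", "index", "charge", "mz", "primary")]
}

#' Theoretical glycopeptide Y-ion m/z values
#'
#' Y ions are the peptide plus each root-containing subtree of the glycan
#' (deduplicated by mass), at the requested charge states.
#'
#' @param tree Glycan tree.
#' @param pep_mass Neutral peptide mass (Da).
#' @param charges Charge states (default 1:2).
#' @return A data.frame with columns `glycan_mass`, `charge`, `mz`.
#' @export
glycopeptide_y_ions <- function(tree, pep_mass, charges = 1:2) {
  gmass <- c(0, sort(unique(round(enumerate_y_fragments(tree, 0)$glycan_mass,
                                  6))))
  gmass <- unique(gmass)
  out <- do.call(rbind, lapply(charges, function(z) {
    data.frame(glycan_mass = gmass, charge = z,
               mz = mass_to_mz(pep_mass + gmass, z))
  }))
  rownames(out) <- NULL
  out
}

# Matches of a theoretical ion table against a spectrum.
# tol_da: absolute Da tolerance; tol_ppm: ppm tolerance (one of the two).
# Returns the table with obs_mz / intensity / rel_intensity columns and
# matched rows only.
match_ions <- function(theo_mz, s, tol_da = NULL, tol_ppm = NULL) {
  if (length(theo_mz) == 0L || length(s$mz) == 0L) {
    return(data.frame(theo_mz = numeric(0), peak = integer(0),
                      obs_mz = numeric(0), intensity = numeric(0),
                      rel_intensity = numeric(0)))
  }
  tol <- if (!is.null(tol_ppm)) ppm_tol(theo_mz, tol_ppm) else tol_da
  idx <- match_nearest(theo_mz, s$mz, tol)
  hit <- which(!is.na(idx))
  base <- if (length(s$intensity) > 0L) max(s$intensity) else 1
  data.frame(
    theo_mz = theo_mz[hit],
    peak = idx[hit],
    obs_mz = s$mz[idx[hit]],
    intensity = s$intensity[idx[hit]],
    rel_intensity = if (base > 0) s$intensity[idx[hit]] / base else 0
  )
}
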