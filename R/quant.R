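# Label-free glycopeptide quantification.
#
# A glycopeptide's abundance is the sum of the areas of its MS1 precursor
# features over charge states. Per glycosylation site, glycan areas are
# pooled over all carrier glycopeptides and normalised to fractions.

#' Read a precursor feature-area table
#'
#' Tab-separated with columns `sequence`, `glycan`, `site`, `charge`,
#' `area` (one row per precursor feature).
#'
#' @param path TSV file path.
#' @return A data.frame.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence", "glycan", "site", "charge", "area")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(df$area < 0)) stop("negative feature areas")
  df
}

#' Sum feature areas per glycopeptide
#'
#' @param features Data.frame with columns `sequence`, `glycan`, `site`,
#'   `charge`, `area`.
#' @return A data.frame with one row per (sequence, glycan, site) and the
#'   summed `area` across charge states; order-independent.
#' @export
glycopeptide_area <- function(features) {
  if (nrow(features) == 0L) {
    return(data.frame(sequence = character(0), glycan = character(0),
                      site = integer(0), area = numeric(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(features$sequence, features$glycan, features$site,
               sep = "\r")
  agg <- tapply(features$area, key, sum)
  agg <- agg[order(names(agg), method = "radix")]
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  data.frame(
    sequence = vapply(parts, `[`, character(1), 1L),
    glycan = vapply(parts, `[`, character(1), 2L),
    site = as.integer(vapply(parts, `[`, character(1), 3L)),
    area = unname(agg),
    stringsAsFactors = FALSE
  )
}

#' Per-site glycan profiles
#'
#' For each glycosylation site (protein, position), the area of each
#' glycan form is the sum over all glycopeptides carrying that glycan at
#' that site (e.g. missed-cleavage variants pool together); the profile is
#' those areas normalised to fractions.
#'
#' @param areas Data.frame from [glycopeptide_area()] with an additional
#'   `protein` column (or `site` already encoding protein+position).
#' @param identifications Optional data.frame of FDR-passing glycoPSMs
#'   with `sequence`, `glycan_composition` columns used to restrict the
#'   features to identified glycopeptides.
#' @return A data.frame with columns `site`, `glycan`, `area`,
#'   `fraction`; fractions sum to 1 per site. Sites whose total area is 0
#'   are dropped with a warning.
#' @export
site_profile <- function(areas, identifications = NULL) {
  if (!is.null(identifications)) {
    ok <- paste(areas$sequence, areas$glycan) %in%
      paste(identifications$sequence, identifications$glycan_composition)
    areas <- areas[ok, , drop = FALSE]
  }
  if (nrow(areas) == 0L) {
    return(data.frame(site = character(0), glycan = character(0),
                      area = numeric(0), fraction = numeric(0),
                      stringsAsFactors = FALSE))
  }
  site_key <- if ("protein" %in% names(areas)) {
    paste(areas$protein, areas$site, sep = ":")
  } else as.character(areas$site)
  key <- paste(site_key, areas$glycan, sep = "\r")
  agg <- tapply(areas$area, key, sum)
  agg <- agg[order(names(agg), method = "radix")]
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(
    site = vapply(parts, `[`, character(1), 1L),
    glycan = vapply(parts, `[`, character(1), 2L),
    area = unname(agg),
    stringsAsFactors = FALSE
  )
  totals <- tapply(out$area, out$site, sum)
  zero_sites <- names(totals)[totals <= 0]
  if (length(zero_sites) > 0L) {
    warning("site(s) with zero total area dropped: ",
            paste(zero_sites, collapse = ", "))
    out <- out[!out$site %in% zero_sites, , drop = FALSE]
  }
  out$fraction <- out$area / as.numeric(totals[out$site])
  rownames(out) <- NULL
  out
}

#' Extracted-ion-chromatogram area by trapezoidal integration
#'
#' Fallback when no feature table is available: integrates an MS1
#' intensity trace over time.
#'
#' @param time Numeric vector of time points (ascending).
#' @param intensity Non-negative intensities, same length.
#' @return The trapezoidal integral; 0 for fewer than two points.
#' @export
xic_area <- function(time, intensity) {
  stopifnot(length(time) == length(intensity))
  if (length(time) < 2L) return(0)
  ord <- order(time)
  time <- time[ord]
  intensity <- intensity[ord]
  sum(diff(time) * (head(intensity, -1L) + tail(intensity, -1L)) / 2)
}
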