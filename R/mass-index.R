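# Sorted mass index over peptides or glycan records.

#' Build a mass index
#'
#' @param masses Numeric vector of item masses (Da).
#' @param items Optional payload: a data.frame (row-aligned with `masses`)
#'   or a list of the same length.
#' @return A `mass_index` object supporting [query_mass_index()].
#' @export
build_mass_index <- function(masses, items = NULL) {
  stopifnot(is.numeric(masses), all(is.finite(masses)))
  ord <- order(masses)
  structure(list(masses = masses[ord], order = ord, items = items),
            class = "mass_index")
}

#' Query a mass index
#'
#' @param index A [build_mass_index()] object.
#' @param mass Query mass (Da).
#' @param tol Window half-width: Da when `unit = "da"`, ppm of `mass` when
#'   `unit = "ppm"`.
#' @param unit `"da"` or `"ppm"`.
#' @return Integer vector of original item positions (as supplied to
#'   `build_mass_index`) whose mass lies within `mass +/- tol`, in
#'   ascending mass order.
#' @export
query_mass_index <- function(index, mass, tol, unit = "da") {
  half <- if (unit[1L] == "ppm") ppm_tol(mass, tol) else tol
  lo <- mass - half
  hi <- mass + half
  i <- findInterval(lo, index$masses, left.open = TRUE) + 1L
  j <- findInterval(hi, index$masses)
  if (i > j) return(integer(0))
  index$order[i:j]
}

#' @export
print.mass_index <- function(x, ...) {
  cat(sprintf("<mass_index> %d items, %.4f..%.4f Da\n", length(x$masses),
              if (length(x$masses)) min(x$masses) else NA,
              if (length(x$masses)) max(x$masses) else NA))
  invisible(x)
}
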