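# Small internal helpers.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from a base seed and a stream index (kept < 2^31).
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 2246822519) %%
               2147483647)
}

# For each value in `theo`, index of the nearest element of the sorted
# vector `mz` (NA if none within `tol`). `tol` may be a scalar (Da) or a
# vector the length of `theo` (for ppm tolerances).
match_nearest <- function(theo, mz, tol) {
  if (length(mz) == 0L || length(theo) == 0L) {
    return(rep(NA_integer_, length(theo)))
  }
  idx <- findInterval(theo, mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(mz))
  d_lo <- abs(theo - mz[lo])
  d_hi <- abs(theo - mz[hi])
  best <- ifelse(d_lo <= d_hi, lo, hi)
  d <- pmin(d_lo, d_hi)
  ifelse(d <= tol, best, NA_integer_)
}

# ppm window half-width in Da at a given mass
ppm_tol <- function(mass, ppm) mass * ppm * 1e-6
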