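# Independent brute-force oracles used by the tests. These deliberately
# avoid the package's search-path code: trees are enumerated exhaustively
# and scored as complete objects.

# All distinct rooted trees (up to sibling order) realising a composition,
# with out-degree capped at `max_out_degree`. Forests are generated in
# canonical (non-decreasing key) child order so every multiset of subtrees
# is produced exactly once.
enumerate_trees <- function(comp, max_out_degree = 4L) {
  memo_t <- new.env(parent = emptyenv())
  memo_f <- new.env(parent = emptyenv())
  memo_s <- new.env(parent = emptyenv())
  comp_key <- function(cc) paste(cc, collapse = ",")

  subcomps <- function(cc) {
    key <- comp_key(cc)
    hit <- memo_s[[key]]
    if (!is.null(hit)) return(hit)
    grid <- expand.grid(lapply(cc, function(k) 0:k))
    out <- list()
    for (i in seq_len(nrow(grid))) {
      v <- as.integer(grid[i, ])
      names(v) <- names(cc)
      if (sum(v) > 0L) out[[length(out) + 1L]] <- v
    }
    memo_s[[key]] <- out
    out
  }

  trees <- function(cc) {
    key <- comp_key(cc)
    hit <- memo_t[[key]]
    if (!is.null(hit)) return(hit)
    out <- list()
    for (r in names(cc)[cc > 0L]) {
      rest <- cc
      rest[r] <- rest[r] - 1L
      for (f in forests(rest, "")) {
        out[[length(out) + 1L]] <- glycoscout::glycan_node(r, f)
      }
    }
    memo_t[[key]] <- out
    out
  }

  forests <- function(cc, min_key) {
    if (sum(cc) == 0L) return(list(list()))
    key <- paste(comp_key(cc), min_key)
    hit <- memo_f[[key]]
    if (!is.null(hit)) return(hit)
    out <- list()
    for (sub in subcomps(cc)) {
      for (t in trees(sub)) {
        k <- glycoscout::canonical_key(t)
        if (k < min_key) next
        for (f in forests(cc - sub, k)) {
          if (length(f) + 1L > max_out_degree) next
          out[[length(out) + 1L]] <- c(list(t), f)
        }
      }
    }
    memo_f[[key]] <- out
    out
  }

  trees(comp[glycoscout::MONO_CODES])
}

# Oracle ranking: enumerate all trees of the composition and score each
# complete tree with the supplied scorer; returns keys sorted by
# (score desc, key).
oracle_rank_trees <- function(s, peptide_mass, comp,
                              scorer = function(tree)
                                glycoscout::fragment_match_score(
                                  tree, s, peptide_mass)) {
  all_trees <- enumerate_trees(comp)
  if (length(all_trees) == 0L) {
    return(data.frame(key = character(0), score = numeric(0)))
  }
  keys <- vapply(all_trees, glycoscout::canonical_key, character(1))
  scores <- vapply(all_trees, scorer, numeric(1))
  ord <- order(-scores, keys, method = "radix")
  data.frame(key = keys[ord], score = scores[ord],
             stringsAsFactors = FALSE)
}

# TRUE iff the tree's deduplicated Y fragment mass set is unique among all
# same-composition topologies.
y_set_unique <- function(tree) {
  comp <- glycoscout::tree_composition(tree)
  yset <- function(t) paste(
    sort(round(glycoscout::enumerate_y_fragments(t, 0)$glycan_mass, 4)),
    collapse = ",")
  target <- yset(tree)
  others <- enumerate_trees(comp)
  keys <- vapply(others, glycoscout::canonical_key, character(1))
  me <- glycoscout::canonical_key(tree)
  !any(vapply(others[keys != me], function(t)
    identical(yset(t), target), logical(1)))
}

# Brute-force oracle for the composition dynamic program: enumerate every
# residue multiset whose lattice mass can reach the final bins, then every
# distinct ordering of it, tracking all +/-1-bin slack choices with a tiny
# per-ordering position table. Returns the best cumulative intensity (and
# its compositions); mirrors the DP's binning exactly but shares none of
# its code path.
oracle_dp_best <- function(s, peptide_mass, precursor_mass, tol = 0.01,
                           max_residues = 10L) {
  L <- as.integer(round((precursor_mass - peptide_mass) / tol))
  intensity <- numeric(L + 1L)
  m <- as.integer(round((glycoscout::mz_to_mass(s$mz, 1L) - peptide_mass) /
                          tol))
  ok <- which(m >= 0L & m <= L)
  for (i in ok) intensity[m[i] + 1L] <- intensity[m[i] + 1L] + s$intensity[i]
  offs <- as.integer(round(glycoscout::MONO_MASS / tol))

  # candidate multisets: counts whose lattice mass is within n+1 bins of L
  comps <- list()
  grid_max <- pmin(L %/% offs, max_residues)
  cand <- expand.grid(lapply(grid_max, function(k) 0:k))
  for (i in seq_len(nrow(cand))) {
    v <- as.integer(cand[i, ])
    n <- sum(v)
    if (n == 0L || n > max_residues) next
    if (abs(sum(v * offs) - L) <= n + 1L) {
      names(v) <- names(offs)
      comps[[length(comps) + 1L]] <- v
    }
  }

  perms <- function(counts) {
    if (sum(counts) == 0L) return(list(integer(0)))
    out <- list()
    for (r in which(counts > 0L)) {
      rest <- counts
      rest[r] <- rest[r] - 1L
      for (p in perms(rest)) out[[length(out) + 1L]] <- c(r, p)
    }
    out
  }

  best <- -Inf
  best_comps <- list()
  for (v in comps) {
    for (p in perms(v)) {
      # positions reachable after each step under +/-1 slack
      pos <- 0L
      val <- stats::setNames(0, "0")
      for (r in p) {
        nxt <- new.env(parent = emptyenv())
        for (b in names(val)) {
          for (d in -1:1) {
            q <- as.integer(b) + offs[r] + d
            if (q < 0L || q > L) next
            vv <- val[[b]] + intensity[q + 1L]
            kq <- as.character(q)
            if (is.null(nxt[[kq]]) || nxt[[kq]] < vv) nxt[[kq]] <- vv
          }
        }
        val <- stats::setNames(
          vapply(ls(nxt), function(k) nxt[[k]], numeric(1)), ls(nxt))
        if (length(val) == 0L) break
      }
      if (length(val) == 0L) next
      finals <- names(val)[as.integer(names(val)) %in% c(L - 1L, L)]
      if (length(finals) == 0L) next
      v_best <- max(unlist(val[finals]))
      if (v_best > best + 1e-9) {
        best <- v_best
        best_comps <- list(v)
      } else if (abs(v_best - best) <= 1e-9) {
        best_comps <- c(best_comps, list(v))
      }
    }
  }
  list(best = best, comps = unique(best_comps))
}
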