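# De novo glycan sequencing.
#
# Two steps: (1) a dynamic program over the glycan-mass interval infers the
# monosaccharide composition from potential Y-ion peaks above the peptide
# mass; (2) a beam search grows the glycan tree from the peptide
# attachment point, one extension candidate (a multiset of 1-2 residues,
# or a termination token) per open node, scored by fragment-ion evidence.
# The scorer is pluggable: a trained structure-aware model with the same
# signature can replace the fragment-evidence default.

#' Infer a glycan composition by dynamic programming
#'
#' The glycan-mass interval `[0, precursor - peptide]` is discretised into
#' bins of width `tol`. Each bin accumulates the intensity of peaks whose
#' neutral mass minus the peptide mass falls into it; transitions step by
#' one monosaccharide residue mass (+/- one bin to absorb rounding drift).
#' The table is filled left to right and the maximum-intensity path is
#' traced back from the final bin; the residues on that path are the
#' composition. Bins with no peak stay traversable at zero reward, so
#' compositions can bridge Y-ion gaps.
#'
#' @param s A [spectrum()].
#' @param peptide_mass Neutral peptide mass (Da).
#' @param precursor_mass Neutral precursor mass (Da); must exceed
#'   `peptide_mass` unless the glycan mass is 0.
#' @param tol Bin width / tolerance in Da (default 0.01).
#' @param charges Fragment charge states assumed when converting peaks to
#'   neutral masses (default 1).
#' @return A list with `composition` (named count vector), `intensity`
#'   (cumulative path intensity), `residues` (path order, root first), or
#'   `NULL` if the final bin is unreachable.
#' @export
dp_composition <- function(s, peptide_mass, precursor_mass, tol = 0.01,
                           charges = 1L) {
  glycan_mass <- precursor_mass - peptide_mass
  if (glycan_mass < min(MONO_MASS) - tol) {
    if (glycan_mass < tol) {
      return(list(composition = glycan_composition(), intensity = 0,
                  residues = character(0)))
    }
    return(NULL)
  }
  L <- as.integer(round(glycan_mass / tol))
  intensity <- numeric(L + 1L)
  for (z in charges) {
    neutral <- mz_to_mass(s$mz, z)
    m <- as.integer(round((neutral - peptide_mass) / tol))
    ok <- which(m >= 0L & m <= L)
    for (i in ok) {
      intensity[m[i] + 1L] <- intensity[m[i] + 1L] + s$intensity[i]
    }
  }
  base <- as.integer(round(MONO_MASS / tol))
  steps <- as.integer(outer(base, -1:1, `+`))
  res_id <- rep(seq_along(MONO_CODES), 3L)
  fill <- dp_fill_cpp(intensity, steps, res_id)
  finals <- unique(pmax(pmin(c(L, L - 1L), L), 0L))
  finals <- finals[fill$T[finals + 1L] > -Inf]
  if (length(finals) == 0L) return(NULL)
  final <- finals[order(-fill$T[finals + 1L], abs(finals - L))][1L]
  path <- character(0)
  m <- final
  while (m > 0L) {
    path <- c(MONO_CODES[fill$back_res[m + 1L]], path)
    m <- fill$back_bin[m + 1L]
  }
  comp <- glycan_composition()
  for (r in path) comp[r] <- comp[r] + 1L
  list(composition = comp, intensity = fill$T[final + 1L],
       residues = path)
}

#' The 21 extension candidates
#'
#' All 20 non-empty multisets of size at most 2 over the five
#' monosaccharide classes (5 singletons + 15 unordered pairs), plus the
#' termination token that closes the current open node. Ordering is
#' stable.
#'
#' @return A list of 21 candidates; each is `list(type = "extend",
#'   codes = <character>)` or `list(type = "end")`.
#' @export
candidate_set <- function() {
  out <- lapply(MONO_CODES, function(c1) list(type = "extend", codes = c1))
  for (i in seq_along(MONO_CODES)) {
    for (j in i:length(MONO_CODES)) {
      out[[length(out) + 1L]] <- list(
        type = "extend", codes = c(MONO_CODES[i], MONO_CODES[j]))
    }
  }
  out[[length(out) + 1L]] <- list(type = "end")
  out
}

# --- beam state -------------------------------------------------------------
# A partial tree under construction:
#   nodes     list of list(code, parent, children = integer ids)
#   queue     open node ids in breadth-first order; queue[1] is the
#             frontier; id 0 is the peptide attachment point
#   remaining composition still to place
new_beam_state <- function(comp) {
  list(nodes = list(), queue = 0L, remaining = comp, score = 0)
}

beam_state_complete <- function(state) {
  length(state$queue) == 0L && all(state$remaining == 0L)
}

#' Apply one extension candidate to a beam state
#'
#' An `"extend"` candidate attaches its residues as children of the
#' frontier node (a size-2 multiset creates a branch); the node stays open
#' for further candidates until the termination token closes it and the
#' frontier advances in breadth-first order. The peptide attachment point
#' accepts exactly one single residue (the glycan root) and closes
#' immediately. Candidates that exceed the remaining composition or the
#' out-degree cap are rejected.
#'
#' @param state A beam state (see [beam_search()]).
#' @param cand One element of [candidate_set()].
#' @param max_out_degree Maximum children per node (default 4).
#' @return The extended state, or `NULL` if the candidate is invalid here.
#' @export
extend <- function(state, cand, max_out_degree = 4L) {
  if (length(state$queue) == 0L) return(NULL)
  head_id <- state$queue[1L]
  if (cand$type == "end") {
    if (head_id == 0L) return(NULL)   # the attachment point needs a root
    state$queue <- state$queue[-1L]
    return(state)
  }
  codes <- sort(cand$codes, method = "radix")
  need <- glycan_composition()
  for (cd in codes) need[cd] <- need[cd] + 1L
  if (any(need > state$remaining)) return(NULL)
  if (head_id == 0L) {
    if (length(codes) != 1L) return(NULL)     # single glycan root
    state$nodes[[1L]] <- list(code = codes, parent = 0L,
                              children = integer(0))
    state$queue <- c(state$queue[-1L], 1L)    # peptide closes itself
  } else {
    node <- state$nodes[[head_id]]
    if (length(node$children) + length(codes) > max_out_degree) {
      return(NULL)
    }
    for (cd in codes) {
      id <- length(state$nodes) + 1L
      state$nodes[[id]] <- list(code = cd, parent = head_id,
                                children = integer(0))
      node$children <- c(node$children, id)
      state$queue <- c(state$queue, id)
    }
    state$nodes[[head_id]] <- node
  }
  state$remaining <- state$remaining - need
  state
}

# Nested tree from a beam state (NULL while no root is placed).
beam_state_tree <- function(state) {
  if (length(state$nodes) == 0L) return(NULL)
  build <- function(id) {
    node <- state$nodes[[id]]
    glycan_node(node$code, lapply(node$children, build))
  }
  build(1L)
}

#' Fragment-evidence score of a (partial) glycan tree
#'
#' Builds the theoretical Y masses of the partial tree anchored at the
#' peptide mass (plus the B masses of its multi-residue subtrees) and
#' scores each theoretical ion by the best observed peak under the
#' exponential mass-gap activation `exp(-|delta m/z| * c)`, weighted by
#' `(1 + relative intensity) / 2`; contributions are summed and each
#' theoretical ion with no supporting peak subtracts a small miss penalty.
#' The weight is bounded below by 1/2 so that a genuinely observed
#' low-intensity fragment always adds evidence, and the miss penalty
#' breaks the systematic tie between a topology and any rival that
#' predicts a superset of its observed fragment masses: candidate
#' topologies are separated primarily by which fragment masses they
#' predict, with peak intensity modulating the contribution by at most a
#' factor of two.
#'
#' @param tree Glycan tree (or `NULL` for the bare peptide).
#' @param s A [spectrum()].
#' @param peptide_mass Neutral peptide mass (Da).
#' @param c Decay constant of the activation per Da of mass gap
#'   (default 100).
#' @param use_b Include B-ion masses.
#' @param miss_penalty Score subtracted per theoretical ion without a
#'   supporting peak (default 0.1).
#' @return Score (can be slightly negative for heavily unsupported
#'   topologies).
#' @export
fragment_match_score <- function(tree, s, peptide_mass, c = 100,
                                 use_b = TRUE, miss_penalty = 0.1) {
  stopifnot(c > 0)
  theo <- round(mass_to_mz(peptide_mass, 1L), 6)
  if (!is.null(tree)) {
    theo <- c(theo, round(mass_to_mz(y_fragment_masses(tree, peptide_mass),
                                     1L), 6))
    if (use_b) {
      # oxonium ions at the ubiquitous signature masses (single residues,
      # Hex+HexNAc, water losses) are emitted by essentially any glycan
      # and carry no topology information: exclude them
      b <- enumerate_b_fragments(tree, include_intact = TRUE)
      bmz <- b$neutral_mass[b$n_residues >= 2L] + PROTON_MASS
      sig <- signature_ions()$mz
      near_sig <- vapply(bmz, function(x) any(abs(x - sig) < 0.05),
                         logical(1))
      theo <- c(theo, round(bmz[!near_sig], 6))
    }
    theo <- unique(theo)
  }
  if (length(s$mz) == 0L) return(0)
  base <- max(s$intensity)
  if (base <= 0) base <- 1
  window <- 20 / c   # beyond this the activation is below ~2e-9
  total <- 0
  lo <- findInterval(theo - window, s$mz) + 1L
  hi <- findInterval(theo + window, s$mz)
  for (i in seq_along(theo)) {
    contrib <- 0
    if (lo[i] <= hi[i]) {
      j <- lo[i]:hi[i]
      contrib <- max((1 + s$intensity[j] / base) / 2 *
                       exp(-abs(s$mz[j] - theo[i]) * c))
    }
    total <- total + if (contrib >= 0.05) contrib else -miss_penalty
  }
  total
}

#' Beam search for the glycan tree of a composition
#'
#' Iteratively applies the 21 extension candidates to every state in the
#' beam, scores the resulting partial trees, and keeps the top
#' `beam_width`. Only complete trees using exactly the given composition
#' are emitted. Deterministic: ties are broken by canonical key.
#'
#' @param s A [spectrum()].
#' @param peptide_mass Neutral peptide mass (Da).
#' @param comp Glycan composition (from [dp_composition()]).
#' @param beam_width Number of states kept per iteration (use `Inf` for an
#'   exhaustive search).
#' @param scorer Function `(tree, spectrum, peptide_mass) -> numeric`;
#'   defaults to [fragment_match_score()]. A trained structure-aware model
#'   satisfying the same contract may be plugged in.
#' @param max_out_degree Maximum children per node.
#' @return A data.frame of complete trees ranked by score (`key`, `score`)
#'   with the trees in `attr(, "trees")` (named by key); zero rows if the
#'   composition cannot be completed.
#' @export
beam_search <- function(s, peptide_mass, comp, beam_width = 5L,
                        scorer = NULL, max_out_degree = 4L) {
  stopifnot(beam_width >= 1L)
  if (is.null(scorer)) {
    scorer <- function(tree, s, peptide_mass) {
      fragment_match_score(tree, s, peptide_mass)
    }
  }
  cands <- candidate_set()
  attach_cands <- Filter(function(cand) cand$type == "extend", cands)
  end_token <- list(type = "end")
  states <- list(new_beam_state(comp))
  done <- list()
  done_keys <- character(0)
  max_iter <- sum(comp) + 1L
  iter <- 0L
  # the score depends only on the partial tree, so cache it by key
  score_cache <- new.env(parent = emptyenv())
  scored <- function(tree, key) {
    hit <- score_cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- scorer(tree, s, peptide_mass)
    score_cache[[key]] <- val
    val
  }
  # one beam iteration = one group attachment, so states stay synchronized
  # by residue count; termination events are replayed implicitly, i.e. a
  # group may be attached at any open node reachable by closing the nodes
  # before it in breadth-first order
  while (length(states) > 0L && iter < max_iter) {
    iter <- iter + 1L
    nxt <- list()
    sigs <- character(0)
    for (st in states) {
      cur <- st
      repeat {
        for (cand in attach_cands) {
          st2 <- extend(cur, cand, max_out_degree)
          if (is.null(st2)) next
          tree <- beam_state_tree(st2)
          key <- canonical_key(tree)
          sig <- paste(key, paste(st2$queue, collapse = "."),
                       paste(st2$remaining, collapse = "."))
          if (sig %in% sigs) next   # same partial tree + frontier
          sigs <- c(sigs, sig)
          st2$score <- scored(tree, key)
          st2$sig <- sig
          nxt <- c(nxt, list(st2))
        }
        cur <- extend(cur, end_token, max_out_degree)
        if (is.null(cur) || length(cur$queue) == 0L) break
      }
      if (all(st$remaining == 0L) && length(st$nodes) > 0L) {
        # everything placed: closing all open nodes completes the tree
        tree <- beam_state_tree(st)
        key <- canonical_key(tree)
        if (!key %in% done_keys) {
          done_keys <- c(done_keys, key)
          done[[length(done) + 1L]] <- list(key = key,
                                            score = scored(tree, key),
                                            tree = tree)
        }
      }
    }
    if (length(nxt) == 0L) break
    ord <- order(-vapply(nxt, `[[`, numeric(1), "score"),
                 vapply(nxt, `[[`, character(1), "sig"),
                 method = "radix")
    nxt <- nxt[ord]
    if (is.finite(beam_width)) {
      # prune to beam_width distinct partial trees per residue count:
      # size-2 groups advance twice as fast as single residues, and an
      # unstratified beam would let those paths starve the serial ones;
      # states sharing a partial tree (frontier bookkeeping variants)
      # ride along with their tree's slot
      keys <- vapply(nxt, function(st) sub(" .*$", "", st$sig),
                     character(1))
      size <- vapply(nxt, function(st) length(st$nodes), integer(1))
      keep <- logical(length(nxt))
      for (sz in unique(size)) {
        at <- which(size == sz)
        rank <- match(keys[at], unique(keys[at]))
        # a tree's slot admits at most 8 frontier-bookkeeping variants,
        # otherwise closure permutations of large trees explode
        variant <- stats::ave(seq_along(at), keys[at],
                              FUN = seq_along)
        keep[at[rank <= beam_width & variant <= 8L]] <- TRUE
      }
      nxt <- nxt[keep]
    }
    states <- nxt
  }
  if (length(done) == 0L) {
    out <- data.frame(key = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "trees") <- list()
    return(out)
  }
  keys <- vapply(done, `[[`, character(1), "key")
  scores <- vapply(done, `[[`, numeric(1), "score")
  trees <- lapply(done, `[[`, "tree")
  ord <- order(-scores, keys, method = "radix")
  out <- data.frame(key = keys[ord], score = scores[ord],
                    stringsAsFactors = FALSE)
  attr(out, "trees") <- setNames(trees[ord], keys[ord])
  out
}

# Convenience wrapper used by the search workflow: DP composition then
# beam search; returns list(tree, key, score, composition) or NULL.
denovo_glycan <- function(s, peptide_mass, precursor_mass, cfg) {
  dp <- dp_composition(s, peptide_mass, precursor_mass, tol = cfg$dp_tol)
  if (is.null(dp) || sum(dp$composition) == 0L) return(NULL)
  max_res <- if (is.null(cfg$max_denovo_residues)) 16L else
    cfg$max_denovo_residues
  if (sum(dp$composition) > max_res) return(NULL)
  ranked <- beam_search(s, peptide_mass, dp$composition,
                        beam_width = cfg$beam_width)
  if (nrow(ranked) == 0L) return(NULL)
  list(tree = attr(ranked, "trees")[[1L]], key = ranked$key[1L],
       score = ranked$score[1L], composition = dp$composition)
}

#' Reverse-construction training pairs of a glycan tree
#'
#' Produces the deterministic sequence of (partial tree, candidate) pairs
#' whose forward replay through [extend()] rebuilds the canonical form of
#' the tree: leaves are conceptually removed group-wise from the last
#' attachment back to the root, i.e. the reverse of the construction
#' order. Children of each node are sorted by canonical key and chunked
#' into groups of two (remainder one); each node's attachment groups are
#' followed by its termination token.
#'
#' @param tree A glycan tree.
#' @return A list of `list(partial_key, candidate)` pairs, where
#'   `partial_key` is the canonical key of the partial tree (or `""` at
#'   the attachment point) before the candidate is applied.
#' @export
training_pairs <- function(tree) {
  # canonicalize: sort children recursively by canonical key
  canon <- function(node) {
    if (length(node$children) == 0L) return(node)
    kids <- lapply(node$children, canon)
    ord <- order(vapply(kids, canonical_key, character(1)),
                 method = "radix")
    node$children <- kids[ord]
    node
  }
  tree <- canon(tree)
  # breadth-first node order over the canonical tree
  events <- list(list(type = "extend", codes = tree$code))
  bfs <- list(tree)
  i <- 1L
  while (i <= length(bfs)) {
    node <- bfs[[i]]
    kids <- node$children
    k <- 1L
    while (k <= length(kids)) {
      grp <- kids[k:min(k + 1L, length(kids))]
      events[[length(events) + 1L]] <- list(
        type = "extend",
        codes = sort(vapply(grp, `[[`, character(1), "code"),
                     method = "radix"))
      k <- k + 2L
    }
    events[[length(events) + 1L]] <- list(type = "end")
    bfs <- c(bfs, kids)
    i <- i + 1L
  }
  # replay to capture the partial tree before each event
  state <- new_beam_state(tree_composition(tree))
  pairs <- vector("list", length(events))
  for (e in seq_along(events)) {
    partial <- beam_state_tree(state)
    pairs[[e]] <- list(
      partial_key = if (is.null(partial)) "" else canonical_key(partial),
      candidate = events[[e]])
    state <- extend(state, events[[e]], max_out_degree = Inf)
    if (is.null(state)) stop("internal error: replay rejected an event")
  }
  if (!beam_state_complete(state) ||
      !structure_equal(beam_state_tree(state), tree)) {
    stop("internal error: replay did not rebuild the tree")
  }
  pairs
}

#' Second-round database search with de novo glycans
#'
#' Appends the de novo glycan trees of a finished search to the glycan
#' database (deduplicated by canonical key) and re-runs the full database
#' search with FDR control, reporting the gain.
#'
#' @param result A [search_dataset()] result containing `denovo_trees`.
#' @param spectra,proteins,glycan_records,cfg,seed As for
#'   [search_dataset()] (the same inputs as the first round).
#' @return A list: `result` (the second-round `glyco_search_result`),
#'   `added` (the appended [glycan_record()]s), `n_new_psms` and
#'   `n_new_glycans` (gain in FDR-passing PSMs / distinct glycan keys over
#'   the first round).
#' @export
second_round_rescue <- function(result, spectra, proteins, glycan_records,
                                cfg = search_config(), seed = 1L) {
  known <- vapply(glycan_records, `[[`, character(1), "key")
  # only de novo glycans identified on target spectra at the FDR filter
  # are promoted into the database (decoy-spectrum de novo products are a
  # by-product of the identical decoy search path, not identifications)
  ok_ids <- result$psms$glycan_id[result$psms$denovo &
                                    result$psms$passes_fdr &
                                    !result$psms$is_decoy_spectrum]
  added <- list()
  for (nm in intersect(names(result$denovo_trees), ok_ids)) {
    tree <- result$denovo_trees[[nm]]
    key <- canonical_key(tree)
    if (key %in% known) next
    known <- c(known, key)
    added[[length(added) + 1L]] <- glycan_record(
      tree, id = paste0("denovo_", length(added) + 1L),
      link_type = cfg$mode)
  }
  second <- search_dataset(spectra, proteins, c(glycan_records, added),
                           cfg, seed)
  pass1 <- result$psms[result$psms$passes_fdr, , drop = FALSE]
  pass2 <- second$psms[second$psms$passes_fdr, , drop = FALSE]
  list(
    result = second,
    added = added,
    n_new_psms = nrow(pass2) - nrow(pass1),
    n_new_glycans = length(setdiff(unique(pass2$glycan_key),
                                   unique(pass1$glycan_key)))
  )
}
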