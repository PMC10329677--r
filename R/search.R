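# The three-stage identification workflow: peptide-based search,
# glycan-based search, and second-round rescoring, orchestrated over a
# whole dataset with two-level FDR control and optional de novo rescue.

#' Search configuration
#'
#' Defaults follow common practice for HCD glycopeptide searches:
#' 10 ppm precursor tolerance, 0.05 Da fragment tolerance for backbone
#' ions, 20 ppm for glycan (Y/B) ions, 1% FDR at both levels.
#'
#' @param mode `"N"` or `"O"` glycosylation.
#' @param precursor_tol_ppm Precursor tolerance (ppm).
#' @param fragment_tol Backbone fragment tolerance (Da).
#' @param glycan_tol_ppm Glycan fragment tolerance (ppm).
#' @param fdr Joint FDR filter level for both peptide and glycan levels.
#' @param min_peptide_score Minimum peptide score for a stage to count as
#'   "identified" (the stage fall-through criterion).
#' @param min_glycan_score Minimum glycan score for glycan-based-search
#'   candidates.
#' @param glycan_weight Weight of the glycan score in the combined ranking
#'   score.
#' @param max_o_glycans Maximum O-glycans per peptide (at most 2).
#' @param denovo Attempt de novo glycan sequencing for confident peptides
#'   without a database glycan (N mode only).
#' @param beam_width Beam width for de novo tree construction.
#' @param dp_tol Bin width / tolerance of the composition dynamic program
#'   (Da).
#' @param max_denovo_residues Upper bound on the residue count attempted
#'   by de novo sequencing (runtime guard).
#' @param enzyme An [enzyme_spec()].
#' @param mods A [mod_spec()].
#' @param triage_tol Tolerance (Da) for signature-ion/ladder triage.
#' @return A `search_config` list.
#' @export
search_config <- function(mode = c("N", "O"), precursor_tol_ppm = 10,
                          fragment_tol = 0.05, glycan_tol_ppm = 20,
                          fdr = 0.01, min_peptide_score = 1,
                          min_glycan_score = 0.1, glycan_weight = 10,
                          max_o_glycans = 2L, denovo = TRUE,
                          beam_width = 5L, dp_tol = 0.01,
                          max_denovo_residues = 16L,
                          enzyme = enzyme_spec(), mods = mod_spec(),
                          triage_tol = 0.02) {
  mode <- match.arg(mode)
  stopifnot(precursor_tol_ppm > 0, fragment_tol > 0, glycan_tol_ppm > 0,
            fdr > 0, fdr <= 1, max_o_glycans <= 2L, beam_width >= 1L,
            dp_tol > 0)
  structure(list(
    mode = mode, precursor_tol_ppm = precursor_tol_ppm,
    fragment_tol = fragment_tol, glycan_tol_ppm = glycan_tol_ppm,
    fdr = fdr, min_peptide_score = min_peptide_score,
    min_glycan_score = min_glycan_score, glycan_weight = glycan_weight,
    max_o_glycans = as.integer(max_o_glycans), denovo = denovo,
    beam_width = as.integer(beam_width), dp_tol = dp_tol,
    max_denovo_residues = as.integer(max_denovo_residues),
    enzyme = enzyme, mods = mods, triage_tol = triage_tol
  ), class = "search_config")
}

# cached full theoretical backbone ion table per (sequence, mods, scheme)
ion_cache_seq <- function(cache, sequence, mods, fragmentation) {
  key <- paste(sequence, mods, fragmentation)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  ions <- peptide_ions(sequence, decode_mods(sequence, mods),
                       fragmentation = fragmentation)
  cache[[key]] <- ions
  ions
}

ion_cache_get <- function(cache, peptides, row, fragmentation) {
  ion_cache_seq(cache, peptides$sequence[row], peptides$mods[row],
                fragmentation)
}

empty_candidates <- function() {
  data.frame(
    spectrum_id = character(0), stage = character(0),
    sequence = character(0), mods = character(0), pep_mass = numeric(0),
    proteins = character(0), is_decoy_peptide = logical(0),
    glycan_id = character(0), glycan_key = character(0),
    glycan_composition = character(0), glycan_mass = numeric(0),
    site = integer(0), peptide_score = numeric(0),
    glycan_score = numeric(0), total_score = numeric(0),
    is_decoy_spectrum = logical(0), denovo = logical(0),
    stringsAsFactors = FALSE
  )
}

# Score dispatch over registry entries: a plain tree, or an O-glycan pair
# (list(pair = TRUE, a = <tree>, b = <tree>)). A pair is scored by cleaving
# one glycan while the other stays intact on the peptide.
score_glycan_entry <- function(s, pep_mass, entry, cfg) {
  if (is.null(entry)) return(0)
  if (!is.null(entry$pair)) {
    (glycan_score(s, pep_mass + entry$b$mass, NULL, cfg, frags = entry$a) +
       glycan_score(s, pep_mass + entry$a$mass, NULL, cfg,
                    frags = entry$b)) / 2
  } else {
    glycan_score(s, pep_mass, NULL, cfg, frags = entry)
  }
}

# one candidate as a plain list; data.frame conversion happens once per
# spectrum in rows_to_candidates() (cheap hot path)
candidate_row <- function(s, stage, peptides, prow, rec, pscore, gscore,
                          cfg) {
  list(
    spectrum_id = s$id, stage = stage,
    sequence = peptides$sequence[prow], mods = peptides$mods[prow],
    pep_mass = peptides$mass[prow], proteins = peptides$proteins[prow],
    is_decoy_peptide = peptides$is_decoy[prow],
    glycan_id = if (is.null(rec)) NA_character_ else rec$id,
    glycan_key = if (is.null(rec)) NA_character_ else rec$key,
    glycan_composition = if (is.null(rec)) NA_character_ else
      format_composition(rec$composition),
    glycan_mass = if (is.null(rec)) NA_real_ else rec$mass,
    site = as.integer(strsplit(peptides$glyco_sites[prow],
                               ",", fixed = TRUE)[[1L]][1L]),
    peptide_score = pscore,
    glycan_score = gscore,
    total_score = pscore + cfg$glycan_weight * gscore,
    is_decoy_spectrum = isTRUE(s$is_decoy),
    denovo = FALSE
  )
}

rows_to_candidates <- function(rows) {
  if (length(rows) == 0L) return(empty_candidates())
  col <- function(f, proto) vapply(rows, `[[`, proto, f)
  df <- data.frame(
    spectrum_id = col("spectrum_id", character(1)),
    stage = col("stage", character(1)),
    sequence = col("sequence", character(1)),
    mods = col("mods", character(1)),
    pep_mass = col("pep_mass", numeric(1)),
    proteins = col("proteins", character(1)),
    is_decoy_peptide = col("is_decoy_peptide", logical(1)),
    glycan_id = col("glycan_id", character(1)),
    glycan_key = col("glycan_key", character(1)),
    glycan_composition = col("glycan_composition", character(1)),
    glycan_mass = col("glycan_mass", numeric(1)),
    site = col("site", integer(1)),
    peptide_score = col("peptide_score", numeric(1)),
    glycan_score = col("glycan_score", numeric(1)),
    total_score = col("total_score", numeric(1)),
    is_decoy_spectrum = col("is_decoy_spectrum", logical(1)),
    denovo = col("denovo", logical(1)),
    stringsAsFactors = FALSE
  )
  df
}

#' Peptide-based search of one glycopeptide spectrum
#'
#' Strips putative glycan peaks, scores candidate peptides on backbone
#' ions at the lower end of the spectrum (below peptide mass + 2 HexNAc),
#' then fetches glycans whose mass matches the precursor minus the peptide
#' mass and scores them on Y/B ions.
#'
#' @param s A [spectrum()] classified as glyco.
#' @param peptides Glyco-peptide candidate table
#'   ([build_peptide_table()]).
#' @param pep_index Mass index over `peptides$mass`.
#' @param glycans List of [glycan_record()]s.
#' @param glycan_index Mass index over the glycan masses.
#' @param cfg A [search_config()].
#' @param cache Environment used as an ion cache (optional).
#' @param trees Environment registry mapping glycan keys to trees (or
#'   O-glycan pair entries); pair candidates register themselves here.
#' @return Candidate data.frame (possibly zero rows); peptide-only
#'   candidates (no database glycan in reach) have `NA` glycan columns.
#' @export
peptide_based_search <- function(s, peptides, pep_index, glycans,
                                 glycan_index, cfg,
                                 cache = new.env(parent = emptyenv()),
                                 trees = new.env(parent = emptyenv())) {
  prec <- precursor_neutral_mass(s)
  stripped <- remove_glycan_peaks(s, cfg$triage_tol)
  half <- ppm_tol(prec, cfg$precursor_tol_ppm)
  min_res <- min(MONO_MASS)
  rows <- which(peptides$mass <= prec - min_res + half)
  out <- list()
  for (prow in rows) {
    ions <- ion_cache_get(cache, peptides, prow, s$fragmentation)
    max_mz <- mass_to_mz(peptides$mass[prow] +
                           2 * MONO_MASS[["HexNAc"]], 1L)
    pscore <- peptide_score(stripped, peptides$sequence[prow], cfg = cfg,
                            max_mz = max_mz, ions = ions)
    if (pscore < cfg$min_peptide_score) next
    gmass <- prec - peptides$mass[prow]
    recs <- query_mass_index(glycan_index, gmass, half, unit = "da")
    found <- FALSE
    for (g in recs) {
      rec <- glycans[[g]]
      gscore <- glycan_score(s, peptides$mass[prow], NULL, cfg,
                             frags = rec)
      out[[length(out) + 1L]] <- candidate_row(s, "peptide", peptides,
                                               prow, rec, pscore, gscore,
                                               cfg)
      found <- TRUE
    }
    # O mode: up to two glycans per peptide, enumerated over glycan pairs
    # whose summed mass fits the precursor (peptide needs >= 2 S/T sites)
    n_sites <- length(strsplit(peptides$glyco_sites[prow], ",")[[1L]])
    if (cfg$mode == "O" && cfg$max_o_glycans >= 2L && n_sites >= 2L) {
      for (a in seq_along(glycans)) {
        ra <- glycans[[a]]
        if (ra$mass > gmass + half) next
        bs <- query_mass_index(glycan_index, gmass - ra$mass, half, "da")
        for (b in bs[bs >= a]) {
          rb <- glycans[[b]]
          pair_key <- paste(sort(c(ra$key, rb$key)), collapse = " + ")
          if (is.null(trees[[pair_key]])) {
            trees[[pair_key]] <- list(pair = TRUE, a = ra, b = rb)
          }
          gscore <- score_glycan_entry(s, peptides$mass[prow],
                                       trees[[pair_key]], cfg)
          rec2 <- list(id = paste(ra$id, rb$id, sep = "+"),
                       key = pair_key,
                       composition = ra$composition + rb$composition,
                       mass = ra$mass + rb$mass)
          out[[length(out) + 1L]] <- candidate_row(s, "peptide", peptides,
                                                   prow, rec2, pscore,
                                                   gscore, cfg)
          found <- TRUE
        }
      }
    }
    if (!found) {
      out[[length(out) + 1L]] <- candidate_row(s, "peptide", peptides,
                                               prow, NULL, pscore, 0, cfg)
    }
  }
  rows_to_candidates(out)
}

#' Glycan-based search of one glycopeptide spectrum
#'
#' For each database glycan, infers the peptide mass from the precursor,
#' fetches peptides within tolerance and scores the glycopeptide Y-ion
#' series (plus the backbone series) for each pairing.
#'
#' @inheritParams peptide_based_search
#' @return Candidate data.frame (possibly zero rows).
#' @export
glycan_based_search <- function(s, peptides, pep_index, glycans,
                                glycan_index, cfg,
                                cache = new.env(parent = emptyenv())) {
  prec <- precursor_neutral_mass(s)
  half <- ppm_tol(prec, cfg$precursor_tol_ppm)
  out <- list()
  for (rec in glycans) {
    pmass <- prec - rec$mass
    if (pmass < 4 * min(AA_MASS)) next
    prows <- query_mass_index(pep_index, pmass, half, unit = "da")
    for (prow in prows) {
      gscore <- glycan_score(s, peptides$mass[prow], NULL, cfg,
                             frags = rec)
      if (gscore < cfg$min_glycan_score) next
      ions <- ion_cache_get(cache, peptides, prow, s$fragmentation)
      pscore <- peptide_score(s, peptides$sequence[prow], cfg = cfg,
                              ions = ions)
      out[[length(out) + 1L]] <- candidate_row(s, "glycan", peptides,
                                               prow, rec, pscore, gscore,
                                               cfg)
    }
  }
  rows_to_candidates(out)
}

#' Second-round rescoring of pooled candidates
#'
#' Rescoring uses the comprehensive ion set for every candidate regardless
#' of the stage that produced it: full-range backbone ions (b/y or c/z,
#' losses, HexNAc stubs, charges 1-2) and the glycopeptide Y and B series.
#' Candidates are deduplicated by (peptide, mods, glycan, site) and
#' re-ranked by the combined score.
#'
#' @param candidates Candidate data.frame from the two search stages.
#' @param s The [spectrum()].
#' @param trees Environment (or named list) mapping `glycan_key` to glycan
#'   trees or pair entries.
#' @param cfg A [search_config()].
#' @param cache Ion cache environment.
#' @return The rescored, deduplicated, re-ranked candidate data.frame.
#' @export
second_round_score <- function(candidates, s, trees, cfg,
                               cache = new.env(parent = emptyenv())) {
  if (nrow(candidates) == 0L) return(candidates)
  key <- paste(candidates$sequence, candidates$mods,
               candidates$glycan_key, candidates$site)
  candidates <- candidates[!duplicated(key), , drop = FALSE]
  for (i in seq_len(nrow(candidates))) {
    ions <- ion_cache_seq(cache, candidates$sequence[i],
                          candidates$mods[i], s$fragmentation)
    pscore <- peptide_score(s, candidates$sequence[i], cfg = cfg,
                            ions = ions)
    gscore <- 0
    if (!is.na(candidates$glycan_key[i])) {
      gscore <- score_glycan_entry(s, candidates$pep_mass[i],
                                   trees[[candidates$glycan_key[i]]], cfg)
    }
    candidates$peptide_score[i] <- pscore
    candidates$glycan_score[i] <- gscore
    candidates$total_score[i] <- pscore + cfg$glycan_weight * gscore
  }
  ord <- order(-candidates$total_score, candidates$sequence,
               candidates$glycan_key, method = "radix")
  candidates <- candidates[ord, , drop = FALSE]
  rownames(candidates) <- NULL
  candidates
}

# Search a single spectrum through the staged workflow. Returns a list
# with the best PSM row (or NULL), all candidates, and any de novo tree.
search_one_spectrum <- function(s, peptides, pep_index, glycans,
                                glycan_index, trees, cfg, cache) {
  c1 <- peptide_based_search(s, peptides, pep_index, glycans,
                             glycan_index, cfg, cache, trees)
  identified <- any(!is.na(c1$glycan_key) &
                      c1$peptide_score >= cfg$min_peptide_score)
  c2 <- if (!identified) {
    glycan_based_search(s, peptides, pep_index, glycans, glycan_index,
                        cfg, cache)
  } else empty_candidates()
  pool <- rbind(c1, c2)
  pool <- second_round_score(pool, s, trees, cfg, cache)
  denovo_tree <- NULL
  with_glycan <- pool[!is.na(pool$glycan_key), , drop = FALSE]
  if (nrow(with_glycan) > 0L) {
    best <- with_glycan[1L, , drop = FALSE]
  } else if (nrow(pool) > 0L && cfg$denovo && cfg$mode == "N" &&
             pool$peptide_score[1L] >= cfg$min_peptide_score) {
    # confident peptide, no database glycan: de novo rescue
    best <- pool[1L, , drop = FALSE]
    prec <- precursor_neutral_mass(s)
    dn <- tryCatch(
      denovo_glycan(s, best$pep_mass, prec, cfg),
      error = function(e) NULL
    )
    if (!is.null(dn) && !is.null(dn$tree)) {
      denovo_tree <- dn$tree
      best$glycan_id <- paste0("denovo_", s$id)
      best$glycan_key <- canonical_key(dn$tree)
      best$glycan_composition <- format_composition(tree_composition(dn$tree))
      best$glycan_mass <- tree_mass(dn$tree)
      best$glycan_score <- glycan_score(s, best$pep_mass, dn$tree, cfg)
      best$total_score <- best$peptide_score +
        cfg$glycan_weight * best$glycan_score
      best$stage <- "denovo"
      best$denovo <- TRUE
    } else {
      best <- NULL
    }
  } else {
    best <- NULL
  }
  list(best = best, candidates = pool, denovo_tree = denovo_tree)
}

#' Search a dataset of spectra against protein and glycan databases
#'
#' Runs the full workflow: decoy protein generation, digestion and sequon
#' filtering, decoy spectrum generation, per-spectrum triage and staged
#' search (peptide-based, then glycan-based, then de novo for confident
#' peptides without a database glycan), second-round rescoring, site
#' localization, S-scores, and joint two-level FDR.
#'
#' @param spectra List of [spectrum()] objects.
#' @param proteins Target protein data.frame (`accession`, `sequence`;
#'   `is_decoy` is added/overwritten as `FALSE`).
#' @param glycan_records List of [glycan_record()]s (the glycan database).
#' @param cfg A [search_config()].
#' @param seed Integer seed controlling decoy generation (the only source
#'   of randomness); the result table is deterministic given the seed.
#' @return A list of class `glyco_search_result`:
#'   `psms` (best PSM per spectrum, incl. decoy-spectrum PSMs, with
#'   q-values, `a_score`, `s_score` and `passes_fdr`), `native`
#'   (peptide-only identifications of native spectra), `denovo_trees`
#'   (named list), and `report` (per-stage counts).
#' @export
search_dataset <- function(spectra, proteins, glycan_records,
                           cfg = search_config(), seed = 1L) {
  proteins$is_decoy <- FALSE
  decoys <- make_decoy_proteins(proteins, derive_seed(seed, 1L), cfg$enzyme)
  all_prot <- rbind(proteins[, c("accession", "sequence", "is_decoy")],
                    decoys)

  all_peptides <- build_peptide_table(all_prot, cfg$enzyme, cfg$mods,
                                      cfg$mode, require_site = FALSE)
  has_site <- all_peptides$glyco_sites != ""
  glyco_peptides <- all_peptides[has_site, , drop = FALSE]
  rownames(glyco_peptides) <- NULL
  pep_index <- build_mass_index(glyco_peptides$mass)
  native_index <- build_mass_index(all_peptides$mass)

  glycan_records <- Filter(function(r) r$link_type == cfg$mode,
                           glycan_records)
  glycan_index <- build_mass_index(
    vapply(glycan_records, `[[`, numeric(1), "mass"))
  trees <- new.env(parent = emptyenv())
  for (rec in glycan_records) trees[[rec$key]] <- rec

  cache <- new.env(parent = emptyenv())
  psm_rows <- list()
  native_rows <- list()
  denovo_trees <- list()
  n_stage <- c(glyco = 0L, native = 0L, peptide = 0L, glycan = 0L,
               denovo = 0L, unidentified = 0L)

  process <- function(s) {
    # decoy spectra are paired with spectra already triaged as glyco and
    # must take the identical glyco search path (their shifted signature
    # ions would otherwise divert them)
    tr <- if (s$is_decoy) list(label = "glyco") else
      classify_spectrum(s, cfg$triage_tol)
    if (tr$label == "native") {
      n_stage["native"] <<- n_stage["native"] + 1L
      prec <- precursor_neutral_mass(s)
      prows <- query_mass_index(native_index, prec,
                                ppm_tol(prec, cfg$precursor_tol_ppm), "da")
      if (length(prows) > 0L) {
        scores <- vapply(prows, function(prow) {
          ions <- ion_cache_get(cache, all_peptides, prow, s$fragmentation)
          peptide_score(s, all_peptides$sequence[prow], cfg = cfg,
                        ions = ions)
        }, numeric(1))
        best <- prows[which.max(scores)]
        if (max(scores) >= cfg$min_peptide_score) {
          native_rows[[length(native_rows) + 1L]] <<- data.frame(
            spectrum_id = s$id, sequence = all_peptides$sequence[best],
            mods = all_peptides$mods[best],
            proteins = all_peptides$proteins[best],
            is_decoy_peptide = all_peptides$is_decoy[best],
            peptide_score = max(scores),
            is_decoy_spectrum = isTRUE(s$is_decoy),
            stringsAsFactors = FALSE)
        }
      }
      return(invisible(NULL))
    }
    n_stage["glyco"] <<- n_stage["glyco"] + 1L
    res <- search_one_spectrum(s, glyco_peptides, pep_index,
                               glycan_records, glycan_index, trees, cfg,
                               cache)
    if (is.null(res$best)) {
      n_stage["unidentified"] <<- n_stage["unidentified"] + 1L
      return(invisible(NULL))
    }
    best <- res$best
    n_stage[best$stage] <<- n_stage[best$stage] + 1L
    if (!is.null(res$denovo_tree)) {
      denovo_trees[[best$glycan_id]] <<- res$denovo_tree
    }
    # site localization and structure confidence on the winning candidate
    sites <- as.integer(strsplit(
      glyco_peptides$glyco_sites[match(paste(best$sequence, best$mods),
                                       paste(glyco_peptides$sequence,
                                             glyco_peptides$mods))],
      ",")[[1L]])
    entry <- if (isTRUE(best$denovo)) NULL else trees[[best$glycan_key]]
    tree <- if (isTRUE(best$denovo)) res$denovo_tree else
      if (!is.null(entry$pair)) entry$a$tree else entry$tree
    delta <- decode_mods(best$sequence, best$mods)
    sa <- a_score(s, best$sequence, delta, tree, sites, cfg)
    best$site <- sa$best_site
    best$a_score <- sa$a_score
    same_comp <- res$candidates$glycan_score[
      !is.na(res$candidates$glycan_composition) &
        res$candidates$glycan_composition == best$glycan_composition]
    best$s_score <- if (length(same_comp) > 0L) s_score(same_comp) else
      NA_real_
    psm_rows[[length(psm_rows) + 1L]] <<- best
    invisible(NULL)
  }

  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    process(s)
    # pair every glyco-triaged target spectrum with one decoy spectrum
    if (classify_spectrum(s, cfg$triage_tol)$label == "glyco") {
      ds <- make_decoy_spectrum(s, derive_seed(seed, 1000L + i))
      process(ds)
    }
  }

  psms <- if (length(psm_rows) > 0L) do.call(rbind, psm_rows) else {
    x <- empty_candidates()
    x$a_score <- numeric(0)
    x$s_score <- numeric(0)
    x
  }
  rownames(psms) <- NULL

  if (nrow(psms) > 0L) {
    tgt <- !psms$is_decoy_spectrum
    psms$peptide_q <- NA_real_
    psms$peptide_fdr <- NA_real_
    if (any(tgt)) {
      pf <- peptide_fdr(psms[tgt, , drop = FALSE])
      psms$peptide_q[tgt] <- pf$peptide_q
      psms$peptide_fdr[tgt] <- pf$peptide_fdr
    }
    gf <- glycan_fdr(psms)
    psms$glycan_q <- gf$glycan_q
    psms$glycan_fdr <- gf$glycan_fdr
    psms$passes_fdr <- FALSE
    ok <- tgt & !psms$is_decoy_peptide &
      psms$peptide_q <= cfg$fdr & psms$glycan_q <= cfg$fdr
    psms$passes_fdr[ok] <- TRUE
  }

  native <- if (length(native_rows) > 0L) do.call(rbind, native_rows) else
    NULL

  structure(list(
    psms = psms,
    native = native,
    denovo_trees = denovo_trees,
    report = as.list(n_stage),
    config = cfg,
    seed = seed
  ), class = "glyco_search_result")
}

#' @export
print.glyco_search_result <- function(x, ...) {
  cat("<glyco_search_result>\n")
  cat(sprintf("  glyco spectra: %d (peptide-based %d, glycan-based %d, de novo %d, unidentified %d)\n",
              x$report$glyco, x$report$peptide, x$report$glycan,
              x$report$denovo, x$report$unidentified))
  cat(sprintf("  native spectra: %d\n", x$report$native))
  if (nrow(x$psms) > 0L) {
    cat(sprintf("  glycoPSMs passing %.2g%% joint FDR: %d\n",
                100 * x$config$fdr, sum(x$psms$passes_fdr)))
  }
  invisible(x)
}
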