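# Protein databases: FASTA I/O, in-silico digestion, glycosylation sequons,
# decoy generation and peptide candidate tables.

#' Read / write a protein FASTA database
#'
#' @param path FASTA file path.
#' @param proteins A data.frame with columns `accession`, `sequence`,
#'   `is_decoy` (for the writer).
#' @return `read_protein_fasta()` a data.frame with columns `accession`,
#'   `sequence`, `is_decoy` (decoy status inferred from a `DECOY_` prefix).
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  acc <- sub("\\s.*$", "", names(aa))
  data.frame(
    accession = acc,
    sequence = as.character(aa),
    is_decoy = startsWith(acc, "DECOY_"),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_protein_fasta
#' @export
write_protein_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- proteins$accession
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Specify a proteolytic enzyme
#'
#' @param name Enzyme name; only the cut rule matters.
#' @param cleave_after Residues after which the enzyme cleaves.
#' @param not_before Cleavage is suppressed before these residues.
#' @param missed_cleavages Maximum number of missed cleavages.
#' @param specificity `"full"` (both termini enzymatic) or `"semi"` (at
#'   least one terminus enzymatic).
#' @return An `enzyme_spec` list.
#' @export
enzyme_spec <- function(name = "trypsin", cleave_after = c("K", "R"),
                        not_before = "P", missed_cleavages = 1L,
                        specificity = c("full", "semi")) {
  stopifnot(missed_cleavages >= 0L)
  structure(list(
    name = name, cleave_after = cleave_after, not_before = not_before,
    missed_cleavages = as.integer(missed_cleavages),
    specificity = match.arg(specificity)
  ), class = "enzyme_spec")
}

# 0-based cut positions (after residue i), including both protein ends
cut_sites <- function(aa, enzyme) {
  n <- length(aa)
  cuts <- which(aa %in% enzyme$cleave_after)
  if (length(enzyme$not_before) > 0L && length(cuts) > 0L) {
    nxt <- aa[pmin(cuts + 1L, n)]
    cuts <- cuts[!(cuts < n & nxt %in% enzyme$not_before)]
  }
  unique(c(0L, cuts, n))
}

#' Digest a protein into peptides
#'
#' @param sequence Protein sequence (single string).
#' @param enzyme An [enzyme_spec()].
#' @param min_length,max_length Peptide length bounds (defaults 5 and 50).
#' @return A data.frame with columns `sequence`, `start`, `end` (1-based
#'   protein coordinates), `missed`, deduplicated by peptide+position.
#' @export
digest <- function(sequence, enzyme = enzyme_spec(), min_length = 5L,
                   max_length = 50L) {
  if (nchar(sequence) == 0L) {
    return(data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), missed = integer(0),
                      stringsAsFactors = FALSE))
  }
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  cuts <- sort(cut_sites(aa, enzyme))
  rows <- list()
  ncut <- length(cuts)
  for (i in seq_len(ncut - 1L)) {
    for (j in (i + 1L):min(ncut, i + 1L + enzyme$missed_cleavages)) {
      start <- cuts[i] + 1L
      end <- cuts[j]
      if (enzyme$specificity == "full") {
        len <- end - start + 1L
        if (len >= min_length && len <= max_length) {
          rows[[length(rows) + 1L]] <- c(start, end, j - i - 1L)
        }
      } else {
        # semi-specific: one terminus may be non-enzymatic
        for (s2 in start:end) {
          len <- end - s2 + 1L
          if (s2 != start && len >= min_length && len <= max_length) {
            rows[[length(rows) + 1L]] <- c(s2, end, j - i - 1L)
          }
        }
        for (e2 in start:end) {
          len <- e2 - start + 1L
          if (len >= min_length && len <= max_length) {
            rows[[length(rows) + 1L]] <- c(start, e2, j - i - 1L)
          }
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), missed = integer(0),
                      stringsAsFactors = FALSE))
  }
  mat <- do.call(rbind, rows)
  df <- data.frame(
    sequence = substring(sequence, mat[, 1L], mat[, 2L]),
    start = mat[, 1L], end = mat[, 2L], missed = mat[, 3L],
    stringsAsFactors = FALSE
  )
  df <- df[order(df$start, df$end, df$missed), , drop = FALSE]
  df[!duplicated(df[c("sequence", "start", "end")]), , drop = FALSE]
}

#' Find glycosylation sequon positions in a peptide
#'
#' N mode: positions `i` with `N` at `i`, anything but `P` at `i + 1` and
#' `S`/`T`/`C` at `i + 2`. O mode: every `S` or `T`.
#'
#' @param sequence Peptide (or protein) sequence.
#' @param mode `"N"` or `"O"`.
#' @return Integer vector of 1-based positions (possibly empty).
#' @export
find_glyco_sites <- function(sequence, mode = c("N", "O")) {
  mode <- match.arg(mode)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(aa)
  if (mode == "O") return(which(aa %in% c("S", "T")))
  if (n < 3L) return(integer(0))
  i <- seq_len(n - 2L)
  i[aa[i] == "N" & aa[i + 1L] != "P" & aa[i + 2L] %in% c("S", "T", "C")]
}

#' Generate shuffled decoy proteins
#'
#' Each target protein yields one decoy of identical length and residue
#' composition. Shuffling is performed within enzymatic segments, keeping
#' the segment-terminal (cleavage) residue in place so decoy peptides
#' remain enzymatic and the decoy peptide mass distribution matches the
#' target one.
#'
#' @param proteins Data.frame with `accession`, `sequence`.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @param enzyme An [enzyme_spec()] (segment boundaries only).
#' @return A data.frame of decoys with accessions prefixed `DECOY_` and
#'   `is_decoy = TRUE`.
#' @export
make_decoy_proteins <- function(proteins, seed, enzyme = enzyme_spec()) {
  shuffle_one <- function(sequence) {
    aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    cuts <- sort(cut_sites(aa, enzyme))
    for (i in seq_len(length(cuts) - 1L)) {
      lo <- cuts[i] + 1L
      hi <- cuts[i + 1L]
      if (hi - lo >= 2L) {                 # keep cleavage residue at `hi`
        idx <- lo:(hi - 1L)
        aa[idx] <- aa[sample(idx)]
      }
    }
    paste(aa, collapse = "")
  }
  with_seed(seed, {
    data.frame(
      accession = paste0("DECOY_", proteins$accession),
      sequence = vapply(proteins$sequence, shuffle_one, character(1),
                        USE.NAMES = FALSE),
      is_decoy = TRUE,
      stringsAsFactors = FALSE
    )
  })
}

#' Modification settings for peptide candidate generation
#'
#' @param fixed Named numeric vector: residue -> delta mass applied to
#'   every occurrence (default carbamidomethyl on C).
#' @param variable Named numeric vector: residue -> delta mass optionally
#'   applied (default oxidation on M, deamidation on N/Q).
#' @param max_variable Maximum number of variable modifications per peptide.
#' @return A `mod_spec` list.
#' @export
mod_spec <- function(fixed = c(C = MOD_CARBAMIDOMETHYL),
                     variable = c(M = MOD_OXIDATION, N = MOD_DEAMIDATION,
                                  Q = MOD_DEAMIDATION),
                     max_variable = 2L) {
  structure(list(fixed = fixed, variable = variable,
                 max_variable = as.integer(max_variable)),
            class = "mod_spec")
}

# Per-residue delta vectors for all variable-mod combinations (<= max_variable)
mod_combinations <- function(aa, mods) {
  base <- numeric(length(aa))
  if (length(mods$fixed) > 0L) {
    hit <- aa %in% names(mods$fixed)
    base[hit] <- mods$fixed[aa[hit]]
  }
  out <- list(base)
  if (length(mods$variable) > 0L && mods$max_variable > 0L) {
    sites <- which(aa %in% names(mods$variable))
    if (length(sites) > 0L) {
      for (k in seq_len(min(mods$max_variable, length(sites)))) {
        for (pick in utils::combn(sites, k, simplify = FALSE)) {
          v <- base
          v[pick] <- v[pick] + mods$variable[aa[pick]]
          out[[length(out) + 1L]] <- v
        }
      }
    }
  }
  out
}

#' Build the peptide candidate table for a search
#'
#' Digests every protein (targets and decoys alike), applies fixed and
#' variable modifications, computes masses, and annotates glycosylation
#' sites for the requested mode. Identical (sequence, modification) pairs
#' from different proteins collapse to one row carrying all accessions;
#' a row is a decoy only if all parent proteins are decoys.
#'
#' @param proteins Data.frame with `accession`, `sequence`, `is_decoy`.
#' @param enzyme An [enzyme_spec()].
#' @param mods A [mod_spec()].
#' @param mode `"N"` or `"O"`: sequon rule for `glyco_sites`.
#' @param min_length,max_length Peptide length bounds.
#' @param require_site Keep only peptides with at least one glycosylation
#'   site (the glyco-search table); set `FALSE` for the native-search
#'   table.
#' @return A data.frame with columns `sequence`, `mods` (encoded
#'   `"pos:delta"` comma-string, `""` if none beyond fixed), `mass`,
#'   `glyco_sites` (comma-string of positions), `proteins`, `is_decoy`.
#' @export
build_peptide_table <- function(proteins, enzyme = enzyme_spec(),
                                mods = mod_spec(), mode = "N",
                                min_length = 5L, max_length = 50L,
                                require_site = TRUE) {
  rows <- list()
  for (p in seq_len(nrow(proteins))) {
    pep <- digest(proteins$sequence[p], enzyme, min_length, max_length)
    if (nrow(pep) == 0L) next
    pep <- pep[!duplicated(pep$sequence), , drop = FALSE]
    for (q in seq_len(nrow(pep))) {
      seqq <- pep$sequence[q]
      sites <- find_glyco_sites(seqq, mode)
      if (require_site && length(sites) == 0L) next
      aa <- strsplit(seqq, "", fixed = TRUE)[[1L]]
      if (any(!aa %in% names(AA_MASS))) next   # X etc: unmatchable
      for (delta in mod_combinations(aa, mods)) {
        modded <- which(delta != ifelse(aa %in% names(mods$fixed),
                                        mods$fixed[aa], 0))
        enc <- if (length(modded) == 0L) "" else
          paste(sprintf("%d:%.5f", modded, delta[modded]), collapse = ",")
        rows[[length(rows) + 1L]] <- list(
          sequence = seqq,
          mods = enc,
          mass = sum(AA_MASS[aa]) + WATER_MASS + sum(delta),
          glyco_sites = paste(sites, collapse = ","),
          proteins = proteins$accession[p],
          is_decoy = proteins$is_decoy[p]
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(sequence = character(0), mods = character(0),
                      mass = numeric(0), glyco_sites = character(0),
                      proteins = character(0), is_decoy = logical(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(rows, as.data.frame,
                              stringsAsFactors = FALSE))
  key <- paste(df$sequence, df$mods)
  agg_prot <- tapply(df$proteins, key, function(x)
    paste(sort(unique(x)), collapse = ";"))
  agg_decoy <- tapply(df$is_decoy, key, all)
  df <- df[!duplicated(key), , drop = FALSE]
  key <- key[!duplicated(key)]
  df$proteins <- unname(agg_prot[key])
  df$is_decoy <- unname(agg_decoy[key])
  df <- df[order(df$mass, df$sequence, df$mods), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# decode the per-residue delta vector of a peptide-table row
decode_mods <- function(sequence, enc,
                        fixed = c(C = MOD_CARBAMIDOMETHYL)) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  delta <- numeric(length(aa))
  if (length(fixed) > 0L) {
    hit <- aa %in% names(fixed)
    delta[hit] <- fixed[aa[hit]]
  }
  if (!is.na(enc) && nzchar(enc)) {
    for (tok in strsplit(enc, ",", fixed = TRUE)[[1L]]) {
      kv <- strsplit(tok, ":", fixed = TRUE)[[1L]]
      delta[as.integer(kv[1L])] <- as.numeric(kv[2L])
    }
  }
  delta
}
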