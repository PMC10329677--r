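# Synthetic-data generation with known ground truth.
#
# The generator emulates the evidence structure of HCD glycopeptide
# spectra: peptide-backbone b/y ions at the lower end, glycopeptide Y-ion
# ladders at the upper end, glycan B (oxonium) ions at high intensity, a
# configurable number of uniform noise peaks, and Gaussian ppm mass
# errors. It does not emulate chromatography, co-isolation or isotope
# envelopes; a green test on simulated data establishes algorithmic
# correctness, not instrument-level performance.

#' Simulation settings
#'
#' Defaults describe a clean, well-fragmented Orbitrap-like HCD
#' experiment: 90% backbone/Y-ion coverage, 70% B-ion coverage, always
#' visible oxonium signature ions, 30 noise peaks, 5 ppm fragment mass
#' error, precursor charges 2-4.
#'
#' @param seed Base seed fixing the whole run.
#' @param n_proteins Number of target proteins.
#' @param protein_length Approximate protein length (residues).
#' @param n_glycans Number of distinct glycans in the generating set.
#' @param glycan_size Inclusive residue-count range of generated glycans.
#' @param glycan_classes Monosaccharide classes the generating set may
#'   use.
#' @param forced_core Prefix every generated N-glycan with the
#'   HexNAc2Hex3 core.
#' @param charge_states Precursor charges sampled uniformly.
#' @param peptide_coverage,y_coverage,b_coverage Per-ion emission
#'   probabilities of the backbone, Y and B series.
#' @param noise_peaks Number of uniform noise peaks per spectrum.
#' @param mass_error_ppm Gaussian fragment/precursor mass error (ppm, sd).
#' @param intensity_model `"lognormal"` (realistic) or `"constant"`
#'   (noise-free oracle spectra).
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(seed = 1L, n_proteins = 12L,
                            protein_length = 240L, n_glycans = 25L,
                            glycan_size = c(5L, 9L),
                            glycan_classes = MONO_CODES,
                            forced_core = TRUE,
                            charge_states = 2:4,
                            peptide_coverage = 0.9, y_coverage = 0.9,
                            b_coverage = 0.7, noise_peaks = 30L,
                            mass_error_ppm = 5,
                            intensity_model = c("lognormal", "constant")) {
  stopifnot(peptide_coverage >= 0, peptide_coverage <= 1,
            y_coverage >= 0, y_coverage <= 1,
            b_coverage >= 0, b_coverage <= 1,
            noise_peaks >= 0, mass_error_ppm >= 0)
  structure(list(
    seed = as.integer(seed), n_proteins = as.integer(n_proteins),
    protein_length = as.integer(protein_length),
    n_glycans = as.integer(n_glycans), glycan_size = as.integer(glycan_size),
    glycan_classes = glycan_classes, forced_core = forced_core,
    charge_states = as.integer(charge_states),
    peptide_coverage = peptide_coverage, y_coverage = y_coverage,
    b_coverage = b_coverage, noise_peaks = as.integer(noise_peaks),
    mass_error_ppm = mass_error_ppm,
    intensity_model = match.arg(intensity_model)
  ), class = "simulation_spec")
}

#' A noise-free simulation spec
#'
#' Full ion coverage, no noise peaks, no mass error, constant intensity:
#' spectra equal their theoretical peak sets exactly, which makes the
#' generating truth an oracle for search and de novo tests.
#'
#' @param ... Overrides passed to [simulation_spec()].
#' @return A `simulation_spec`.
#' @export
noise_free_spec <- function(...) {
  args <- utils::modifyList(
    list(peptide_coverage = 1, y_coverage = 1, b_coverage = 1,
         noise_peaks = 0L, mass_error_ppm = 0,
         intensity_model = "constant"),
    list(...))
  do.call(simulation_spec, args)
}

# The conserved N-glycan core: HexNAc-HexNAc-Hex(-Hex)(-Hex).
n_core_tree <- function() {
  glycan_node("HexNAc", list(
    glycan_node("HexNAc", list(
      glycan_node("Hex", list(
        glycan_node("Hex"),
        glycan_node("Hex")
      ))
    ))
  ))
}

# Random rooted tree of `size` residues (uniform leaf growth, out-degree
# capped at 2 beyond the core branch point). Caller controls the RNG.
random_glycan_tree <- function(size, classes = MONO_CODES,
                               forced_core = TRUE) {
  class_w <- c(Hex = 0.45, HexNAc = 0.3, Fuc = 0.1, NeuAc = 0.1,
               NeuGc = 0.05)[classes]
  class_w <- class_w / sum(class_w)
  nodes <- list()
  if (forced_core && size >= 5L) {
    nodes <- list(
      list(code = "HexNAc", parent = 0L, children = 2L),
      list(code = "HexNAc", parent = 1L, children = 3L),
      list(code = "Hex", parent = 2L, children = c(4L, 5L)),
      list(code = "Hex", parent = 3L, children = integer(0)),
      list(code = "Hex", parent = 3L, children = integer(0))
    )
  } else {
    nodes <- list(list(code = sample(classes, 1L, prob = class_w),
                       parent = 0L, children = integer(0)))
  }
  while (length(nodes) < size) {
    deg_ok <- which(vapply(nodes, function(n) length(n$children) < 2L,
                           logical(1)))
    at <- if (length(deg_ok) == 1L) deg_ok else sample(deg_ok, 1L)
    id <- length(nodes) + 1L
    nodes[[id]] <- list(code = sample(classes, 1L, prob = class_w),
                        parent = at, children = integer(0))
    nodes[[at]]$children <- c(nodes[[at]]$children, id)
  }
  build <- function(id) {
    glycan_node(nodes[[id]]$code, lapply(nodes[[id]]$children, build))
  }
  build(1L)
}

#' Simulate a glycan structure database
#'
#' Random trees grown by repeated leaf attachment (optionally on top of
#' the forced N-core), deduplicated by canonical key; deterministic under
#' the spec seed.
#'
#' @param spec A [simulation_spec()].
#' @param link_type `"N"` or `"O"`.
#' @return A list of [glycan_record()]s of length `spec$n_glycans`.
#' @export
simulate_glycan_db <- function(spec = simulation_spec(), link_type = "N") {
  with_seed(derive_seed(spec$seed, 11L), {
    records <- list()
    keys <- character(0)
    tries <- 0L
    while (length(records) < spec$n_glycans && tries < 50L * spec$n_glycans) {
      tries <- tries + 1L
      size <- sample(spec$glycan_size[1L]:spec$glycan_size[2L], 1L)
      tree <- random_glycan_tree(size, spec$glycan_classes,
                                 spec$forced_core && link_type == "N")
      key <- canonical_key(tree)
      if (key %in% keys) next
      keys <- c(keys, key)
      records[[length(records) + 1L]] <- glycan_record(
        tree, id = sprintf("G%03d", length(records) + 1L),
        link_type = link_type)
    }
    records
  })
}

#' Simulate a target protein database
#'
#' Tryptic-like random proteins: K/R placed every 6-14 residues, an
#' N-glycosylation sequon (N-X-S/T, X != P) inserted into about 60% of
#' tryptic segments so glyco-candidates exist at any scale.
#'
#' @param spec A [simulation_spec()].
#' @param prefix Accession prefix.
#' @param seed_stream Internal stream offset (lets entrapment designs draw
#'   a second, disjoint proteome).
#' @return A data.frame with `accession`, `sequence`, `is_decoy`.
#' @export
simulate_proteins <- function(spec = simulation_spec(), prefix = "SPA",
                              seed_stream = 21L) {
  aa_pool <- c("A", "G", "S", "T", "V", "L", "I", "F", "Y", "D", "E",
               "Q", "H", "M", "W")
  with_seed(derive_seed(spec$seed, seed_stream), {
    seqs <- vapply(seq_len(spec$n_proteins), function(p) {
      out <- character(0)
      while (length(out) < spec$protein_length) {
        seg_len <- sample(6:14, 1L)
        seg <- sample(aa_pool, seg_len, replace = TRUE)
        if (runif(1) < 0.6 && seg_len >= 5L) {
          # insert N-X-S/T away from the segment ends
          at <- sample(2:(seg_len - 3L), 1L)
          seg[at] <- "N"
          if (seg[at + 1L] == "P") seg[at + 1L] <- "A"
          seg[at + 2L] <- sample(c("S", "T"), 1L)
        }
        out <- c(out, seg, sample(c("K", "R"), 1L))
      }
      paste(out, collapse = "")
    }, character(1))
    data.frame(
      accession = sprintf("%s%03d", prefix, seq_len(spec$n_proteins)),
      sequence = seqs,
      is_decoy = FALSE,
      stringsAsFactors = FALSE
    )
  })
}

# Sample theoretical peaks into an observed peak list (RNG from caller).
emit_peaks <- function(mz, keep_p, mean_int, spec) {
  keep <- runif(length(mz)) < keep_p
  mz <- mz[keep]
  n <- length(mz)
  if (n == 0L) return(list(mz = numeric(0), intensity = numeric(0)))
  intensity <- if (spec$intensity_model == "constant") {
    rep(mean_int, n)
  } else {
    rlnorm(n, meanlog = log(mean_int), sdlog = 0.5)
  }
  if (spec$mass_error_ppm > 0) {
    mz <- mz * (1 + rnorm(n, 0, spec$mass_error_ppm) * 1e-6)
  }
  list(mz = mz, intensity = intensity)
}

#' Simulate one glycopeptide spectrum
#'
#' Emits primary b/y ions (1+), the full glycopeptide Y-ion series (1+),
#' B ions and boosted oxonium signature ions per the coverage
#' probabilities, applies Gaussian ppm mass error, and adds uniform noise
#' peaks. The precursor m/z balances peptide + glycan mass exactly before
#' error injection.
#'
#' @param sequence Peptide sequence (must contain the glycosylation
#'   site).
#' @param tree Glycan tree.
#' @param site Glycosylation site position within the peptide.
#' @param spec A [simulation_spec()].
#' @param id Spectrum id.
#' @param seed Seed for this spectrum's randomness.
#' @return A [spectrum()] with a `truth` attribute
#'   (`list(sequence, site, key, composition)`).
#' @export
simulate_spectrum <- function(sequence, tree, site,
                              spec = simulation_spec(),
                              id = "sim_1", seed = 1L) {
  pmass <- peptide_mass(sequence)
  gmass <- tree_mass(tree)
  with_seed(seed, {
    z <- if (length(spec$charge_states) == 1L) spec$charge_states else
      sample(spec$charge_states, 1L)
    prec_mz <- mass_to_mz(pmass + gmass, z)

    bm <- backbone_masses(sequence)
    backbone_mz <- mass_to_mz(c(bm$b, bm$y), 1L)
    pk_b <- emit_peaks(backbone_mz, spec$peptide_coverage, 40, spec)

    # site-determining glycan-stub ions: backbone ions spanning the
    # glycosylation site carry the glycan root residue
    n_frag <- length(bm$b)
    npep <- n_frag + 1L
    idx <- seq_len(n_frag)
    yi <- rev(bm$y)
    stub <- MONO_MASS[[tree$code]]
    stub_mz <- mass_to_mz(c(bm$b[idx >= site],
                            yi[idx >= npep - site + 1L]) + stub, 1L)
    pk_stub <- emit_peaks(stub_mz, spec$peptide_coverage, 30, spec)

    ymass <- y_fragment_masses(tree, pmass)
    pk_y <- emit_peaks(mass_to_mz(ymass, 1L), spec$y_coverage, 60, spec)

    bfrag <- enumerate_b_fragments(tree)
    pk_bb <- emit_peaks(bfrag$neutral_mass + PROTON_MASS,
                        spec$b_coverage, 50, spec)

    sig <- signature_ions()
    comp <- tree_composition(tree)
    present <- c("HexNAc", "HexNAc-H2O", "Hex+HexNAc")
    if (comp[["Hex"]] == 0L) present <- c("HexNAc", "HexNAc-H2O")
    pk_ox <- emit_peaks(sig$mz[sig$ion %in% present], 1, 120, spec)

    mzv <- c(pk_b$mz, pk_stub$mz, pk_y$mz, pk_bb$mz, pk_ox$mz)
    inten <- c(pk_b$intensity, pk_stub$intensity, pk_y$intensity,
               pk_bb$intensity, pk_ox$intensity)
    if (spec$noise_peaks > 0L) {
      nmz <- runif(spec$noise_peaks, 150, max(prec_mz * z, 500))
      nint <- runif(spec$noise_peaks, 1, 8)
      mzv <- c(mzv, nmz)
      inten <- c(inten, nint)
    }
    s <- spectrum(id = id, precursor_mz = prec_mz, precursor_charge = z,
                  mz = mzv, intensity = inten, fragmentation = "HCD")
    attr(s, "truth") <- list(sequence = sequence, site = site,
                             key = canonical_key(tree),
                             composition = format_composition(comp))
    s
  })
}

# Enumerate the glycopeptides (sequence, site) available in a protein set.
glyco_peptide_pool <- function(proteins, enzyme = enzyme_spec(),
                               mode = "N") {
  pool <- list()
  for (p in seq_len(nrow(proteins))) {
    pep <- digest(proteins$sequence[p], enzyme)
    pep <- pep[!duplicated(pep$sequence), , drop = FALSE]
    for (q in seq_len(nrow(pep))) {
      sites <- find_glyco_sites(pep$sequence[q], mode)
      if (length(sites) == 0L) next
      aa <- strsplit(pep$sequence[q], "", fixed = TRUE)[[1L]]
      if (any(!aa %in% names(AA_MASS))) next
      pool[[length(pool) + 1L]] <- list(
        sequence = pep$sequence[q], sites = sites,
        protein = proteins$accession[p])
    }
  }
  pool[!duplicated(vapply(pool, `[[`, character(1), "sequence"))]
}

#' Simulate a complete glycopeptide dataset with ground truth
#'
#' Generates a protein database, a glycan database, and `n_spectra`
#' glycopeptide spectra from random (peptide, site, glycan) assignments.
#' A fraction of the generating glycans can be withheld from the search
#' database to exercise de novo sequencing and second-round rescue.
#'
#' @param spec A [simulation_spec()].
#' @param n_spectra Number of glycopeptide spectra.
#' @param withheld_fraction Fraction of generating glycans excluded from
#'   the returned search database (their spectra are still generated).
#' @param mode `"N"` or `"O"`.
#' @return A list: `spectra`, `proteins`, `glycan_records` (search
#'   database), `generating_records` (full generating set), `truth`
#'   (data.frame: `spectrum_id`, `sequence`, `protein`, `site`, `key`,
#'   `composition`, `withheld`), `withheld_keys`.
#' @export
simulate_dataset <- function(spec = simulation_spec(), n_spectra = 100L,
                             withheld_fraction = 0, mode = "N") {
  proteins <- simulate_proteins(spec)
  glycans <- simulate_glycan_db(spec, link_type = mode)
  pool <- glyco_peptide_pool(proteins, mode = mode)
  if (length(pool) == 0L) stop("simulated proteome yielded no glycopeptides")
  keys <- vapply(glycans, `[[`, character(1), "key")
  comps <- vapply(glycans, function(r) format_composition(r$composition),
                  character(1))
  n_withheld <- round(withheld_fraction * length(glycans))
  # withholding is composition-level: a same-composition structure left in
  # the database would still absorb the withheld spectra by mass
  withheld_comps <- if (n_withheld > 0L) {
    with_seed(derive_seed(spec$seed, 31L),
              sample(unique(comps), min(n_withheld, length(unique(comps)))))
  } else character(0)
  withheld_keys <- keys[comps %in% withheld_comps]
  search_db <- Filter(function(r)
    !format_composition(r$composition) %in% withheld_comps, glycans)

  assign_df <- with_seed(derive_seed(spec$seed, 41L), {
    data.frame(
      pep = sample(length(pool), n_spectra, replace = TRUE),
      gly = sample(length(glycans), n_spectra, replace = TRUE),
      seed = sample.int(2^30, n_spectra)
    )
  })
  spectra <- vector("list", n_spectra)
  truth <- vector("list", n_spectra)
  for (i in seq_len(n_spectra)) {
    pp <- pool[[assign_df$pep[i]]]
    rec <- glycans[[assign_df$gly[i]]]
    site <- pp$sites[1L]
    id <- sprintf("sim_%04d", i)
    spectra[[i]] <- simulate_spectrum(pp$sequence, rec$tree, site, spec,
                                      id = id, seed = assign_df$seed[i])
    truth[[i]] <- data.frame(
      spectrum_id = id, sequence = pp$sequence, protein = pp$protein,
      site = site, key = rec$key,
      composition = format_composition(rec$composition),
      withheld = rec$key %in% withheld_keys,
      stringsAsFactors = FALSE
    )
  }
  list(
    spectra = spectra,
    proteins = proteins,
    glycan_records = search_db,
    generating_records = glycans,
    truth = do.call(rbind, truth),
    withheld_keys = withheld_keys,
    withheld_comps = withheld_comps
  )
}

#' Two-species / impossible-glycan entrapment design
#'
#' Emulates the classic FDR audit: spectra are generated exclusively from
#' species-A proteins and from glycans built without the designated
#' monosaccharide classes (high-mannose-like HexNAc/Hex trees), while the
#' searched databases additionally contain an equally sized species-B
#' proteome and glycans that do contain the designated classes. Any
#' accepted identification hitting species B or a designated-class glycan
#' is a known false positive, so realized entrapment rates can be compared
#' with the reported FDR.
#'
#' @param spec A [simulation_spec()] (its `glycan_classes` are overridden
#'   to `c("Hex", "HexNAc")` for the generating set).
#' @param n_spectra Number of spectra.
#' @param entrap_classes Monosaccharide classes reserved for entrapment
#'   glycans.
#' @return A list: `spectra`, `proteins` (A + B), `glycan_records`
#'   (generating + entrapment), `truth`, `entrap_accessions`,
#'   `entrap_keys`.
#' @export
entrapment_design <- function(spec = simulation_spec(), n_spectra = 100L,
                              entrap_classes = c("Fuc", "NeuAc", "NeuGc")) {
  gen_spec <- spec
  gen_spec$glycan_classes <- c("Hex", "HexNAc")
  ds <- simulate_dataset(gen_spec, n_spectra, withheld_fraction = 0)

  entrap_prot <- simulate_proteins(spec, prefix = "SPB", seed_stream = 22L)
  entrap_spec <- spec
  entrap_spec$seed <- derive_seed(spec$seed, 7L)
  entrap_gly <- simulate_glycan_db(entrap_spec)
  # keep only entrapment glycans that actually contain a designated class
  entrap_gly <- Filter(function(r)
    sum(r$composition[entrap_classes]) > 0L, entrap_gly)
  gen_keys <- vapply(ds$glycan_records, `[[`, character(1), "key")
  entrap_gly <- Filter(function(r) !r$key %in% gen_keys, entrap_gly)
  for (i in seq_along(entrap_gly)) {
    entrap_gly[[i]]$id <- sprintf("E%03d", i)
  }
  list(
    spectra = ds$spectra,
    proteins = rbind(ds$proteins, entrap_prot),
    glycan_records = c(ds$glycan_records, entrap_gly),
    truth = ds$truth,
    entrap_accessions = entrap_prot$accession,
    entrap_keys = vapply(entrap_gly, `[[`, character(1), "key")
  )
}
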