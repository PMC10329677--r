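# shared small noise-free world for the search tests
nf_world <- local({
  sp <- noise_free_spec(seed = 3, n_proteins = 6, n_glycans = 8,
                        glycan_size = c(5L, 7L))
  ds <- simulate_dataset(sp, n_spectra = 15)
  cfg <- search_config(mods = mod_spec(variable = NULL), denovo = FALSE)
  res <- search_dataset(ds$spectra, ds$proteins, ds$glycan_records, cfg,
                        seed = 3)
  list(sp = sp, ds = ds, cfg = cfg, res = res)
})

test_that("noise-free spectra with complete databases identify perfectly", {
  ds <- nf_world$ds
  res <- nf_world$res
  psms <- res$psms[!res$psms$is_decoy_spectrum, ]
  m <- merge(psms, ds$truth, by = "spectrum_id")
  expect_equal(nrow(m), nrow(ds$truth))
  expect_true(all(m$sequence.x == m$sequence.y))
  expect_true(all(m$glycan_key == m$key))
  expect_true(all(m$site.x == m$site.y))
  expect_true(all(m$passes_fdr))
})

test_that("every reported glycoPSM balances the precursor mass", {
  res <- nf_world$res
  psms <- res$psms[!is.na(res$psms$glycan_mass) &
                     !res$psms$is_decoy_spectrum, ]
  spectra <- nf_world$ds$spectra
  prec <- vapply(psms$spectrum_id, function(id) {
    s <- spectra[[match(id, vapply(spectra, `[[`, character(1), "id"))]]
    precursor_neutral_mass(s)
  }, numeric(1))
  err <- abs(prec - psms$pep_mass - psms$glycan_mass)
  tol <- prec * nf_world$cfg$precursor_tol_ppm * 1e-6
  expect_true(all(err <= tol))
})

test_that("search results are byte-identical across reruns with one seed", {
  ds <- nf_world$ds
  res2 <- search_dataset(ds$spectra, ds$proteins, ds$glycan_records,
                         nf_world$cfg, seed = 3)
  expect_identical(nf_world$res$psms, res2$psms)
})

test_that("peptide score is monotone in matched ions, scale invariant", {
  cfg <- nf_world$cfg
  seqq <- "AANLSTGWK"
  ions <- peptide_ions(seqq, fragmentation = "HCD")
  prim <- ions[ions$primary, ]
  s_all <- spectrum("a", 700, 2, prim$mz, rep(50, nrow(prim)))
  half_idx <- seq_len(nrow(prim) %/% 2)
  s_half <- spectrum("b", 700, 2, prim$mz[half_idx],
                     rep(50, length(half_idx)))
  expect_gt(peptide_score(s_all, seqq, cfg = cfg),
            peptide_score(s_half, seqq, cfg = cfg))
  # zero matched ions
  expect_equal(peptide_score(spectrum("c", 700, 2, 5000, 10), seqq,
                             cfg = cfg), 0)
  # global intensity scaling leaves the score unchanged
  s_scaled <- spectrum("d", 700, 2, prim$mz, rep(5000, nrow(prim)))
  expect_equal(peptide_score(s_all, seqq, cfg = cfg),
               peptide_score(s_scaled, seqq, cfg = cfg))
})

test_that("the true peptide outscores its shuffle on simulated spectra", {
  # scaled-down simulation study (60 spectra) of the score's discrimination
  sp <- simulation_spec(seed = 21, n_proteins = 4)
  cfg <- search_config(mods = mod_spec(variable = NULL))
  wins <- 0L
  n <- 60L
  glycoscout:::with_seed(77, {
    shuffle_seq <- function(x) {
      aa <- strsplit(x, "")[[1]]
      paste(sample(aa), collapse = "")
    }
    pool <- glycoscout:::glyco_peptide_pool(simulate_proteins(sp))
    for (i in seq_len(n)) {
      pp <- pool[[sample(length(pool), 1)]]
      tr <- rnd_tree(6)
      s <- simulate_spectrum(pp$sequence, tr, pp$sites[1], sp,
                             seed = 300 + i)
      truth <- peptide_score(s, pp$sequence, cfg = cfg)
      shuf <- peptide_score(s, shuffle_seq(pp$sequence), cfg = cfg)
      wins <- wins + (truth > shuf)
    }
  })
  expect_gte(wins / n, 0.95)
})

test_that("glycan score is monotone in observed Y ions", {
  cfg <- nf_world$cfg
  core <- core_tree()
  pep <- peptide_mass("AANLSTGWK")
  ym <- glycoscout:::y_fragment_masses(core, pep)
  full <- spectrum("a", 900, 2, mass_to_mz(ym, 1), rep(100, length(ym)))
  partial <- spectrum("b", 900, 2, mass_to_mz(ym[1:(length(ym) - 2)], 1),
                      rep(100, length(ym) - 2))
  expect_gt(glycan_score(full, pep, core, cfg),
            glycan_score(partial, pep, core, cfg))
  # no glycan evidence at all
  expect_lt(glycan_score(spectrum("c", 900, 2, 150, 10), pep, core, cfg),
            0.05)
})

test_that("a strong Y ladder without backbone ions falls through to the glycan-based stage", {
  sp <- noise_free_spec(seed = 9, n_proteins = 5, n_glycans = 6,
                        peptide_coverage = 0)   # no b/y ions at all
  ds <- simulate_dataset(sp, n_spectra = 8)
  cfg <- search_config(mods = mod_spec(variable = NULL), denovo = FALSE)
  res <- search_dataset(ds$spectra, ds$proteins, ds$glycan_records, cfg,
                        seed = 9)
  expect_gt(res$report$glycan, 0)
  psms <- res$psms[!res$psms$is_decoy_spectrum, ]
  m <- merge(psms, ds$truth, by = "spectrum_id")
  expect_true(all(m$glycan_key == m$key))
})

test_that("second-round rescoring is reproducible and non-degrading", {
  ds <- nf_world$ds
  cfg <- nf_world$cfg
  s <- ds$spectra[[1]]
  all_prot <- rbind(ds$proteins,
                    make_decoy_proteins(ds$proteins,
                                        glycoscout:::derive_seed(3, 1)))
  peptides <- build_peptide_table(all_prot, cfg$enzyme, cfg$mods, "N")
  pep_index <- build_mass_index(peptides$mass)
  gl_index <- build_mass_index(vapply(ds$glycan_records, `[[`,
                                      numeric(1), "mass"))
  trees <- new.env(parent = emptyenv())
  for (rec in ds$glycan_records) trees[[rec$key]] <- rec
  c1 <- peptide_based_search(s, peptides, pep_index, ds$glycan_records,
                             gl_index, cfg)
  expect_gt(nrow(c1), 0)
  r1 <- second_round_score(c1, s, trees, cfg)
  r2 <- second_round_score(c1[sample(nrow(c1)), ], s, trees, cfg)
  expect_identical(r1[order(r1$glycan_key), ]$total_score,
                   r2[order(r2$glycan_key), ]$total_score)
  # on one and the same spectrum, widening the matched ion range (the
  # round-2 comprehensive set) can only add evidence
  best1 <- c1[which.max(c1$total_score), ]
  cut <- mass_to_mz(best1$pep_mass + 2 * MONO_MASS[["HexNAc"]], 1)
  expect_gte(peptide_score(s, best1$sequence, cfg = cfg),
             peptide_score(s, best1$sequence, cfg = cfg, max_mz = cut) -
               1e-9)
})

test_that("candidates merge without duplicates across stages", {
  res <- nf_world$res
  key <- paste(res$psms$spectrum_id, res$psms$sequence, res$psms$mods,
               res$psms$glycan_key, res$psms$site)
  expect_false(any(duplicated(key)))
})

test_that("O-linked mode assigns pairs of glycans by summed mass", {
  pepseq <- "AATTLGGWK"          # two O sites (T3, T4) + S/T content
  g1 <- chain_tree(c("HexNAc", "Hex"))
  g2 <- chain_tree(c("HexNAc", "NeuAc"))
  recs <- list(glycan_record(g1, id = "o1", link_type = "O"),
               glycan_record(g2, id = "o2", link_type = "O"))
  pm <- peptide_mass(pepseq)
  total <- pm + tree_mass(g1) + tree_mass(g2)
  bm <- glycoscout:::backbone_masses(pepseq)
  # backbone ions + Y ions of each glycan with the other intact
  y1 <- glycoscout:::y_fragment_masses(g1, pm + tree_mass(g2))
  y2 <- glycoscout:::y_fragment_masses(g2, pm + tree_mass(g1))
  mz <- c(mass_to_mz(c(bm$b, bm$y), 1), mass_to_mz(c(y1, y2), 1),
          oxonium_mz(glycan_composition(HexNAc = 1)))
  s <- spectrum("opair", mass_to_mz(total, 2), 2, mz,
                rep(100, length(mz)))
  prot <- data.frame(accession = "OP1",
                     sequence = paste0("MK", pepseq, "AAAGGR"),
                     is_decoy = FALSE, stringsAsFactors = FALSE)
  cfg <- search_config(mode = "O", mods = mod_spec(variable = NULL),
                       denovo = FALSE)
  res <- search_dataset(list(s), prot, recs, cfg, seed = 2)
  psms <- res$psms[!res$psms$is_decoy_spectrum, ]
  expect_equal(nrow(psms), 1L)
  expect_true(grepl("+", psms$glycan_id, fixed = TRUE))
  expect_equal(psms$glycan_mass, tree_mass(g1) + tree_mass(g2),
               tolerance = 1e-6)
})
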