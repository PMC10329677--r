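test_that("decoy spectra shift every peak by 3-30 m/z, deterministically", {
  glycoscout:::with_seed(4, {
    s <- spectrum("t", 900, 2, sort(runif(50, 100, 1500)), rlnorm(50, 3))
  })
  d <- make_decoy_spectrum(s, seed = 12)
  expect_true(d$is_decoy)
  expect_equal(length(d$mz), length(s$mz))
  expect_identical(sort(d$intensity), sort(s$intensity))
  # per-peak shifts (match peaks by intensity since order can change)
  shifts <- abs(d$mz[order(d$intensity)] - s$mz[order(s$intensity)])
  expect_true(all(shifts >= 3 - 1e-9 & shifts <= 30 + 1e-9))
  expect_identical(make_decoy_spectrum(s, seed = 12)$mz, d$mz)
  expect_false(identical(make_decoy_spectrum(s, seed = 13)$mz, d$mz))
  expect_equal(d$precursor_mz, s$precursor_mz)
})

test_that("peptide- and glycan-level FDR follow the decoy ratios", {
  psms <- data.frame(
    peptide_score = c(seq(100, 1, length.out = 202)),
    is_decoy_peptide = c(rep(FALSE, 200), TRUE, TRUE))
  # at the loosest threshold: 2 decoys over 200 targets = 1%
  out <- peptide_fdr(psms)
  expect_equal(max(out$peptide_fdr), 2 / 200)
  expect_equal(out$peptide_q[1], 0)   # top target sees no decoy above it
  # no decoys at all -> 0 everywhere
  clean <- peptide_fdr(data.frame(peptide_score = 10:1,
                                  is_decoy_peptide = rep(FALSE, 10)))
  expect_true(all(clean$peptide_q == 0))
  # glycan level mirrors with decoy spectra
  g <- glycan_fdr(data.frame(
    glycan_score = seq(1, 0, length.out = 303),
    is_decoy_spectrum = c(rep(FALSE, 300), TRUE, TRUE, TRUE)))
  expect_equal(max(g$glycan_fdr), 3 / 300)
  # decoys outscoring all targets push FDR to >= 1
  g2 <- glycan_fdr(data.frame(glycan_score = c(10, 9, 1),
                              is_decoy_spectrum = c(TRUE, TRUE, FALSE)))
  expect_true(all(g2$glycan_q[!g2$is_decoy_spectrum] >= 1))
})

test_that("q-values are monotone non-increasing in score", {
  glycoscout:::with_seed(15, {
    for (rep in 1:5) {
      psms <- data.frame(
        peptide_score = runif(200),
        is_decoy_peptide = runif(200) < 0.3)
      out <- peptide_fdr(psms)
      ord <- order(-out$peptide_score)
      expect_true(all(diff(out$peptide_q[ord]) >= -1e-12))
    }
  })
})

test_that("the joint filter requires both levels at or below the cut", {
  psms <- data.frame(
    peptide_q = c(0.005, 0.005, 0.01, 0),
    glycan_q = c(0.02, 0.01, 0.01, 0),
    is_decoy_peptide = FALSE, is_decoy_spectrum = FALSE)
  out <- joint_fdr_filter(psms, fdr = 0.01)
  expect_identical(out$passes_fdr, c(FALSE, TRUE, TRUE, TRUE))
})

test_that("S-score is the relative gap between top structures", {
  expect_equal(s_score(c(10, 8)), 0.2)
  expect_equal(s_score(c(7, 7, 3)), 0)
  expect_equal(s_score(5), 1)
  expect_true(is.na(s_score(c(0, -1))))
  expect_error(s_score(numeric(0)))
})

test_that("A-score contract: singleton sites are forced, P maps to -10log10", {
  core <- core_tree()
  s <- toy_spectrum(c(300, 500, 700))
  one <- a_score(s, "AANCSTK", NULL, core, sites = 3L)
  expect_equal(one$a_score, 1000)
  expect_equal(one$best_site, 3L)
  # -10 log10 arithmetic of the published anchor values
  expect_equal(-10 * log10(1e-4), 40)
  expect_lt(10^(-42.89 / 10), 1 / 15000)
  # two-site case on a spectrum built to support the first site
  pepseq <- "ANSTANSTK"
  sites <- find_glyco_sites(pepseq, "N")
  expect_length(sites, 2L)
  det <- glycoscout:::site_ions(pepseq, numeric(nchar(pepseq)), sites[1],
                                core, "HCD")
  s2 <- spectrum("x", 1200, 2, sort(det), rep(100, length(det)))
  two <- a_score(s2, pepseq, NULL, core, sites = sites)
  expect_equal(two$best_site, sites[1])
  expect_gt(two$a_score, 0)
  expect_lt(two$a_score, 1000)
  # symmetric in site relabeling
  two_rev <- a_score(s2, pepseq, NULL, core, sites = rev(sites))
  expect_equal(two_rev$best_site, two$best_site)
  expect_equal(two_rev$a_score, two$a_score)
})

test_that("decoy spectra take the identical search path as targets", {
  sp <- noise_free_spec(seed = 31, n_proteins = 4, n_glycans = 5)
  ds <- simulate_dataset(sp, n_spectra = 3)
  cfg <- search_config(mods = mod_spec(variable = NULL), denovo = FALSE)
  all_prot <- rbind(ds$proteins,
                    make_decoy_proteins(ds$proteins,
                                        glycoscout:::derive_seed(31, 1)))
  peptides <- build_peptide_table(all_prot, cfg$enzyme, cfg$mods, "N")
  pidx <- build_mass_index(peptides$mass)
  gidx <- build_mass_index(vapply(ds$glycan_records, `[[`, numeric(1),
                                  "mass"))
  d <- make_decoy_spectrum(ds$spectra[[1]], seed = 5)
  d_as_target <- d
  d_as_target$is_decoy <- FALSE
  a <- peptide_based_search(d, peptides, pidx, ds$glycan_records, gidx, cfg)
  b <- peptide_based_search(d_as_target, peptides, pidx, ds$glycan_records,
                            gidx, cfg)
  expect_identical(a[setdiff(names(a), "is_decoy_spectrum")],
                   b[setdiff(names(b), "is_decoy_spectrum")])
})

test_that("de novo glycans are compared to targets at three levels", {
  core <- core_tree()
  same <- glycan_match_levels(core, core)
  expect_true(same$composition_match)
  expect_equal(same$fragment_fraction, 1)
  expect_true(same$structure_match)
  # chain vs branch of one composition: fraction from brute-force sets
  chain <- chain_tree(c("HexNAc", "HexNAc", "Hex", "Hex"))
  branch <- glycan_node("HexNAc", list(
    glycan_node("Hex"),
    glycan_node("HexNAc", list(glycan_node("Hex")))))
  lv <- glycan_match_levels(chain, branch)
  expect_true(lv$composition_match)
  expect_false(lv$structure_match)
  frag_set <- function(tree) unique(c(
    round(enumerate_y_fragments(tree, 0)$glycan_mass, 3),
    round(enumerate_b_fragments(tree)$neutral_mass, 3)))
  want <- length(intersect(frag_set(chain), frag_set(branch))) /
    length(frag_set(branch))
  expect_equal(lv$fragment_fraction, want)
  # disjoint compositions share only the empty retained set
  lv2 <- glycan_match_levels(chain_tree(c("Fuc", "Fuc")),
                             chain_tree(c("NeuAc", "NeuAc")))
  expect_false(lv2$composition_match)
  expect_false(lv2$structure_match)
})
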