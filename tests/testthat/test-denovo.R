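test_that("the DP recovers compositions from Y-ion evidence", {
  pep <- peptide_mass("ANCSTK")
  # glycan mass zero: empty composition
  s0 <- toy_spectrum(500, pmz = mass_to_mz(pep, 2), z = 2)
  dp0 <- dp_composition(s0, pep, pep)
  expect_equal(sum(dp0$composition), 0L)
  # Hex + HexNAc at 365.132 with both ladder peaks present
  gl <- residue_mass("HexNAc") + residue_mass("Hex")
  s <- spectrum("t", mass_to_mz(pep + gl, 2), 2,
                mass_to_mz(pep + c(residue_mass("HexNAc"), gl), 1),
                c(10, 10))
  dp <- dp_composition(s, pep, pep + gl)
  expect_equal(unname(dp$composition[c("Hex", "HexNAc")]), c(1L, 1L))
  expect_equal(dp$intensity, 20)
  # unreachable glycan mass (no residue combination fits)
  expect_null(dp_composition(s, pep, pep + 50))
})

test_that("the extension candidate set has exactly 21 stable members", {
  cs <- candidate_set()
  expect_length(cs, 21L)
  expect_equal(sum(vapply(cs, function(x) x$type == "end", logical(1))), 1L)
  keys <- vapply(cs, function(x)
    if (x$type == "end") "END" else paste(sort(x$codes), collapse = "+"),
    character(1))
  expect_false(any(duplicated(keys)))
  expect_true(all(c("Hex", "Hex+Hex", "Hex+HexNAc", "END") %in% keys))
  sizes <- vapply(cs, function(x)
    if (x$type == "end") 0L else length(x$codes), integer(1))
  expect_equal(sum(sizes == 1), 5L)
  expect_equal(sum(sizes == 2), 15L)
})

test_that("extend attaches groups, branches, and respects the budget", {
  comp <- glycan_composition(HexNAc = 1, Hex = 2)
  st <- glycoscout:::new_beam_state(comp)
  st <- extend(st, list(type = "extend", codes = "HexNAc"))   # root
  st2 <- extend(st, list(type = "extend", codes = c("Hex", "Hex")))
  tree <- glycoscout:::beam_state_tree(st2)
  expect_equal(length(tree$children), 2L)   # branch created
  # candidate exceeding the remaining composition is rejected
  expect_null(extend(st2, list(type = "extend", codes = "Hex")))
  # conservation: placed + remaining = total
  expect_equal(tree_composition(tree) + st2$remaining, comp)
  # termination on the last open node completes the tree
  st3 <- extend(st2, list(type = "end"))   # close root
  st3 <- extend(st3, list(type = "end"))   # close first Hex
  st3 <- extend(st3, list(type = "end"))   # close second Hex
  expect_true(glycoscout:::beam_state_complete(st3))
})

test_that("the fragment activation behaves as exp(-|D| c)", {
  pep <- 1000
  tree <- glycan_node("HexNAc")
  y1 <- mass_to_mz(pep + residue_mass("HexNAc"), 1)
  # exact match at base-peak intensity contributes weight 1 per ion
  s_exact <- spectrum("a", 700, 2, c(mass_to_mz(pep, 1), y1), c(100, 100))
  expect_equal(fragment_match_score(tree, s_exact, pep, use_b = FALSE), 2,
               tolerance = 1e-4)
  # a gap of ln(2)/c halves the contribution
  c0 <- 100
  s_off <- spectrum("b", 700, 2, c(mass_to_mz(pep, 1), y1 + log(2) / c0),
                    c(100, 100))
  expect_equal(fragment_match_score(tree, s_off, pep, c = c0,
                                    use_b = FALSE), 1.5, tolerance = 1e-4)
  # empty partial tree scores the bare peptide only
  expect_equal(fragment_match_score(NULL, s_exact, pep), 1,
               tolerance = 1e-4)
})

test_that("beam search rebuilds the N-core from its own spectrum", {
  core <- core_tree()
  pep <- peptide_mass("ANCSTK")
  s <- simulate_spectrum("ANCSTK", core, 3, noise_free_spec(seed = 1),
                         seed = 5)
  ranked <- beam_search(s, pep, tree_composition(core), beam_width = 5)
  expect_gt(nrow(ranked), 0)
  expect_identical(ranked$key[1], canonical_key(core))
  # single-residue composition has exactly one tree
  r1 <- beam_search(s, pep, glycan_composition(HexNAc = 1), beam_width = 5)
  expect_equal(nrow(r1), 1L)
  expect_identical(r1$key, "HexNAc")
  # only complete trees using exactly the composition are emitted
  comps <- lapply(attr(ranked, "trees"), tree_composition)
  for (cc in comps) expect_identical(cc, tree_composition(core))
})

test_that("training pairs replay to the canonical tree through extend()", {
  single <- glycan_node("Hex")
  tp <- training_pairs(single)
  expect_equal(tp[[1]]$partial_key, "")
  expect_identical(tp[[1]]$candidate$codes, "Hex")
  cand_keys <- vapply(candidate_set(), function(x)
    if (x$type == "end") "END" else paste(sort(x$codes), collapse = "+"),
    character(1))
  glycoscout:::with_seed(23, {
    for (i in 1:40) {
      tr <- rnd_tree(sample(1:8, 1))
      tp <- training_pairs(tr)   # errors internally if replay fails
      for (p in tp) {
        key <- if (p$candidate$type == "end") "END" else
          paste(sort(p$candidate$codes), collapse = "+")
        expect_true(key %in% cand_keys)
      }
    }
  })
})

test_that("an empty de novo set leaves rescue results unchanged", {
  sp <- noise_free_spec(seed = 13, n_proteins = 4, n_glycans = 5)
  ds <- simulate_dataset(sp, n_spectra = 6)
  cfg <- search_config(mods = mod_spec(variable = NULL), denovo = FALSE)
  res <- search_dataset(ds$spectra, ds$proteins, ds$glycan_records, cfg,
                        seed = 13)
  expect_length(res$denovo_trees, 0L)
  resc <- second_round_rescue(res, ds$spectra, ds$proteins,
                              ds$glycan_records, cfg, seed = 13)
  expect_length(resc$added, 0L)
  expect_identical(resc$result$psms, res$psms)
  expect_equal(resc$n_new_psms, 0L)
})
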