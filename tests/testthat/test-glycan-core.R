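test_that("residue masses derive from elemental composition", {
  expect_equal(round(residue_mass("HexNAc"), 3), 203.079)
  expect_equal(round(residue_mass("Hex"), 3), 162.053)
  expect_equal(round(residue_mass("Fuc"), 3), 146.058)
  # integer-rounded ladder deltas used in triage
  expect_equal(round(residue_mass(c("HexNAc", "Hex", "Fuc"))),
               c(203, 162, 146))
  # fixed mass ordering of the five classes
  expect_true(residue_mass("Fuc") < residue_mass("Hex"))
  expect_true(residue_mass("Hex") < residue_mass("HexNAc"))
  expect_true(residue_mass("HexNAc") < residue_mass("NeuAc"))
  expect_true(residue_mass("NeuAc") < residue_mass("NeuGc"))
  expect_error(residue_mass("Xyl"), "unknown")
})

test_that("oxonium m/z values match the diagnostic-ion table", {
  expect_equal(round(oxonium_mz(glycan_composition(HexNAc = 1)), 3),
               204.087)
  expect_equal(round(oxonium_mz(glycan_composition(Hex = 1, HexNAc = 1)), 3),
               366.139)
  expect_equal(round(oxonium_mz(glycan_composition(HexNAc = 1), 1L), 3),
               186.076)
  expect_equal(round(oxonium_mz(glycan_composition(HexNAc = 1), 2L), 3),
               168.066)
  expect_error(oxonium_mz(glycan_composition()), "empty")
})

test_that("glycan dialect parses, canonicalizes and round-trips", {
  one <- parse_glycan("HexNAc")
  expect_equal(tree_size(one), 1L)
  core <- core_tree()
  expect_equal(tree_size(core), 5L)
  expect_equal(unname(tree_composition(core)[c("HexNAc", "Hex")]),
               c(2L, 3L))
  # sibling order never matters
  shuffled <- parse_glycan(c("HexNAc", "  HexNAc", "    Hex",
                             "      Hex", "      Hex"))
  expect_true(structure_equal(core, shuffled))
  # errors name the offending token
  expect_error(parse_glycan("Xylose"), "Xylose")
  expect_error(parse_glycan(c("HexNAc", "Hex")), "orphan|root")
  expect_error(parse_glycan(c("HexNAc", "    Hex")), "orphan")
  # round-trip property over random trees
  glycoscout:::with_seed(42, {
    for (i in 1:30) {
      tr <- rnd_tree(sample(1:9, 1))
      back <- parse_glycan(write_glycan(tr))
      expect_identical(canonical_key(back), canonical_key(tr))
      # canonicalization idempotence
      expect_identical(canonical_key(parse_glycan(write_glycan(back))),
                       canonical_key(tr))
    }
  })
})

test_that("structure equality distinguishes topologies, not sibling order", {
  chain <- chain_tree(c("HexNAc", "HexNAc", "Hex", "Hex"))
  branch <- glycan_node("HexNAc", list(
    glycan_node("Hex"),
    glycan_node("HexNAc", list(glycan_node("Hex")))))
  expect_identical(tree_composition(chain), tree_composition(branch))
  expect_false(structure_equal(chain, branch))
  expect_false(structure_equal(chain, chain$children[[1]]))
})

test_that("glycan records check mass consistency and cache fragments", {
  rec <- glycan_record(core_tree(), id = "core")
  expect_equal(rec$mass, composition_mass(rec$composition),
               tolerance = 1e-6)
  expect_equal(length(rec$y_masses), 6L)  # distinct retained masses incl. Y0
  comp_rec <- glycan_record(NULL, id = "c",
                            composition = parse_composition("HexNAc(2)Hex(3)"))
  expect_true(comp_rec$structure_inferred)
  expect_equal(comp_rec$mass, rec$mass, tolerance = 1e-6)
})

test_that("composition strings parse and format", {
  comp <- parse_composition("HexNAc(2)Hex(11)")
  expect_equal(unname(comp[c("HexNAc", "Hex")]), c(2L, 11L))
  expect_identical(format_composition(comp), "HexNAc(2)Hex(11)")
  expect_error(parse_composition("Foo(1)"), "unknown")
  expect_error(parse_composition("HexNAc2"), "malformed")
})

test_that("the GlycoCT subset reader maps the five residue classes", {
  path <- system.file("extdata", "n_core.glycoct", package = "glycoscout")
  recs <- read_glycoct_db(path)
  expect_length(recs, 2L)
  expect_true(structure_equal(recs[[1]]$tree, core_tree()))
  comp2 <- recs[[2]]$composition
  expect_equal(unname(comp2), c(1L, 2L, 1L, 1L, 1L),
               ignore_attr = TRUE)  # Hex, HexNAc, Fuc, NeuAc, NeuGc
  # malformed inputs are rejected with context
  expect_error(parse_glycoct(c("RES", "1x:b-dglc-HEX-1:5")), "malformed")
  expect_error(parse_glycoct(c("RES", "1b:b-dglc-HEX-1:5",
                               "2b:b-dglc-HEX-1:5")), "root")
})
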