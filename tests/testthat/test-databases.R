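test_that("tryptic digestion enumerates cut-site windows", {
  enz0 <- enzyme_spec(missed_cleavages = 0L)
  expect_setequal(digest("MKNLSGR", enz0, min_length = 2)$sequence,
                  c("MK", "NLSGR"))
  enz1 <- enzyme_spec(missed_cleavages = 1L)
  expect_setequal(digest("MKNLSGR", enz1, min_length = 2)$sequence,
                  c("MK", "NLSGR", "MKNLSGR"))
  expect_equal(nrow(digest("", enz1)), 0L)
  # proline suppression
  expect_true("FKPAAR" %in% digest("FKPAAR", enz0, min_length = 2)$sequence)
  # semi-specific digestion keeps one enzymatic terminus
  semi <- digest("MKNLSGR", enzyme_spec(missed_cleavages = 0,
                                        specificity = "semi"),
                 min_length = 3)
  expect_true(all(c("NLSGR", "LSGR", "NLSG", "NLS") %in% semi$sequence))
})

test_that("sequon rules select glycosylation sites", {
  expect_equal(find_glyco_sites("AANCSK", "N"), 3L)    # N-C-S allowed
  expect_equal(find_glyco_sites("AANPSK", "N"), integer(0))  # X != P
  expect_equal(find_glyco_sites("ATSK", "O"), c(2L, 3L))
  expect_equal(find_glyco_sites("AANTTK", "N"), 3L)
  expect_equal(find_glyco_sites("NK", "N"), integer(0))
})

test_that("decoy proteins shuffle within enzymatic segments", {
  prot <- data.frame(accession = "P1",
                     sequence = "MKAAANLSGTKWERAPK",
                     stringsAsFactors = FALSE)
  d1 <- make_decoy_proteins(prot, seed = 7)
  expect_true(d1$is_decoy)
  expect_equal(d1$accession, "DECOY_P1")
  split_sorted <- function(x) sort(strsplit(x, "")[[1]])
  expect_identical(split_sorted(d1$sequence), split_sorted(prot$sequence))
  # determinism
  expect_identical(make_decoy_proteins(prot, seed = 7)$sequence,
                   d1$sequence)
  expect_false(identical(make_decoy_proteins(prot, seed = 8)$sequence,
                         d1$sequence))
  # a long protein virtually always differs from its decoy
  glycoscout:::with_seed(1, {
    long <- paste(sample(c(names(glycoscout::AA_MASS)), 1000,
                         replace = TRUE), collapse = "")
  })
  dlong <- make_decoy_proteins(data.frame(accession = "L",
                                          sequence = long), seed = 3)
  expect_false(identical(dlong$sequence, long))
})

test_that("the mass index reproduces a linear scan", {
  glycoscout:::with_seed(11, {
    masses <- runif(10000, 500, 5000)
    idx <- build_mass_index(masses)
    expect_true(1 %in% query_mass_index(idx, masses[1], 0.001))
    expect_length(query_mass_index(idx, 10000, 1), 0L)
    for (i in 1:100) {
      q <- runif(1, 500, 5000)
      tol <- runif(1, 0.001, 5)
      got <- sort(query_mass_index(idx, q, tol))
      want <- which(abs(masses - q) <= tol)
      expect_identical(got, want)
      ppm <- runif(1, 1, 50)
      got_ppm <- sort(query_mass_index(idx, q, ppm, unit = "ppm"))
      expect_identical(got_ppm, which(abs(masses - q) <= q * ppm * 1e-6))
    }
  })
})

test_that("peptide tables carry mods, sites and decoy provenance", {
  prot <- data.frame(
    accession = c("P1", "DECOY_P1"),
    sequence = c("AAANLSMGKTTTCK", "AAANLSMGKTTTCK"),
    is_decoy = c(FALSE, TRUE), stringsAsFactors = FALSE)
  tab <- build_peptide_table(prot, enzyme_spec(missed_cleavages = 0),
                             mode = "N", require_site = TRUE)
  expect_true(all(tab$glyco_sites != ""))
  # same peptide from target+decoy protein is not a decoy
  expect_false(any(tab$is_decoy))
  # masses agree with peptide_mass over the decoded modification vector
  for (i in seq_len(nrow(tab))) {
    delta <- glycoscout:::decode_mods(tab$sequence[i], tab$mods[i])
    expect_equal(tab$mass[i],
                 peptide_mass(tab$sequence[i]) + sum(delta),
                 tolerance = 1e-6)
  }
  # the mods string encodes variable modifications only, at most 2
  n_var <- vapply(strsplit(tab$mods, ",", fixed = TRUE), function(x)
    sum(nzchar(x)), integer(1))
  expect_true(all(n_var <= 2L))
  expect_true(any(n_var > 0L))  # oxidised-Met variants exist
  # digestion output independent of protein order
  tab_rev <- build_peptide_table(prot[2:1, ],
                                 enzyme_spec(missed_cleavages = 0),
                                 mode = "N", require_site = TRUE)
  expect_identical(tab[c("sequence", "mods", "mass")],
                   tab_rev[c("sequence", "mods", "mass")])
})

test_that("FASTA round-trips through Biostrings", {
  prot <- data.frame(accession = c("A1", "DECOY_A1"),
                     sequence = c("MKAAANLSGTK", "MKTGSLNAAAK"),
                     is_decoy = c(FALSE, TRUE), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_protein_fasta(prot, path)
  back <- read_protein_fasta(path)
  expect_identical(back$sequence, prot$sequence)
  expect_identical(back$is_decoy, c(FALSE, TRUE))
})
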