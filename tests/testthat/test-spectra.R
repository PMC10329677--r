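test_that("MGF round-trips and skips records without charge", {
  s1 <- toy_spectrum(c(204.0867, 366.1395, 500.123), c(50, 20, 100))
  s2 <- spectrum("b", 800.2, 3, c(150.1, 320.5), c(10, 30))
  s3 <- spectrum("c", 700.0, 2, numeric(0), numeric(0))
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(list(s1, s2, s3), path)
  back <- read_spectra(path)
  expect_length(back, 3L)
  expect_equal(back[[1]]$mz, s1$mz, tolerance = 1e-6)
  expect_equal(back[[2]]$precursor_charge, 3L)
  # drop the CHARGE line of the second record
  lines <- readLines(path)
  lines <- lines[-grep("^CHARGE", lines)[2]]
  writeLines(lines, path)
  expect_message(back2 <- read_mgf(path), "skipped")
  expect_length(back2, 2L)
  expect_equal(attr(back2, "skipped"), 1L)
})

test_that("mzML and MGF renderings of one fixture agree", {
  glycoscout:::with_seed(3, {
    mz <- sort(runif(40, 100, 1500))
    s <- spectrum("x", 1234.5678, 3, mz, rlnorm(40, 3, 1))
  })
  p1 <- withr::local_tempfile(fileext = ".mgf")
  p2 <- withr::local_tempfile(fileext = ".mzML")
  write_mgf(list(s), p1)
  write_mzml(list(s), p2)
  a <- read_spectra(p1)[[1]]
  b <- read_spectra(p2)[[1]]
  expect_equal(a$mz, b$mz, tolerance = 1e-4)
  expect_equal(a$precursor_mz, b$precursor_mz, tolerance = 1e-4)
  expect_equal(a$precursor_charge, b$precursor_charge)
})

test_that("signature ions are detected with relative intensities", {
  s <- toy_spectrum(204.0867, 100)
  hits <- detect_signature_ions(s)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$ion, "HexNAc")
  expect_equal(hits$rel_intensity, 1)
  # two weak ions still count
  s2 <- toy_spectrum(c(204.0867, 366.1395, 800), c(3, 2, 100))
  expect_equal(nrow(detect_signature_ions(s2)), 2L)
  # off-mass peak does not match
  expect_equal(nrow(detect_signature_ions(toy_spectrum(205.5))), 0L)
})

test_that("ion ladders require three peaks at residue spacings", {
  run <- detect_ion_ladder(toy_spectrum(c(1100.000, 1303.079, 1465.132)))
  expect_length(run, 1L)
  expect_length(run[[1]], 3L)
  expect_length(detect_ion_ladder(toy_spectrum(c(1100.000, 1303.079))), 0L)
  expect_length(detect_ion_ladder(toy_spectrum(c(1100.000, 1303.5,
                                                 1465.132))), 0L)
})

test_that("triage follows the signature/ladder rules", {
  # one signature ion at >= 5% relative intensity
  s <- toy_spectrum(c(204.0867, 900), c(10, 100))
  expect_equal(classify_spectrum(s)$label, "glyco")
  # one signature ion below 5%, no second ion, no ladder -> native
  s2 <- toy_spectrum(c(204.0867, 900), c(2, 100))
  expect_equal(classify_spectrum(s2)$label, "native")
  # ladder only
  s3 <- toy_spectrum(c(1100.000, 1303.079, 1465.132))
  tr3 <- classify_spectrum(s3)
  expect_equal(tr3$label, "glyco")
  expect_length(tr3$ladders, 1L)
  # plain backbone peaks
  expect_equal(classify_spectrum(toy_spectrum(c(300.1, 450.2, 600.3)))$label,
               "native")
  # label is glyco iff evidence non-empty
  expect_equal(nrow(classify_spectrum(s2)$signature) +
                 length(classify_spectrum(s2)$ladders), 0L)
})

test_that("triage is invariant to global intensity scaling", {
  glycoscout:::with_seed(5, {
    for (i in 1:10) {
      mz <- sort(c(sample(c(204.0867, 366.1395, 163.0601), 2),
                   runif(20, 100, 1500)))
      int <- rlnorm(22, 3, 1.5)
      s <- spectrum("a", 900, 2, mz, int)
      s10 <- spectrum("a", 900, 2, mz, int * 1000)
      expect_identical(classify_spectrum(s)$label,
                       classify_spectrum(s10)$label)
    }
  })
})

test_that("glycan peak removal strips evidence without touching the rest", {
  s <- toy_spectrum(c(204.0867, 500.0))
  out <- remove_glycan_peaks(s)
  expect_equal(out$mz, 500.0)
  expect_equal(s$mz, c(204.0867, 500.0))  # input untouched
  native <- toy_spectrum(c(300.1, 450.2))
  expect_equal(remove_glycan_peaks(native)$mz, native$mz)
  # removing a pure ladder makes the spectrum native
  ladder <- toy_spectrum(c(1100.000, 1303.079, 1465.132))
  expect_equal(classify_spectrum(remove_glycan_peaks(ladder))$label,
               "native")
  # peak count never increases
  glycoscout:::with_seed(6, {
    for (i in 1:10) {
      s <- toy_spectrum(sort(runif(30, 100, 1500)))
      expect_lte(length(remove_glycan_peaks(s)$mz), length(s$mz))
    }
  })
})
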