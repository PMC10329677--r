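# Spectrum container and readers/writers for centroided MGF and mzML.

#' Construct a centroided MS/MS spectrum
#'
#' @param id Spectrum identifier.
#' @param precursor_mz Precursor m/z.
#' @param precursor_charge Precursor charge (1-8).
#' @param mz Numeric vector of fragment m/z values (> 0); re-sorted
#'   ascending together with `intensity`.
#' @param intensity Non-negative intensities, same length as `mz`.
#' @param fragmentation One of `"HCD"`, `"ETD"`, `"EThcD"`.
#' @param is_decoy Whether this is a decoy (mass-shifted) spectrum.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(id, precursor_mz, precursor_charge, mz, intensity,
                     fragmentation = "HCD", is_decoy = FALSE) {
  if (!fragmentation %in% c("HCD", "ETD", "EThcD")) {
    stop("unknown fragmentation scheme: ", fragmentation)
  }
  stopifnot(length(mz) == length(intensity),
            all(is.finite(mz)), all(is.finite(intensity)),
            all(mz > 0), all(intensity >= 0),
            is.finite(precursor_mz), precursor_mz > 0)
  precursor_charge <- as.integer(precursor_charge)
  if (is.na(precursor_charge) || precursor_charge < 1L ||
      precursor_charge > 8L) {
    stop("precursor_charge must be an integer in 1..8")
  }
  ord <- order(mz)
  structure(list(
    id = as.character(id),
    precursor_mz = precursor_mz,
    precursor_charge = precursor_charge,
    mz = mz[ord],
    intensity = intensity[ord],
    fragmentation = fragmentation,
    is_decoy = isTRUE(is_decoy)
  ), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %s> precursor %.4f m/z (%d+), %d peaks, %s%s\n",
              x$id, x$precursor_mz, x$precursor_charge, length(x$mz),
              x$fragmentation, if (x$is_decoy) ", decoy" else ""))
  invisible(x)
}

#' Neutral precursor mass of a spectrum
#' @param s A [spectrum()].
#' @return `precursor_mz * z - z * PROTON_MASS` in Da.
#' @export
precursor_neutral_mass <- function(s) {
  mz_to_mass(s$precursor_mz, s$precursor_charge)
}

#' Read spectra from an MGF or mzML file
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"mgf"` or `"mzml"`.
#' @return A list of [spectrum()] objects. Records without a precursor
#'   charge are skipped; their count is reported in the `skipped` attribute
#'   and a message.
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "mzml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml"
              else "mgf"
  }
  switch(format, mgf = read_mgf(path), mzml = read_mzml(path))
}

#' @rdname read_spectra
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(begins) != length(ends) || any(begins > ends)) {
    stop("malformed MGF (unbalanced BEGIN/END IONS): ", path)
  }
  out <- list()
  skipped <- 0L
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[`, character(1), 1L))
    vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="),
                   character(1))
    getv <- function(key) if (key %in% keys) vals[match(key, keys)] else NA
    charge_raw <- getv("CHARGE")
    if (is.na(charge_raw)) {
      skipped <- skipped + 1L
      next
    }
    z <- as.integer(gsub("[^0-9]", "", charge_raw))
    pepmass <- as.numeric(strsplit(trimws(getv("PEPMASS")), "\\s+")[[1L]][1L])
    if (is.na(pepmass)) stop("MGF record ", k, " lacks PEPMASS")
    title <- getv("TITLE")
    id <- if (is.na(title)) paste0("index_", k) else title
    frag <- getv("FRAGMENTATION")
    peak_lines <- trimws(block[!hdr])
    peak_lines <- peak_lines[peak_lines != ""]
    if (length(peak_lines) > 0L) {
      mat <- do.call(rbind, lapply(strsplit(peak_lines, "[ \t]+"),
                                   function(x) as.numeric(x[1:2])))
      if (anyNA(mat)) stop("malformed peak line in MGF record ", k)
      mzv <- mat[, 1L]; inten <- mat[, 2L]
    } else {
      mzv <- numeric(0); inten <- numeric(0)
    }
    out[[length(out) + 1L]] <- spectrum(
      id = id, precursor_mz = pepmass, precursor_charge = z,
      mz = mzv, intensity = inten,
      fragmentation = if (is.na(frag)) "HCD" else frag
    )
  }
  if (skipped > 0L) {
    message(skipped, " MGF record(s) without CHARGE skipped")
  }
  attr(out, "skipped") <- skipped
  out
}

#' Write spectra to an MGF file
#' @param spectra List of [spectrum()] objects.
#' @param path Output file path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", s$id),
      sprintf("PEPMASS=%.6f", s$precursor_mz),
      paste0("CHARGE=", s$precursor_charge, "+"),
      paste0("FRAGMENTATION=", s$fragmentation),
      sprintf("%.6f %.6g", s$mz, s$intensity),
      "END IONS"
    ), con)
  }
  invisible(path)
}

# --- mzML -------------------------------------------------------------------
# Minimal centroided mzML support: spectrumList/spectrum elements with
# selected ion m/z, charge state and two binary data arrays (m/z +
# intensity), 32- or 64-bit floats, optionally zlib compressed.

decode_binary_array <- function(b64, is64, compressed) {
  raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
  if (compressed) raw <- memDecompress(raw, type = "gzip")
  readBin(raw, what = "double", n = length(raw) %/% (if (is64) 8L else 4L),
          size = if (is64) 8L else 4L, endian = "little")
}

#' @rdname read_spectra
#' @export
read_mzml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  out <- list()
  skipped <- 0L
  for (k in seq_along(nodes)) {
    node <- nodes[[k]]
    id <- xml2::xml_attr(node, "id")
    cv <- function(scope, acc) {
      xml2::xml_attr(
        xml2::xml_find_first(node, sprintf(".//%s/cvParam[@accession='%s']",
                                           scope, acc)), "value")
    }
    pmz <- as.numeric(cv("selectedIon", "MS:1000744"))
    z <- suppressWarnings(as.integer(cv("selectedIon", "MS:1000041")))
    if (is.na(z)) {
      skipped <- skipped + 1L
      next
    }
    arrays <- xml2::xml_find_all(node, ".//binaryDataArray")
    mzv <- NULL; inten <- NULL
    for (arr in arrays) {
      acc <- xml2::xml_attr(xml2::xml_find_all(arr, "./cvParam"), "accession")
      vals <- decode_binary_array(
        xml2::xml_text(xml2::xml_find_first(arr, "./binary")),
        is64 = "MS:1000523" %in% acc,
        compressed = "MS:1000574" %in% acc
      )
      if ("MS:1000514" %in% acc) mzv <- vals
      if ("MS:1000515" %in% acc) inten <- vals
    }
    if (is.null(mzv) || is.null(inten)) {
      stop("mzML spectrum ", k, " lacks m/z or intensity array")
    }
    out[[length(out) + 1L]] <- spectrum(
      id = id, precursor_mz = pmz, precursor_charge = z,
      mz = mzv, intensity = inten
    )
  }
  if (skipped > 0L) {
    message(skipped, " mzML spectrum(s) without charge state skipped")
  }
  attr(out, "skipped") <- skipped
  out
}

encode_binary_array <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L,
                                endian = "little"))
}

#' Write spectra to a minimal centroided mzML file
#'
#' Emits uncompressed 64-bit little-endian arrays; intended for fixtures
#' and interchange with the matching reader, not as a validating writer.
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output file path.
#' @export
write_mzml <- function(spectra, path) {
  spec_xml <- vapply(seq_along(spectra), function(k) {
    s <- spectra[[k]]
    sprintf(paste0(
      '<spectrum index="%d" id="%s" defaultArrayLength="%d">',
      '<cvParam accession="MS:1000511" name="ms level" value="2"/>',
      '<precursorList count="1"><precursor><selectedIonList count="1">',
      '<selectedIon>',
      '<cvParam accession="MS:1000744" name="selected ion m/z" value="%.6f"/>',
      '<cvParam accession="MS:1000041" name="charge state" value="%d"/>',
      '</selectedIon></selectedIonList></precursor></precursorList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray><cvParam accession="MS:1000523" name="64-bit float"/>',
      '<cvParam accession="MS:1000576" name="no compression"/>',
      '<cvParam accession="MS:1000514" name="m/z array"/>',
      '<binary>%s</binary></binaryDataArray>',
      '<binaryDataArray><cvParam accession="MS:1000523" name="64-bit float"/>',
      '<cvParam accession="MS:1000576" name="no compression"/>',
      '<cvParam accession="MS:1000515" name="intensity array"/>',
      '<binary>%s</binary></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      k - 1L, s$id, length(s$mz), s$precursor_mz, s$precursor_charge,
      encode_binary_array(s$mz), encode_binary_array(s$intensity))
  }, character(1))
  writeLines(c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<run id="run1">',
    sprintf('<spectrumList count="%d">', length(spectra)),
    spec_xml,
    '</spectrumList></run></mzML>'
  ), path)
  invisible(path)
}
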