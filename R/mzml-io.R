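# Minimal mzML support (PSI-MS controlled vocabulary, centroided data,
# uncompressed little-endian 64-bit float arrays).  The general-purpose
# Bioconductor readers (mzR) are not available in this toolchain, so the
# subset of mzML this package itself emits is read and written here.

.b64_encode_doubles <- function(x) {
  gsub("[\r\n]", "", jsonlite::base64_enc(writeBin(as.double(x), raw(),
                                                   size = 8L,
                                                   endian = "little")))
}

.b64_decode_doubles <- function(txt, n) {
  raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
  readBin(raw, what = "double", n = n, size = 8L, endian = "little")
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.binary_array_xml <- function(values, accession, name) {
  b64 <- .b64_encode_doubles(values)
  paste0(
    '      <binaryDataArray encodedLength="', nchar(b64), '">\n',
    '        <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
    '        <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
    '        <cvParam cvRef="MS" accession="', accession, '" name="', name,
    '" value=""/>\n',
    '        <binary>', b64, '</binary>\n',
    '      </binaryDataArray>\n')
}

#' Write an LC-MS run to a centroided mzML file
#'
#' Emits the minimal standard-conformant subset this package reads back:
#' centroided spectra, scan start times in minutes, uncompressed 64-bit
#' float binary arrays, MS2 precursor m/z and collision energy when
#' present.
#'
#' @param run An [ms_run()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  con <- try(file(path, open = "wt", encoding = "UTF-8"), silent = TRUE)
  if (inherits(con, "try-error")) {
    stop("cannot open for writing: ", path, call. = FALSE)
  }
  on.exit(close(con))
  pol <- if (run$polarity == "positive") {
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>'
  }
  writeLines(c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '  <cvList count="1">',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '  </cvList>',
    paste0('  <run id="', .xml_escape(run$run_id), '">'),
    paste0('    <spectrumList count="', length(run$spectra), '">')), con)
  for (i in seq_along(run$spectra)) {
    sp <- run$spectra[[i]]
    n <- length(sp$mz)
    prec <- ""
    if (sp$ms_level == 2L) {
      ce <- if (!is.null(sp$collision_energy)) {
        paste0('          <activation>\n',
               '            <cvParam cvRef="MS" accession="MS:1000045" ',
               'name="collision energy" value="',
               format(sp$collision_energy, digits = 12), '" ',
               'unitName="electronvolt"/>\n          </activation>\n')
      } else ""
      si <- if (!is.null(sp$precursor_mz)) {
        paste0('          <selectedIonList count="1">\n',
               '            <selectedIon>\n',
               '              <cvParam cvRef="MS" accession="MS:1000744" ',
               'name="selected ion m/z" value="',
               format(sp$precursor_mz, digits = 15), '"/>\n',
               '            </selectedIon>\n          </selectedIonList>\n')
      } else ""
      prec <- paste0('      <precursorList count="1">\n',
                     '        <precursor>\n', si, ce,
                     '        </precursor>\n      </precursorList>\n')
    }
    writeLines(paste0(
      '      <spectrum index="', i - 1L, '" id="scan=', i,
      '" defaultArrayLength="', n, '">\n',
      '        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="',
      sp$ms_level, '"/>\n',
      '        <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
      '        ', pol, '\n',
      '        <scanList count="1">\n          <scan>\n',
      '            <cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="',
      format(sp$rt, digits = 15), '" unitName="minute"/>\n',
      '          </scan>\n        </scanList>\n',
      prec,
      '        <binaryDataArrayList count="2">\n',
      .binary_array_xml(sp$mz, "MS:1000514", "m/z array"),
      .binary_array_xml(sp$intensity, "MS:1000515", "intensity array"),
      '        </binaryDataArrayList>\n',
      '      </spectrum>'), con)
  }
  writeLines(c('    </spectrumList>', '  </run>', '</mzML>'), con)
  invisible(path)
}

.cv_value <- function(node, accession) {
  p <- xml2::xml_find_first(
    node, paste0(".//cvParam[@accession='", accession, "']"))
  if (inherits(p, "xml_missing")) return(NULL)
  xml2::xml_attr(p, "value")
}

.cv_present <- function(node, accession) {
  !inherits(xml2::xml_find_first(
    node, paste0(".//cvParam[@accession='", accession, "']")), "xml_missing")
}

#' Read a centroided mzML file
#'
#' Supports the PSI mzML subset written by [write_mzml()] plus any file
#' using uncompressed or zlib-free 64-bit float arrays and per-spectrum
#' scan start times. Profile-mode spectra are rejected.
#'
#' @param path mzML file path.
#' @return An [ms_run()] with retention times in minutes.
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("truncated or invalid mzML: ",
                                           conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  run_node <- xml2::xml_find_first(doc, ".//run")
  run_id <- if (!inherits(run_node, "xml_missing")) {
    xml2::xml_attr(run_node, "id")
  } else "run"
  sp_nodes <- xml2::xml_find_all(doc, ".//spectrum")
  if (!length(sp_nodes)) stop("no spectra", call. = FALSE)
  polarity <- "positive"
  spectra <- vector("list", length(sp_nodes))
  for (i in seq_along(sp_nodes)) {
    node <- sp_nodes[[i]]
    if (.cv_present(node, "MS:1000128")) {
      stop("profile-mode spectra are not supported (centroided data required)",
           call. = FALSE)
    }
    if (i == 1L && .cv_present(node, "MS:1000129")) polarity <- "negative"
    level <- as.integer(.cv_value(node, "MS:1000511"))
    if (!length(level) || is.na(level)) level <- 1L
    rt_node <- xml2::xml_find_first(
      node, ".//scan/cvParam[@accession='MS:1000016']")
    if (inherits(rt_node, "xml_missing")) {
      stop("spectrum ", i, " has no scan start time", call. = FALSE)
    }
    rt <- as.numeric(xml2::xml_attr(rt_node, "value"))
    unit <- xml2::xml_attr(rt_node, "unitName")
    if (!is.na(unit) && unit == "second") rt <- rt / 60
    n <- as.integer(xml2::xml_attr(node, "defaultArrayLength"))
    arrays <- xml2::xml_find_all(node, ".//binaryDataArray")
    mz <- intensity <- numeric(0)
    for (arr in arrays) {
      if (!.cv_present(arr, "MS:1000576")) {
        stop("only uncompressed binary arrays are supported", call. = FALSE)
      }
      if (!.cv_present(arr, "MS:1000523")) {
        stop("only 64-bit float binary arrays are supported", call. = FALSE)
      }
      txt <- xml2::xml_text(xml2::xml_find_first(arr, ".//binary"))
      vals <- .b64_decode_doubles(txt, n)
      if (.cv_present(arr, "MS:1000514")) mz <- vals
      if (.cv_present(arr, "MS:1000515")) intensity <- vals
    }
    if (length(mz) != n || length(intensity) != n) {
      stop("spectrum ", i, ": binary array lengths disagree with ",
           "defaultArrayLength", call. = FALSE)
    }
    prec <- ce <- NULL
    if (level == 2L) {
      v <- .cv_value(node, "MS:1000744")
      if (!is.null(v)) prec <- as.numeric(v)
      v <- .cv_value(node, "MS:1000045")
      if (!is.null(v)) ce <- as.numeric(v)
    }
    spectra[[i]] <- ms_spectrum(rt, mz, intensity, ms_level = level,
                                precursor_mz = prec, collision_energy = ce)
  }
  ms_run(spectra, run_id = run_id, polarity = polarity)
}
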