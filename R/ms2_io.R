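#' Construct an MS2 scan
#'
#' @param precursor_mz precursor ion m/z, Da.
#' @param rt scan retention time, seconds.
#' @param fragments two-column numeric matrix (\code{mz}, \code{intensity});
#'   fragments are sorted ascending by m/z on construction.
#' @param source_run identifier of the run (file) the scan came from.
#' @return An object of class \code{ms2_scan}.
#' @export
ms2_scan <- function(precursor_mz, rt, fragments, source_run = "") {
  fragments <- matrix(as.numeric(fragments), ncol = 2,
                      dimnames = list(NULL, c("mz", "intensity")))
  if (nrow(fragments) > 0) {
    if (any(fragments[, "mz"] <= 0)) stop("fragment m/z must be positive")
    fragments <- fragments[order(fragments[, "mz"]), , drop = FALSE]
  }
  structure(list(precursor_mz = precursor_mz, rt = rt,
                 fragments = fragments, source_run = source_run),
            class = "ms2_scan")
}

#' Read MS2 scans from mzML files
#'
#' Reads every MS-level-2 spectrum from centroided mzML files. Retention
#' times are normalized to seconds (the mzML unit attribute is respected by
#' the parser); MS1 scans are ignored; the source file is recorded per scan.
#'
#' @param paths character vector of mzML file paths.
#' @return List of \code{\link{ms2_scan}} objects. A file containing no MS2
#'   spectra contributes nothing and raises a warning.
#' @export
read_ms2_runs <- function(paths) {
  scans <- list()
  for (path in paths) {
    handle <- mzR::openMSfile(path)
    on.exit(mzR::close(handle), add = TRUE)
    hd <- mzR::header(handle)
    idx <- which(hd$msLevel == 2L)
    if (length(idx) == 0) {
      warning("no MS2 spectra in ", path)
      next
    }
    run <- basename(path)
    pk <- mzR::peaks(handle, idx)
    if (length(idx) == 1L) pk <- list(pk)
    for (k in seq_along(idx)) {
      i <- idx[k]
      scans[[length(scans) + 1L]] <- ms2_scan(
        precursor_mz = hd$precursorMZ[i],
        rt = hd$retentionTime[i],
        fragments = pk[[k]],
        source_run = run
      )
    }
  }
  scans
}

#' Write MS2 scans to a minimal mzML file
#'
#' Emits a small, standard-conformant mzML document (64-bit float arrays,
#' no compression, scan start time in the requested unit) carrying only
#' MS-level-2 spectra. Intended for exporting simulated fragment runs so the
#' full mzML ingestion path can be exercised without instrument data.
#'
#' @param scans list of \code{\link{ms2_scan}} objects.
#' @param path output path.
#' @param rt_unit unit used to record scan start times, \code{"second"} or
#'   \code{"minute"}; values are converted accordingly on writing.
#' @return Invisibly, \code{path}.
#' @export
write_mzml <- function(scans, path, rt_unit = c("second", "minute")) {
  rt_unit <- match.arg(rt_unit)
  acc <- if (rt_unit == "minute") "UO:0000031" else "UO:0000010"
  enc <- function(x) {
    gsub("\n", "", jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                 size = 8,
                                                 endian = "little")),
         fixed = TRUE)
  }
  spec_xml <- function(i, s) {
    rt <- if (rt_unit == "minute") s$rt / 60 else s$rt
    mzs <- enc(s$fragments[, "mz"])
    ints <- enc(s$fragments[, "intensity"])
    paste0(
      sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
              i, i + 1L, nrow(s$fragments)),
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
      sprintf(paste0('<scanList count="1"><scan><cvParam cvRef="MS" ',
                     'accession="MS:1000016" name="scan start time" ',
                     'value="%.6f" unitCvRef="UO" unitAccession="%s" ',
                     'unitName="%s"/></scan></scanList>'),
              rt, acc, rt_unit),
      sprintf(paste0('<precursorList count="1"><precursor>',
                     '<selectedIonList count="1"><selectedIon>',
                     '<cvParam cvRef="MS" accession="MS:1000744" ',
                     'name="selected ion m/z" value="%.6f"/>',
                     '</selectedIon></selectedIonList>',
                     '</precursor></precursorList>'),
              s$precursor_mz),
      '<binaryDataArrayList count="2">',
      sprintf(paste0('<binaryDataArray encodedLength="%d">',
                     '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
                     '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
                     '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
                     '<binary>%s</binary></binaryDataArray>'),
              nchar(mzs), mzs),
      sprintf(paste0('<binaryDataArray encodedLength="%d">',
                     '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
                     '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
                     '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
                     '<binary>%s</binary></binaryDataArray>'),
              nchar(ints), ints),
      '</binaryDataArrayList></spectrum>'
    )
  }
  body <- paste(vapply(seq_along(scans),
                       function(k) spec_xml(k - 1L, scans[[k]]),
                       character(1)),
                collapse = "\n")
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2"><cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="UO" URI="http://ontologies.berkeleybop.org/uo.obo"/></cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>',
    '</fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="sw" version="0.1">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="pmdda"/>',
    '</software></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC">',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
    '</instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp">',
    '<processingMethod order="1" softwareRef="sw">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="run" defaultInstrumentConfigurationRef="IC">\n',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp">\n',
            length(scans)),
    body,
    '\n</spectrumList></run></mzML>\n'
  )
  writeLines(doc, path)
  invisible(path)
}

#' Write consensus spectra to an MGF file
#'
#' Standard Mascot generic format: one \code{BEGIN IONS} block per spectrum
#' with \code{PEPMASS}, \code{RTINSECONDS} and \code{TITLE} (the MS1 feature
#' id), fragments as \code{mz intensity} lines ascending by m/z. Spectra
#' without fragments are skipped with a warning.
#'
#' @param spectra list of \code{\link{consensus_spectrum}} objects.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) {
    frag <- sp$fragments
    if (is.null(frag) || nrow(frag) == 0) {
      warning("skipping spectrum '", sp$target_feature, "': no fragments")
      next
    }
    frag <- frag[order(frag[, "mz"]), , drop = FALSE]
    writeLines(c(
      "BEGIN IONS",
      sprintf("TITLE=%s", sp$target_feature),
      sprintf("PEPMASS=%.6f", sp$precursor_mz),
      sprintf("RTINSECONDS=%.4f", sp$rt),
      sprintf("%.6f %.6f", frag[, "mz"], frag[, "intensity"]),
      "END IONS", ""
    ), con)
  }
  invisible(path)
}
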