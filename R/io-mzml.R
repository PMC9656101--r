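# Minimal mzML support: reading goes through mzR (proteowizard backend);
# only centroided MS2 scans with a selected-ion m/z are in contract. The
# writer emits a small self-contained mzML 1.1.0 document (64-bit float
# arrays, no compression) sufficient for round-tripping fixture spectra.

#' Read MS2 spectra from an mzML file
#'
#' Non-MS2 scans are ignored. Scan start times (seconds) are converted to
#' minutes. The native spectrum id is kept as the spectrum id.
#'
#' @param path Path to an mzML file.
#' @return A list of [new_spectrum()] objects (possibly empty).
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e)
                       stop("cannot parse mzML file '", path, "': ",
                            conditionMessage(e), call. = FALSE))
  on.exit(mzR::close(handle))
  hd <- mzR::header(handle)
  if (nrow(hd) == 0L) return(list())
  ms2 <- which(hd$msLevel == 2L & !is.na(hd$precursorMZ) & hd$precursorMZ > 0)
  lapply(ms2, function(i) {
    pk <- mzR::peaks(handle, i)
    rt <- hd$retentionTime[i]
    new_spectrum(spectrum_id = as.character(hd$spectrumId[i]),
                 precursor_mz = hd$precursorMZ[i],
                 rt = if (is.na(rt)) NA_real_ else rt / 60,
                 peaks = data.frame(mz = pk[, 1], intensity = pk[, 2]))
  })
}

.b64_doubles <- function(x) {
  # single-line base64: the encodedLength attribute counts characters
  gsub("\n", "", jsonlite::base64_enc(writeBin(as.double(x), raw(),
                                               size = 8L, endian = "little")),
       fixed = TRUE)
}

#' Write MS2 spectra to a minimal mzML file
#'
#' Emits an mzML 1.1.0 document with one MS2 spectrum per input: selected-ion
#' m/z, scan start time in seconds, and uncompressed little-endian 64-bit
#' float m/z / intensity arrays. Intended for fixtures and format
#' round-trips, not as a general-purpose converter.
#'
#' @param spectra List of [new_spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path) {
  spec_xml <- vapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    stopifnot(inherits(sp, "ms2_spectrum"))
    enc_mz <- .b64_doubles(sp$peaks$mz)
    enc_in <- .b64_doubles(sp$peaks$intensity)
    rt_xml <- if (is.na(sp$rt)) "" else sprintf(
      '<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/><scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.6f" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/></scan></scanList>',
      sp$rt * 60)
    sprintf(paste0(
      '<spectrum index="%d" id="%s" defaultArrayLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>',
      '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
      '%s',
      '<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>',
      '<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.6f"/>',
      '<cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="1"/>',
      '</selectedIon></selectedIonList></precursor></precursorList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/><binary>%s</binary></binaryDataArray>',
      '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/><binary>%s</binary></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, xml_escape(sp$spectrum_id), nrow(sp$peaks), rt_xml,
      sp$precursor_mz, nchar(enc_mz), enc_mz, nchar(enc_in), enc_in)
  }, character(1))

  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2"><cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/><cv id="UO" fullName="Unit Ontology" URI="http://ontologies.berkeleybop.org/uo.obo"/></cvList>\n',
    '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/></fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="aporphiner" version="0.1.0"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/></software></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="ic"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="aporphiner"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="run" defaultInstrumentConfigurationRef="ic">\n',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp">\n', length(spectra)),
    paste(spec_xml, collapse = "\n"),
    '\n</spectrumList>\n</run>\n</mzML>\n')
  writeLines(doc, path, useBytes = TRUE)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}
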