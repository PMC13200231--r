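# Minimal mzML 1.1.0 writer for centroided synthetic runs. Peak arrays
# are 64-bit little-endian floats, base64, no compression, so the files
# are plain text and read back bit-identically through mzR. mzR itself
# is read-only, hence this writer.

.b64_doubles <- function(x)
  gsub("\n", "", jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8,
                                               endian = "little")),
       fixed = TRUE)

.cv <- function(acc, name, value = "", unit = NULL) {
  u <- if (!is.null(unit))
    sprintf(' unitCvRef="%s" unitAccession="%s" unitName="%s"',
            unit[1], unit[2], unit[3]) else ""
  sprintf('<cvParam cvRef="MS" accession="%s" name="%s" value="%s"%s/>',
          acc, name, value, u)
}

.spectrum_xml <- function(scan, index) {
  pol_cv <- if (scan$polarity == "pos")
    .cv("MS:1000130", "positive scan")
  else
    .cv("MS:1000129", "negative scan")
  prec <- ""
  if (scan$ms_level == 2L) {
    half <- if (is.na(scan$isolation_width)) 0.5 else scan$isolation_width / 2
    prec <- sprintf(
      '<precursorList count="1"><precursor><isolationWindow>%s%s%s</isolationWindow><selectedIonList count="1"><selectedIon>%s</selectedIonList><activation>%s%s</activation></precursor></precursorList>',
      .cv("MS:1000827", "isolation window target m/z",
          sprintf("%.6f", scan$precursor_mz), c("MS", "MS:1000040", "m/z")),
      .cv("MS:1000828", "isolation window lower offset",
          sprintf("%.3f", half), c("MS", "MS:1000040", "m/z")),
      .cv("MS:1000829", "isolation window upper offset",
          sprintf("%.3f", half), c("MS", "MS:1000040", "m/z")),
      paste0(.cv("MS:1000744", "selected ion m/z",
                 sprintf("%.6f", scan$precursor_mz),
                 c("MS", "MS:1000040", "m/z")), "</selectedIon>"),
      .cv("MS:1000422", "beam-type collision-induced dissociation"),
      .cv("MS:1000045", "collision energy", sprintf("%g", scan$nce),
          c("UO", "UO:0000266", "electronvolt")))
  }
  mzb <- .b64_doubles(scan$mz)
  inb <- .b64_doubles(scan$intensity)
  sprintf(
    '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">%s%s%s<scanList count="1">%s<scan>%s<scanWindowList count="1"><scanWindow>%s%s</scanWindow></scanWindowList></scan></scanList>%s<binaryDataArrayList count="2"><binaryDataArray encodedLength="%d">%s%s%s<binary>%s</binary></binaryDataArray><binaryDataArray encodedLength="%d">%s%s%s<binary>%s</binary></binaryDataArray></binaryDataArrayList></spectrum>',
    index, scan$scan_id, length(scan$mz),
    .cv("MS:1000511", "ms level", scan$ms_level),
    .cv("MS:1000127", "centroid spectrum"),
    pol_cv,
    .cv("MS:1000795", "no combination"),
    .cv("MS:1000016", "scan start time", sprintf("%.8f", scan$rt),
        c("UO", "UO:0000031", "minute")),
    .cv("MS:1000501", "scan window lower limit",
        sprintf("%.4f", scan$scan_lo), c("MS", "MS:1000040", "m/z")),
    .cv("MS:1000500", "scan window upper limit",
        sprintf("%.4f", scan$scan_hi), c("MS", "MS:1000040", "m/z")),
    prec,
    nchar(mzb),
    .cv("MS:1000523", "64-bit float"),
    .cv("MS:1000576", "no compression"),
    .cv("MS:1000514", "m/z array", "", c("MS", "MS:1000040", "m/z")),
    mzb,
    nchar(inb),
    .cv("MS:1000523", "64-bit float"),
    .cv("MS:1000576", "no compression"),
    .cv("MS:1000515", "intensity array", "",
        c("MS", "MS:1000131", "number of detector counts")),
    inb)
}

#' Write scans to an mzML file
#'
#' @param scans list of `ms_scan` (e.g. from [generate_run()]).
#' @param path output path (`.mzML`).
#' @return Invisibly, `path`.
#' @export
write_run <- function(scans, path) {
  body <- vapply(seq_along(scans), function(i)
    .spectrum_xml(scans[[i]], i - 1L), character(1))
  doc <- c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="http://ontologies.berkeleybop.org/uo.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
    '</fileContent></fileDescription>',
    '<softwareList count="1"><software id="ms2curate" version="0.1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="ms2curate synthetic generator"/></software></softwareList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1">',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
    '</instrumentConfiguration></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp1"><processingMethod order="1" softwareRef="ms2curate">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>',
    sprintf('<run id="run1" defaultInstrumentConfigurationRef="IC1">'),
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp1">',
            length(scans)),
    body,
    '</spectrumList>',
    '</run>',
    '</mzML>')
  writeLines(doc, path)
  invisible(path)
}
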