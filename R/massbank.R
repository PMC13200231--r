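# MassBank flat-file record building, serialization and parsing.

#' Build a MassBank record from a consensus spectrum
#'
#' Combines the processed spectrum with compound and acquisition
#' metadata. Records from non-reference materials (confidence level
#' other than 1) are marked `"TENTATIVE"` in the record title; Level-3
#' records carry one `CH$NAME` line per unresolved isomer name. The
#' confidence level is written as a `COMMENT` following the Schymanski
#' scheme (Level 1: reference-material purity >95% with prior MS2 and
#' NMR confirmation; 2a: external library spectrum match; 2b: prior
#' MS2 annotation without library match; 3: isomers unresolved).
#'
#' @param consensus `consensus_spectrum`.
#' @param compound `compound_entry`.
#' @param acquisition named list: `instrument`, `instrument_type`,
#'   `resolution`, `chromatography` (character vector of
#'   `"SUBTAG value"` lines, optional).
#' @param accession record accession, e.g. from [make_accession()].
#' @return `massbank_record`.
#' @export
build_record <- function(consensus, compound, acquisition, accession) {
  if (is.null(consensus) || nrow(consensus$peaks) == 0L)
    stop("cannot build a record from an empty consensus spectrum")
  for (fld in c("instrument", "instrument_type"))
    if (is.null(acquisition[[fld]]))
      stop("missing required acquisition metadata field ", sQuote(fld))
  if (is.null(compound$authors)) stop("missing required metadata field 'authors'")
  type <- strsplit(consensus$type_key, "/", fixed = TRUE)[[1]]
  polarity <- type[1]
  nce <- sub("^NCE", "", type[2])
  tentative <- compound$level != "1"
  title <- paste0(
    compound$names[1], "; ", acquisition$instrument_type, "; MS2; NCE ",
    nce, "%; ", consensus$precursor_type,
    if (tentative) "; TENTATIVE" else "")
  comments <- c(
    paste0("CONFIDENCE Level ", compound$level,
           switch(compound$level,
                  "1" = " (reference material, >95% purity)",
                  "2a" = " (library spectrum match)",
                  "2b" = " (diagnostic MS2 evidence, no library match)",
                  "3" = " (tentative; unresolved isomers)")),
    paste0("ID ", compound$id))
  if (!is.null(consensus$cutoff))
    comments <- c(comments, sprintf(
      "EIC correlation cutoff %.4f (%s)", consensus$cutoff$threshold,
      consensus$cutoff$provenance))
  if (any(consensus$peaks$review))
    comments <- c(comments, sprintf(
      "REVIEW %d fragment(s) without formula but good EIC correlation",
      sum(consensus$peaks$review)))
  if (!is.null(compound$citation))
    comments <- c(comments, paste0("CITATION ", compound$citation))
  peaks <- consensus$peaks
  pk <- data.frame(mz = peaks$mz, intensity = peaks$intensity,
                   rel_int = peaks$rel_int)
  annotation <- NULL
  if (any(!is.na(peaks$formula))) {
    annotation <- data.frame(mz = peaks$mz, formula = peaks$formula,
                             stringsAsFactors = FALSE)
  }
  structure(list(
    accession = accession,
    title = title,
    date = format(Sys.Date(), "%Y.%m.%d"),
    authors = compound$authors,
    license = "CC BY",
    comments = comments,
    ch = list(names = compound$names,
              compound_class = "Natural Product",
              formula = compound$formula_str,
              exact_mass = sprintf("%.6f", monoisotopic_mass(compound$formula)),
              smiles = compound$smiles,
              links = character(0)),
    ac = list(instrument = acquisition$instrument,
              instrument_type = acquisition$instrument_type,
              mass_spectrometry = c(
                "MS_TYPE MS2",
                paste0("ION_MODE ", if (polarity == "pos") "POSITIVE" else "NEGATIVE"),
                "FRAGMENTATION_MODE HCD",
                paste0("COLLISION_ENERGY NCE ", nce, " % (HCD)"),
                if (!is.null(acquisition$resolution))
                  paste0("RESOLUTION ", acquisition$resolution)),
              chromatography = if (!is.null(acquisition$chromatography))
                acquisition$chromatography else character(0)),
    focused_ion = c(
      sprintf("PRECURSOR_M/Z %.6f", consensus$precursor_mz),
      paste0("PRECURSOR_TYPE ", consensus$precursor_type)),
    annotation = annotation,
    pk = pk,
    extras = character(0)),
    class = "massbank_record")
}

#' Generate a MassBank accession
#'
#' Pattern `MSBNK-<contributor>-<prefix><zero-padded number>`.
#'
#' @param contributor contributor code (e.g. `"Eawag"`).
#' @param n sequential number.
#' @param prefix alphanumeric prefix (default `"CM"`).
#' @param width zero-pad width (default 6).
#' @return accession string.
#' @export
make_accession <- function(contributor, n, prefix = "CM", width = 6) {
  sprintf("MSBNK-%s-%s%0*d", contributor, prefix, width, as.integer(n))
}

#' Serialize a MassBank record to flat-file text
#'
#' Fields are written in canonical MassBank order; the peak table has
#' three columns (m/z, intensity, relative intensity) with m/z printed
#' to 4 decimals; the record ends with `//`.
#'
#' @param r `massbank_record`.
#' @return single character string (lines joined by `"\n"`).
#' @export
serialize_record <- function(r) {
  out <- c(
    paste0("ACCESSION: ", r$accession),
    paste0("RECORD_TITLE: ", r$title),
    paste0("DATE: ", r$date),
    paste0("AUTHORS: ", r$authors),
    paste0("LICENSE: ", r$license),
    paste0("COMMENT: ", r$comments),
    paste0("CH$NAME: ", r$ch$names),
    paste0("CH$COMPOUND_CLASS: ", r$ch$compound_class),
    paste0("CH$FORMULA: ", r$ch$formula),
    paste0("CH$EXACT_MASS: ", r$ch$exact_mass),
    paste0("CH$SMILES: ", r$ch$smiles),
    if (length(r$ch$links)) paste0("CH$LINK: ", r$ch$links),
    paste0("AC$INSTRUMENT: ", r$ac$instrument),
    paste0("AC$INSTRUMENT_TYPE: ", r$ac$instrument_type),
    paste0("AC$MASS_SPECTROMETRY: ", r$ac$mass_spectrometry),
    if (length(r$ac$chromatography))
      paste0("AC$CHROMATOGRAPHY: ", r$ac$chromatography),
    paste0("MS$FOCUSED_ION: ", r$focused_ion),
    r$extras,
    if (!is.null(r$annotation)) c(
      "PK$ANNOTATION: m/z formula",
      sprintf("  %.4f %s", r$annotation$mz, r$annotation$formula)),
    paste0("PK$NUM_PEAK: ", nrow(r$pk)),
    "PK$PEAK: m/z int. rel.int.",
    sprintf("  %.4f %.1f %d", r$pk$mz, r$pk$intensity, as.integer(r$pk$rel_int)),
    "//")
  paste(out, collapse = "\n")
}

#' Parse a MassBank flat-file record
#'
#' Inverse of [serialize_record()]: `serialize_record(parse_record(x))`
#' reproduces `x` for records in canonical field order. Tags this
#' package does not model are preserved verbatim in `extras` and
#' re-emitted before the peak block.
#'
#' @param text record text (single string or character vector of lines).
#' @return `massbank_record`.
#' @export
parse_record <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[lines != "//"]
  tagval <- function(tag) {
    hit <- grep(paste0("^", gsub("\\$", "\\\\$", tag), ": "), lines, value = TRUE)
    sub(paste0("^", gsub("\\$", "\\\\$", tag), ": "), "", hit)
  }
  accession <- tagval("ACCESSION")
  if (length(accession) != 1L) stop("record lacks an ACCESSION line")
  # peak block
  ipk <- grep("^PK\\$PEAK:", lines)
  inum <- grep("^PK\\$NUM_PEAK:", lines)
  if (length(ipk) != 1L || length(inum) != 1L)
    stop("record lacks PK$NUM_PEAK / PK$PEAK")
  n_declared <- as.integer(sub("^PK\\$NUM_PEAK: *", "", lines[inum]))
  peak_lines <- lines[seq.int(ipk + 1L, length.out = length(lines) - ipk)]
  peak_lines <- peak_lines[nzchar(trimws(peak_lines))]
  pk <- if (length(peak_lines)) {
    m <- do.call(rbind, lapply(strsplit(trimws(peak_lines), " +"), as.numeric))
    data.frame(mz = m[, 1], intensity = m[, 2], rel_int = as.integer(m[, 3]))
  } else data.frame(mz = numeric(0), intensity = numeric(0), rel_int = integer(0))
  if (nrow(pk) != n_declared)
    stop("PK$NUM_PEAK (", n_declared, ") does not match the number of peak rows (",
         nrow(pk), ")")
  # annotation block (optional)
  annotation <- NULL
  iann <- grep("^PK\\$ANNOTATION:", lines)
  if (length(iann) == 1L) {
    j <- iann + 1L
    ann_lines <- character(0)
    while (j < inum && grepl("^  ", lines[j])) {
      ann_lines <- c(ann_lines, trimws(lines[j])); j <- j + 1L
    }
    if (length(ann_lines)) {
      parts <- strsplit(ann_lines, " +")
      annotation <- data.frame(
        mz = vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
        formula = vapply(parts, `[`, character(1), 2),
        stringsAsFactors = FALSE)
    }
  }
  known <- c("ACCESSION", "RECORD_TITLE", "DATE", "AUTHORS", "LICENSE",
             "COMMENT", "CH\\$NAME", "CH\\$COMPOUND_CLASS", "CH\\$FORMULA",
             "CH\\$EXACT_MASS", "CH\\$SMILES", "CH\\$LINK", "AC\\$INSTRUMENT",
             "AC\\$INSTRUMENT_TYPE", "AC\\$MASS_SPECTROMETRY",
             "AC\\$CHROMATOGRAPHY", "MS\\$FOCUSED_ION", "PK\\$NUM_PEAK",
             "PK\\$PEAK", "PK\\$ANNOTATION")
  head_lines <- lines[seq_len(if (length(iann) == 1L) iann - 1L else inum - 1L)]
  is_known <- Reduce(`|`, lapply(known, function(tag)
    grepl(paste0("^", tag, ": "), head_lines)))
  extras <- head_lines[!is_known & !grepl("^  ", head_lines)]
  structure(list(
    accession = accession,
    title = tagval("RECORD_TITLE"),
    date = tagval("DATE"),
    authors = tagval("AUTHORS"),
    license = tagval("LICENSE"),
    comments = tagval("COMMENT"),
    ch = list(names = tagval("CH$NAME"),
              compound_class = tagval("CH$COMPOUND_CLASS"),
              formula = tagval("CH$FORMULA"),
              exact_mass = tagval("CH$EXACT_MASS"),
              smiles = tagval("CH$SMILES"),
              links = tagval("CH$LINK")),
    ac = list(instrument = tagval("AC$INSTRUMENT"),
              instrument_type = tagval("AC$INSTRUMENT_TYPE"),
              mass_spectrometry = tagval("AC$MASS_SPECTROMETRY"),
              chromatography = tagval("AC$CHROMATOGRAPHY")),
    focused_ion = tagval("MS$FOCUSED_ION"),
    annotation = annotation,
    pk = pk,
    extras = extras),
    class = "massbank_record")
}

#' @export
print.massbank_record <- function(x, ...) {
  cat(sprintf("<massbank_record %s> %s (%d peaks)\n",
              x$accession, x$title, nrow(x$pk)))
  invisible(x)
}

#' Write MassBank records to a directory
#'
#' @param records list of `massbank_record`.
#' @param dir output directory (created if needed); one `.txt` file per
#'   record named by accession.
#' @return Invisibly, the written paths.
#' @export
write_records <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(records, function(r) {
    p <- file.path(dir, paste0(r$accession, ".txt"))
    writeLines(serialize_record(r), p)
    p
  }, character(1))
  invisible(paths)
}

#' Summarize a batch of MassBank records
#'
#' @param records list of `massbank_record` (typically several spectrum
#'   types per compound). Compound identity is taken from the `ID`
#'   COMMENT; the confidence level from the `CONFIDENCE` COMMENT.
#' @return list with `n_records`, `n_compounds`, `per_level` (named
#'   count of unique compounds per confidence level), `per_polarity`
#'   (`both` / `pos_only` / `neg_only` partition of compounds),
#'   `spectra_per_compound` (named integer vector).
#' @export
summarize_batch <- function(records) {
  if (!length(records))
    return(list(n_records = 0L, n_compounds = 0L,
                per_level = c(`1` = 0L, `2a` = 0L, `2b` = 0L, `3` = 0L),
                per_polarity = c(both = 0L, pos_only = 0L, neg_only = 0L),
                spectra_per_compound = integer(0)))
  ids <- vapply(records, function(r) {
    hit <- grep("^ID ", r$comments, value = TRUE)
    if (length(hit)) sub("^ID ", "", hit[1]) else r$accession
  }, character(1))
  levels_ <- vapply(records, function(r) {
    hit <- grep("^CONFIDENCE Level ", r$comments, value = TRUE)
    if (length(hit)) sub("^CONFIDENCE Level ([0-9ab]+).*$", "\\1", hit[1])
    else NA_character_
  }, character(1))
  pols <- vapply(records, function(r) {
    if (any(grepl("ION_MODE POSITIVE", r$ac$mass_spectrometry))) "pos" else "neg"
  }, character(1))
  uniq <- unique(ids)
  lev_per_cmpd <- vapply(uniq, function(id) levels_[match(id, ids)], character(1))
  per_level <- vapply(c("1", "2a", "2b", "3"),
                      function(l) sum(lev_per_cmpd == l, na.rm = TRUE), integer(1))
  names(per_level) <- c("1", "2a", "2b", "3")
  pol_class <- vapply(uniq, function(id) {
    p <- unique(pols[ids == id])
    if (all(c("pos", "neg") %in% p)) "both"
    else if ("pos" %in% p) "pos_only" else "neg_only"
  }, character(1))
  per_polarity <- c(both = sum(pol_class == "both"),
                    pos_only = sum(pol_class == "pos_only"),
                    neg_only = sum(pol_class == "neg_only"))
  list(n_records = length(records),
       n_compounds = length(uniq),
       per_level = per_level,
       per_polarity = per_polarity,
       spectra_per_compound = table(ids))
}
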