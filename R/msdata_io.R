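# Reading centroided mzML runs (through mzR) and the compound metadata
# table; spectrum-type classification; targeted per-compound MS2
# extraction.

#' Read all scans of a centroided mzML run
#'
#' Thin wrapper around Bioconductor's \pkg{mzR} that materialises every
#' MS1 and MS2 scan as an `ms_scan` list. Retention times are converted
#' to minutes. Profile-mode spectra are refused (centroid upstream, e.g.
#' with MSConvert vendor centroiding); MS2 scans without precursor
#' metadata are skipped with a warning.
#'
#' @param path Path to an mzML file.
#' @return List of `ms_scan` objects, each with fields `scan_id`,
#'   `ms_level`, `rt` (min), `polarity` (`"pos"`/`"neg"`), `mz`,
#'   `intensity`, `scan_lo`, `scan_hi`, and for MS2 `precursor_mz`,
#'   `isolation_width`, `nce`.
#' @export
read_raw_scans <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hd <- mzR::header(fh)
  if (nrow(hd) == 0L) return(list())
  if (any(!is.na(hd$centroided) & !hd$centroided))
    stop("profile-mode spectra found in ", basename(path),
         "; centroid the data upstream (e.g. MSConvert vendor centroiding)")
  pks <- mzR::peaks(fh)
  if (is.matrix(pks)) pks <- list(pks)
  scans <- vector("list", nrow(hd))
  keep <- logical(nrow(hd))
  n_skipped <- 0L
  for (i in seq_len(nrow(hd))) {
    lev <- hd$msLevel[i]
    if (lev == 2L && (is.na(hd$precursorMZ[i]) || hd$precursorMZ[i] <= 0)) {
      n_skipped <- n_skipped + 1L
      next
    }
    p <- pks[[i]]
    o <- order(p[, 1])
    scans[[i]] <- new_ms_scan(
      scan_id = hd$acquisitionNum[i],
      ms_level = lev,
      rt = hd$retentionTime[i] / 60,
      polarity = if (!is.na(hd$polarity[i]) && hd$polarity[i] == 0L) "neg" else "pos",
      mz = p[o, 1], intensity = p[o, 2],
      scan_lo = hd$scanWindowLowerLimit[i],
      scan_hi = hd$scanWindowUpperLimit[i],
      precursor_mz = if (lev == 2L) hd$precursorMZ[i] else NA_real_,
      isolation_width = if (lev == 2L && "isolationWindowLowerOffset" %in% names(hd))
        hd$isolationWindowLowerOffset[i] + hd$isolationWindowUpperOffset[i] else NA_real_,
      nce = if (lev == 2L) hd$collisionEnergy[i] else NA_real_)
    keep[i] <- TRUE
  }
  if (n_skipped > 0L)
    warning(n_skipped, " MS2 scan(s) without precursor metadata skipped")
  scans[keep]
}

#' Construct an `ms_scan`
#'
#' @param scan_id integer scan identifier.
#' @param ms_level 1 or 2.
#' @param rt retention time, minutes.
#' @param polarity `"pos"` or `"neg"`.
#' @param mz,intensity peak list (sorted by m/z).
#' @param scan_lo,scan_hi scan-window limits, Da.
#' @param precursor_mz,isolation_width,nce MS2 precursor metadata.
#' @return `ms_scan` object.
#' @export
new_ms_scan <- function(scan_id, ms_level, rt, polarity, mz, intensity,
                        scan_lo = NA_real_, scan_hi = NA_real_,
                        precursor_mz = NA_real_, isolation_width = NA_real_,
                        nce = NA_real_) {
  stopifnot(ms_level %in% c(1L, 2L), polarity %in% c("pos", "neg"),
            length(mz) == length(intensity), all(intensity >= 0))
  if (is.unsorted(mz)) {
    o <- order(mz); mz <- mz[o]; intensity <- intensity[o]
  }
  structure(list(scan_id = as.integer(scan_id), ms_level = as.integer(ms_level),
                 rt = rt, polarity = polarity, mz = as.numeric(mz),
                 intensity = as.numeric(intensity),
                 scan_lo = scan_lo, scan_hi = scan_hi,
                 precursor_mz = precursor_mz,
                 isolation_width = isolation_width, nce = nce),
            class = "ms_scan")
}

#' @export
print.ms_scan <- function(x, ...) {
  cat(sprintf("<ms_scan #%d> MS%d %s RT %.3f min, %d peaks\n",
              x$scan_id, x$ms_level, x$polarity, x$rt, length(x$mz)))
  invisible(x)
}

#' Index a scan list as a data frame
#'
#' @param scans List of `ms_scan`.
#' @return data.frame with one row per scan (metadata only, no peaks).
#' @export
scan_index <- function(scans) {
  data.frame(
    idx = seq_along(scans),
    scan_id = vapply(scans, `[[`, integer(1), "scan_id"),
    ms_level = vapply(scans, `[[`, integer(1), "ms_level"),
    rt = vapply(scans, `[[`, numeric(1), "rt"),
    polarity = vapply(scans, `[[`, character(1), "polarity"),
    precursor_mz = vapply(scans, `[[`, numeric(1), "precursor_mz"),
    nce = vapply(scans, `[[`, numeric(1), "nce"),
    scan_lo = vapply(scans, `[[`, numeric(1), "scan_lo"),
    stringsAsFactors = FALSE)
}

#' Classify the spectrum type of an MS2 scan
#'
#' A spectrum type is the combination (polarity, NCE, scan-range mode).
#' The scan-range mode is `"fixed40"` when the scan-window lower limit is
#' at or below `first_mass_threshold` (the acquisition fixes the first
#' mass to m/z 40), otherwise `"auto"` (window adapted per precursor).
#'
#' @param scan An MS2 `ms_scan`.
#' @param first_mass_threshold Da; default 41 (first mass 40 plus slack).
#' @return `spectrum_type` list with `polarity`, `nce`, `mode`.
#' @export
classify_spectrum_type <- function(scan, first_mass_threshold = 41) {
  if (scan$ms_level != 2L) stop("spectrum type is defined for MS2 scans only")
  mode <- if (!is.na(scan$scan_lo) && scan$scan_lo <= first_mass_threshold)
    "fixed40" else "auto"
  spectrum_type(scan$polarity, scan$nce, mode)
}

#' Construct a spectrum type
#'
#' @param polarity `"pos"` or `"neg"`.
#' @param nce normalized collision energy, %.
#' @param mode `"auto"` or `"fixed40"`.
#' @return `spectrum_type` object.
#' @export
spectrum_type <- function(polarity, nce, mode) {
  stopifnot(polarity %in% c("pos", "neg"), mode %in% c("auto", "fixed40"))
  structure(list(polarity = polarity, nce = nce, mode = mode),
            class = "spectrum_type")
}

#' Canonical key string of a spectrum type
#'
#' @param type `spectrum_type`.
#' @return e.g. `"pos/NCE30/auto"`.
#' @export
spectrum_type_key <- function(type) {
  sprintf("%s/NCE%g/%s", type$polarity, type$nce, type$mode)
}

#' @export
print.spectrum_type <- function(x, ...) {
  cat("<spectrum_type> ", spectrum_type_key(x), "\n", sep = "")
  invisible(x)
}

#' Enumerate the acquisition grid of spectrum types
#'
#' The default grid — 9 collision energies, positive and negative
#' ionization, and two MS2 scan-range modes — yields 36 distinct
#' spectrum types.
#'
#' @param nce_list NCE values, % (default
#'   `c(15, 20, 25, 30, 40, 50, 60, 70, 80)`).
#' @param polarities default `c("pos", "neg")`.
#' @param modes default `c("auto", "fixed40")`.
#' @return List of `spectrum_type`, one per grid cell.
#' @export
spectrum_type_grid <- function(nce_list = c(15, 20, 25, 30, 40, 50, 60, 70, 80),
                               polarities = c("pos", "neg"),
                               modes = c("auto", "fixed40")) {
  out <- list()
  for (p in polarities) for (n in nce_list) for (m in modes)
    out[[length(out) + 1L]] <- spectrum_type(p, n, m)
  out
}

#' Read the compound metadata table
#'
#' The table is a UTF-8 CSV with required columns `id`, `name`,
#' `smiles`, `formula`, `rt_min`, `adducts`, `level`, `authors` and an
#' optional `citation`. Multi-valued cells (isomer names of tentative
#' Level-3 entries, multiple expected adducts) are separated by `"|"`.
#' SMILES is carried as opaque metadata; the molecular formula column is
#' authoritative for mass computation.
#'
#' @param path CSV path.
#' @return List of `compound_entry`, each with parsed formula, expected
#'   `ion_spec`s and their theoretical m/z.
#' @export
read_compound_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE)
  required <- c("id", "name", "smiles", "formula", "rt_min", "adducts",
                "level", "authors")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("metadata table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    compound_entry(
      id = row$id,
      names = strsplit(row$name, "|", fixed = TRUE)[[1]],
      smiles = row$smiles,
      formula = row$formula,
      rt = as.numeric(row$rt_min),
      adducts = strsplit(row$adducts, "|", fixed = TRUE)[[1]],
      level = row$level,
      authors = row$authors,
      citation = if ("citation" %in% names(tab) && nzchar(row$citation))
        row$citation else NULL)
  })
}

#' Construct a compound entry
#'
#' @param id compound identifier.
#' @param names one or more compound names (Level-3 tentative entries
#'   may carry all unresolved isomer names).
#' @param smiles SMILES string (opaque metadata).
#' @param formula neutral molecular formula (Hill string).
#' @param rt expected retention time, minutes.
#' @param adducts expected adduct labels, e.g. `c("[M+H]+", "[M-H]-")`.
#' @param level identification confidence level: `"1"`, `"2a"`, `"2b"`
#'   or `"3"` (Schymanski scheme).
#' @param authors contributing team / authors string.
#' @param citation optional literature citation.
#' @return `compound_entry` with `expected_ions`: a list of `ion_spec`s
#'   each carrying its theoretical `mz`.
#' @export
compound_entry <- function(id, names, smiles, formula, rt, adducts, level,
                           authors, citation = NULL) {
  level <- as.character(level)
  if (!level %in% c("1", "2a", "2b", "3"))
    stop("compound ", id, ": confidence level must be one of 1, 2a, 2b, 3 (got ",
         sQuote(level), ")")
  if (length(adducts) < 1L) stop("compound ", id, ": at least one expected ion")
  if (length(names) < 1L || !any(nzchar(names)))
    stop("compound ", id, ": name required")
  fcounts <- parse_formula(formula)
  ions <- lapply(adducts, function(a) {
    spec <- parse_adduct(a)
    spec$mz <- ion_mz(fcounts, spec)
    spec$ion_formula <- ion_formula(fcounts, spec)
    spec
  })
  structure(list(id = id, names = names, smiles = smiles,
                 formula = fcounts, formula_str = format_formula(fcounts),
                 rt = rt, expected_ions = ions, level = level,
                 authors = authors, citation = citation),
            class = "compound_entry")
}

#' @export
print.compound_entry <- function(x, ...) {
  cat(sprintf("<compound %s> %s (%s), RT %.2f min, level %s\n",
              x$id, x$names[1], x$formula_str, x$rt, x$level))
  invisible(x)
}

#' Extract the MS2 spectra of one compound, grouped by spectrum type
#'
#' Selects MS2 scans whose precursor m/z lies within `mz_tol` ppm of any
#' expected ion of the compound and whose retention time is within
#' `rt_window` minutes of the compound's expected RT, then groups them
#' by spectrum type. Matching uses the selected-ion m/z reported in the
#' scan (falling back to the isolation-window centre is handled
#' upstream by the reader).
#'
#' @param scans list of `ms_scan`.
#' @param compound `compound_entry`.
#' @param mz_tol precursor match tolerance, ppm (default 10).
#' @param rt_window RT half-window, minutes (default 0.5).
#' @return Named list keyed by [spectrum_type_key()]; each element a
#'   list of matching `ms_scan`s (each annotated with attributes
#'   `type` and `matched_ion`). Empty list when the compound is not
#'   detected.
#' @export
extract_compound_spectra <- function(scans, compound, mz_tol = 10,
                                     rt_window = 0.5) {
  stopifnot(mz_tol > 0, rt_window > 0)
  out <- list()
  for (sc in scans) {
    if (sc$ms_level != 2L) next
    if (abs(sc$rt - compound$rt) > rt_window) next
    hit <- NULL
    for (ionspec in compound$expected_ions) {
      if (ionspec$polarity != sc$polarity) next
      if (abs(ppm_error(sc$precursor_mz, ionspec$mz)) <= mz_tol) {
        hit <- ionspec
        break
      }
    }
    if (is.null(hit)) next
    type <- classify_spectrum_type(sc)
    attr(sc, "type") <- type
    attr(sc, "matched_ion") <- hit
    key <- spectrum_type_key(type)
    out[[key]] <- c(out[[key]], list(sc))
  }
  # deterministic ordering regardless of input scan order
  if (length(out)) {
    out <- out[order(names(out))]
    out <- lapply(out, function(lst)
      lst[order(vapply(lst, `[[`, numeric(1), "rt"),
                vapply(lst, `[[`, integer(1), "scan_id"))])
  }
  out
}
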