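# Cross-spectrum multiplicity filtering, replicate merging into
# consensus spectra, and curator overrides.

# Group fragment rows across spectra: by assigned formula when present
# (the ion formula string, gas atoms included, is the identity), else by
# greedy m/z clustering with gap > max(tol_da, mz * tol_ppm/1e6).
# `frags` is a data.frame with columns spectrum (id), mz, formula.
fragment_groups <- function(frags, match_tol_ppm = 5, match_tol_da = 0.002) {
  n <- nrow(frags)
  group <- character(n)
  has_f <- !is.na(frags$formula)
  group[has_f] <- paste0("F:", frags$formula[has_f])
  idx <- which(!has_f)
  if (length(idx)) {
    o <- idx[order(frags$mz[idx])]
    gid <- 0L
    last_mz <- -Inf
    for (i in o) {
      tol <- max(match_tol_da, frags$mz[i] * match_tol_ppm / 1e6)
      if (frags$mz[i] - last_mz > tol) gid <- gid + 1L
      group[i] <- paste0("M:", gid)
      last_mz <- frags$mz[i]
    }
  }
  group
}

#' Multiplicity filter: keep fragments seen in at least `min_count` spectra
#'
#' Fragments are matched across all spectra of one compound (within one
#' polarity) by assigned formula when present, otherwise by m/z within
#' `max(match_tol_da, match_tol_ppm)`. Fragment groups observed in
#' fewer than `min_count` distinct spectra are removed everywhere —
#' one-off peaks are overwhelmingly noise or interference.
#'
#' @param frags data.frame with one row per fragment occurrence, columns
#'   at least `spectrum` (spectrum identifier), `mz`, `formula` (`NA`
#'   when unassigned).
#' @param min_count minimum number of distinct spectra (default 2).
#' @param match_tol_ppm,match_tol_da m/z match tolerance for unassigned
#'   peaks (defaults 5 ppm / 0.002 Da, the larger wins).
#' @return `frags` with failing rows removed and a `group` column added.
#' @export
multiplicity_filter <- function(frags, min_count = 2, match_tol_ppm = 5,
                                match_tol_da = 0.002) {
  if (nrow(frags) == 0L) {
    frags$group <- character(0)
    return(frags)
  }
  frags$group <- fragment_groups(frags, match_tol_ppm, match_tol_da)
  occ <- tapply(frags$spectrum, frags$group,
                function(s) length(unique(s)))
  keep <- frags$group %in% names(occ)[occ >= min_count]
  out <- frags[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge replicate spectra of one spectrum type into a consensus spectrum
#'
#' Surviving fragments of the replicates are matched into groups (same
#' rule as the multiplicity filter); per group the consensus m/z is the
#' intensity-weighted mean of the recalibrated m/z values, the
#' consensus intensity the arithmetic mean over the replicates where
#' the fragment occurs, and relative intensities are rescaled to the
#' MassBank 1-999 integer range (base peak = 999, floor 1).
#'
#' @param frags data.frame of surviving fragment occurrences of one
#'   (compound, spectrum type): columns `spectrum`, `mz`, `intensity`,
#'   `formula`, `gas`, `ppm`, `review` (optional), `group` (optional;
#'   recomputed when absent).
#' @param compound_id,type_key,precursor_mz,precursor_type consensus
#'   metadata.
#' @param cutoff `cutoff_result` used upstream (carried for the record
#'   COMMENT), or `NULL`.
#' @param match_tol_ppm,match_tol_da grouping tolerance for unassigned
#'   peaks.
#' @return `consensus_spectrum`: list with `compound_id`, `type_key`,
#'   `n_replicates`, `precursor_mz`, `precursor_type`, `cutoff`, and
#'   `peaks`: data.frame `mz`, `intensity`, `rel_int`, `formula`,
#'   `gas`, `review`, `n_obs`, sorted by m/z. `NULL` when no peaks
#'   survive.
#' @export
merge_replicates <- function(frags, compound_id, type_key,
                             precursor_mz = NA_real_,
                             precursor_type = NA_character_, cutoff = NULL,
                             match_tol_ppm = 5, match_tol_da = 0.002) {
  if (nrow(frags) == 0L) return(NULL)
  if (is.null(frags$group))
    frags$group <- fragment_groups(frags, match_tol_ppm, match_tol_da)
  if (is.null(frags$review)) frags$review <- FALSE
  groups <- split(frags, frags$group)
  rows <- lapply(groups, function(g) {
    data.frame(
      mz = stats::weighted.mean(g$mz, g$intensity),
      intensity = mean(g$intensity),
      formula = if (all(is.na(g$formula))) NA_character_ else
        stats::na.omit(g$formula)[1],
      gas = if (all(is.na(g$gas))) NA_character_ else
        stats::na.omit(g$gas)[1],
      review = any(g$review),
      n_obs = length(unique(g$spectrum)),
      stringsAsFactors = FALSE)
  })
  peaks <- do.call(rbind, rows)
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks$rel_int <- pmax(1L, as.integer(round(999 * peaks$intensity /
                                               max(peaks$intensity))))
  structure(list(compound_id = compound_id, type_key = type_key,
                 n_replicates = length(unique(frags$spectrum)),
                 precursor_mz = precursor_mz,
                 precursor_type = precursor_type, cutoff = cutoff,
                 peaks = peaks[, c("mz", "intensity", "rel_int", "formula",
                                   "gas", "review", "n_obs")]),
            class = "consensus_spectrum")
}

#' @export
print.consensus_spectrum <- function(x, ...) {
  cat(sprintf("<consensus %s %s> %d peaks from %d replicates\n",
              x$compound_id, x$type_key, nrow(x$peaks), x$n_replicates))
  invisible(x)
}

#' Read a curator override file
#'
#' YAML of the form
#' \preformatted{
#' compounds:
#'   CM-0001:
#'     exclude: true
#'   CM-0002:
#'     threshold: 0.9
#'     exclude_spectra: ["pos/NCE80/auto"]
#' }
#'
#' @param path YAML path.
#' @return Parsed override list (empty list for an empty file).
#' @export
read_overrides <- function(path) {
  ov <- yaml::read_yaml(path)
  if (is.null(ov)) ov <- list()
  if (is.null(ov$compounds)) ov$compounds <- list()
  ov
}

#' Apply curator overrides to curation results
#'
#' Supported per-compound overrides: `exclude` (drop the compound from
#' export), `threshold` (replace the auto EIC cutoff; categorization
#' and consensus building are rerun, provenance `"override"`),
#' `exclude_spectra` (drop spectrum types by key). Unknown compound ids
#' are an error listing the valid ids.
#'
#' @param results batch results from [run_curation()] (the `compounds`
#'   element).
#' @param overrides parsed override list from [read_overrides()].
#' @param config pipeline configuration ([curation_config()]).
#' @return Updated results list.
#' @export
apply_overrides <- function(results, overrides, config = curation_config()) {
  if (is.null(overrides$compounds) || !length(overrides$compounds))
    return(results)
  valid <- names(results)
  for (id in names(overrides$compounds)) {
    if (!id %in% valid)
      stop("override references unknown compound id ", sQuote(id),
           "; valid ids: ", paste(valid, collapse = ", "))
    ov <- overrides$compounds[[id]]
    if (isTRUE(ov$exclude)) {
      results[[id]]$status <- "excluded"
      results[[id]]$reason <- "excluded by curator override"
      results[[id]]$consensus <- list()
      next
    }
    res <- results[[id]]
    if (!is.null(ov$exclude_spectra)) {
      res$excluded_types <- as.character(ov$exclude_spectra)
    }
    if (!is.null(ov$threshold)) {
      res$cutoff$threshold <- as.numeric(ov$threshold)
      res$cutoff$provenance <- "override"
    }
    if (identical(res$status, "approved") || identical(res$status, "failed_processing"))
      res <- finalize_compound(res, config)
    results[[id]] <- res
  }
  results
}
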