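# End-to-end curation: configuration, the nine-step per-batch workflow,
# QC report and record export.

#' Pipeline configuration
#'
#' Defaults are the processing constants of the curation workflow:
#' tiered wide assignment tolerance (15 ppm at m/z <= 120, 10 ppm
#' above), calibration-point intensity >= 1e3, strict reassignment at
#' < 5 ppm, multiplicity >= 2 spectra, and EIC-correlation cutoff
#' selection by F_1.5 maximization.
#'
#' @param wide_tol_low,wide_tol_high,mass_boundary tiered first-pass
#'   assignment tolerance (ppm, ppm, Da).
#' @param tight_tol strict reassignment tolerance, ppm (exclusive).
#' @param min_calib_intensity calibration-point intensity floor, counts.
#' @param min_calib_points minimum points for the loess recalibration.
#' @param multiplicity_min_count minimum spectra per retained fragment.
#' @param match_tol_ppm,match_tol_da cross-spectrum fragment match
#'   tolerance.
#' @param precursor_tol precursor m/z match tolerance during MS2
#'   extraction, ppm.
#' @param eic_tol EIC extraction tolerance, ppm.
#' @param rt_window RT half-window for MS2 extraction, min.
#' @param beta recall weight of the F-score used for cutoff selection.
#' @param cutoff_fallback threshold when labels are degenerate.
#' @param min_corr_points minimum EIC points for a valid correlation.
#' @param strict_reference apply `strict_threshold` instead of the auto
#'   cutoff for Level-1 (reference-material) compounds.
#' @param strict_threshold the stricter preset threshold (default 0.9).
#' @param dbe_min optional RDBE candidate filter (default `NULL`, off).
#' @param contributor contributor code used in accessions.
#' @param instrument,instrument_type,resolution acquisition metadata
#'   written into records.
#' @return `curation_config` list.
#' @export
curation_config <- function(wide_tol_low = 15, wide_tol_high = 10,
                            mass_boundary = 120, tight_tol = 5,
                            min_calib_intensity = 1000,
                            min_calib_points = 10,
                            multiplicity_min_count = 2,
                            match_tol_ppm = 5, match_tol_da = 0.002,
                            precursor_tol = 10, eic_tol = 10,
                            rt_window = 0.5, beta = 1.5,
                            cutoff_fallback = 0.5, min_corr_points = 3,
                            strict_reference = FALSE,
                            strict_threshold = 0.9,
                            dbe_min = NULL,
                            contributor = "SYNBENCH",
                            instrument = "synthetic Orbitrap-class benchmark instrument",
                            instrument_type = "LC-ESI-QFT",
                            resolution = 15000) {
  structure(as.list(environment()), class = "curation_config")
}

# per-compound finalization: categorize scored fragments, keep A/B,
# drop curator-excluded spectrum types, merge replicates per type.
finalize_compound <- function(res, config = curation_config()) {
  fr <- res$frags
  if (is.null(fr) || nrow(fr) == 0L) {
    res$consensus <- list()
    res$status <- "failed_processing"
    res$reason <- "insufficient intensity of the precursor peak and/or too many interferences"
    return(res)
  }
  cats <- categorize_fragments(!is.na(fr$formula), fr$score, fr$valid,
                               res$cutoff)
  fr$category <- as.character(cats$category)
  fr$keep <- cats$keep
  fr$review <- cats$review
  res$frags <- fr
  kept <- fr[fr$keep, , drop = FALSE]
  if (!is.null(res$excluded_types) && length(res$excluded_types))
    kept <- kept[!kept$type_key %in% res$excluded_types, , drop = FALSE]
  consensus <- list()
  for (tk in sort(unique(kept$type_key))) {
    sub <- kept[kept$type_key == tk, , drop = FALSE]
    pol <- sub$polarity[1]
    ion <- res$ions[[pol]]
    cs <- merge_replicates(
      sub[, c("spectrum", "mz", "intensity", "formula", "gas", "review",
              "group")],
      compound_id = res$id, type_key = tk,
      precursor_mz = ion$mz, precursor_type = ion$label,
      cutoff = res$cutoff,
      match_tol_ppm = config$match_tol_ppm,
      match_tol_da = config$match_tol_da)
    if (!is.null(cs)) {
      cs$precursor_obs_mz <- ion$obs_mz
      cs$precursor_recal_mz <- ion$recal_mz
      consensus[[tk]] <- cs
    }
  }
  res$consensus <- consensus
  if (length(consensus)) {
    res$status <- "approved"
    res$reason <- NA_character_
  } else {
    res$status <- "failed_processing"
    res$reason <- "insufficient intensity of the precursor peak and/or too many interferences"
  }
  res
}

#' Run the full curation workflow on a batch
#'
#' Steps, per batch: (1) targeted MS2 extraction per metadata compound;
#' (2) fragment formula assignment at tiered wide tolerance; (3)
#' recalibration-curve fit per ionization mode from uniquely assigned
#' peaks with intensity >= 1e3; (4) recalibration of all spectra; (5)
#' strict subformula reassignment (< 5 ppm); (6) collision-gas (N2/O)
#' adduct check for still-unassigned fragments; (7) multiplicity filter
#' (fragment in >= 2 spectra); (8) EIC-correlation scoring with
#' automatic F_1.5-maximizing cutoff per compound; (9) categorization,
#' curator overrides, consensus merging and MassBank export. A failure
#' in one compound is recorded and does not abort the batch.
#'
#' @param mzml_paths character vector of mzML files.
#' @param metadata_path compound metadata CSV.
#' @param out_dir output directory (records/, qc/, summary, log); `NULL`
#'   to skip writing.
#' @param config [curation_config()].
#' @param overrides_path optional curator override YAML.
#' @return list: `compounds` (per-compound results with status
#'   `approved` / `not_detected` / `failed_processing` / `excluded`),
#'   `records`, `summary` ([summarize_batch()]), `models` (recalibration
#'   models per polarity), `config`.
#' @export
run_curation <- function(mzml_paths, metadata_path, out_dir = NULL,
                         config = curation_config(),
                         overrides_path = NULL) {
  scans <- do.call(c, lapply(mzml_paths, read_raw_scans))
  compounds <- read_compound_table(metadata_path)
  log_lines <- c(sprintf("ms2curate run %s", format(Sys.time())),
                 sprintf("inputs: %s", paste(mzml_paths, collapse = ", ")),
                 sprintf("metadata: %s", metadata_path),
                 "config:",
                 paste0("  ", strsplit(yaml::as.yaml(
                   config[!vapply(config, is.null, logical(1))]),
                   "\n")[[1]]))
  results <- list()
  all_assignments <- list()   # wide-tolerance, for calibration points
  extracted <- list()         # per compound: list(type_key -> scans)
  for (cm in compounds) {
    sp <- extract_compound_spectra(scans, cm, mz_tol = config$precursor_tol,
                                   rt_window = config$rt_window)
    extracted[[cm$id]] <- sp
    res <- list(id = cm$id, compound = cm,
                n_spectra = sum(lengths(sp)),
                replicates = lengths(sp))
    if (!length(sp)) {
      res$status <- "not_detected"
      res$reason <- "insufficient intensity of the precursor peak and/or too many interferences"
      results[[cm$id]] <- res
      next
    }
    res$status <- "processing"
    results[[cm$id]] <- res
  }
  # step 2: wide assignment (pooled for calibration)
  for (cm in compounds) {
    if (results[[cm$id]]$status != "processing") next
    for (tk in names(extracted[[cm$id]])) {
      for (sc in extracted[[cm$id]][[tk]]) {
        pool <- attr(sc, "matched_ion")$ion_formula
        a <- assign_fragments(sc, pool, tol_ppm = NULL,
                              gas_adducts = FALSE, dbe_min = config$dbe_min,
                              tol_low = config$wide_tol_low,
                              tol_high = config$wide_tol_high,
                              boundary = config$mass_boundary)
        all_assignments[[length(all_assignments) + 1L]] <- a
      }
    }
  }
  # steps 3-4: recalibration models per ionization mode
  calib <- collect_calibration_points(all_assignments,
                                      min_intensity = config$min_calib_intensity)
  models <- list()
  for (pol in unique(vapply(scans, `[[`, character(1), "polarity"))) {
    models[[pol]] <- fit_recal_curve(calib, pol,
                                     min_points = config$min_calib_points)
    log_lines <- c(log_lines, sprintf(
      "recalibration[%s]: method=%s n=%d", pol, models[[pol]]$method,
      models[[pol]]$n))
  }
  # steps 5-8 per compound; a failure is recorded, not fatal to the batch
  for (cm in compounds) {
    res <- results[[cm$id]]
    if (res$status != "processing") next
    results[[cm$id]] <- tryCatch(
      .process_compound(cm, res, extracted[[cm$id]], models, scans, config),
      error = function(e) {
        res$status <- "failed_processing"
        res$reason <- conditionMessage(e)
        res
      })
    log_lines <- c(log_lines, sprintf(
      "compound %s: %s%s", cm$id, results[[cm$id]]$status,
      if (!is.na(results[[cm$id]]$reason %||% NA_character_))
        paste0(" (", results[[cm$id]]$reason, ")") else ""))
  }
  # step 9: curator overrides
  if (!is.null(overrides_path)) {
    ov <- read_overrides(overrides_path)
    results <- apply_overrides(results, ov, config)
  }
  # export
  records <- list()
  acq <- list(instrument = config$instrument,
              instrument_type = config$instrument_type,
              resolution = config$resolution)
  n_acc <- 0L
  for (res in results) {
    if (!identical(res$status, "approved")) next
    for (cs in res$consensus) {
      n_acc <- n_acc + 1L
      rec <- build_record(cs, res$compound, acq,
                          make_accession(config$contributor, n_acc))
      rec$comments <- c(rec$comments,
                        sprintf("PRECURSOR observed m/z %.6f; recalibrated m/z %.6f",
                                cs$precursor_obs_mz, cs$precursor_recal_mz))
      records[[length(records) + 1L]] <- rec
    }
  }
  summary <- summarize_batch(records)
  out <- list(compounds = results, records = records, summary = summary,
              models = models, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_records(records, file.path(out_dir, "records"))
    dir.create(file.path(out_dir, "qc"), showWarnings = FALSE)
    for (res in results) {
      if (is.null(res$frags) || !nrow(res$frags)) next
      utils::write.table(
        res$frags, file.path(out_dir, "qc", paste0(res$id, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
    status_tab <- data.frame(
      id = vapply(results, `[[`, character(1), "id"),
      status = vapply(results, `[[`, character(1), "status"),
      reason = vapply(results, function(r) r$reason %||% NA_character_,
                      character(1)),
      n_spectra = vapply(results, function(r) as.integer(r$n_spectra %||% 0L),
                         integer(1)),
      n_records = vapply(results, function(r)
        length(r$consensus %||% list()), integer(1)))
    utils::write.table(status_tab, file.path(out_dir, "batch_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
    manifest <- list(
      inputs = list(mzml = mzml_paths, metadata = metadata_path,
                    overrides = overrides_path),
      md5 = as.list(tools::md5sum(c(mzml_paths, metadata_path))),
      config = config[!vapply(config, is.null, logical(1))],
      package_version = as.character(utils::packageVersion("ms2curate")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# steps 5-8 for one detected compound: recalibrate, reassign strictly,
# multiplicity-filter, score EIC co-elution, pick the cutoff, finalize.
.process_compound <- function(cm, res, sp, models, scans, config) {
  frag_rows <- list()
  ions <- list()
  for (tk in names(sp)) {
    for (i in seq_along(sp[[tk]])) {
      sc <- sp[[tk]][[i]]
      ion <- attr(sc, "matched_ion")
      rsc <- apply_recalibration(sc, models[[sc$polarity]])
      sp[[tk]][[i]] <- rsc
      a <- reassign_tight(rsc, ion$ion_formula, tol_ppm = config$tight_tol,
                          dbe_min = config$dbe_min)
      if (is.null(ions[[sc$polarity]])) {
        ions[[sc$polarity]] <- list(label = ion$label, mz = ion$mz,
                                    obs = sc$precursor_mz)
      } else {
        ions[[sc$polarity]]$obs <- c(ions[[sc$polarity]]$obs, sc$precursor_mz)
      }
      if (nrow(a) == 0L) next
      frag_rows[[length(frag_rows) + 1L]] <- data.frame(
        spectrum = attr(a, "scan_id"), type_key = tk,
        rt = attr(a, "rt"), polarity = sc$polarity,
        mz = a$mz, intensity = a$intensity, formula = a$formula,
        gas = a$gas, ppm = a$ppm, stringsAsFactors = FALSE)
    }
  }
  for (pol in names(ions)) {
    obs <- stats::median(ions[[pol]]$obs)
    ions[[pol]]$obs_mz <- obs
    ions[[pol]]$recal_mz <- obs / (1 + models[[pol]]$predict(obs) / 1e6)
  }
  res$ions <- ions
  fr <- if (length(frag_rows)) do.call(rbind, frag_rows) else data.frame()
  # step 7: multiplicity filter, within polarity
  if (nrow(fr)) {
    fr <- do.call(rbind, lapply(split(fr, fr$polarity), function(sub)
      multiplicity_filter(sub, min_count = config$multiplicity_min_count,
                          match_tol_ppm = config$match_tol_ppm,
                          match_tol_da = config$match_tol_da)))
    rownames(fr) <- NULL
  }
  if (!nrow(fr)) {
    res$frags <- fr
    res$status <- "failed_processing"
    res$reason <- "insufficient intensity of the precursor peak and/or too many interferences"
    return(res)
  }
  # step 8: EIC correlation per (fragment group, spectrum type)
  scores <- rep(0, nrow(fr)); valid <- rep(FALSE, nrow(fr))
  unit_score <- numeric(0); unit_label <- logical(0)
  for (pol in unique(fr$polarity)) {
    prec_trace <- extract_eic(
      scans, ions[[pol]]$mz, config$eic_tol, ms_level = 1L, polarity = pol,
      rt_range = c(cm$rt - config$rt_window, cm$rt + config$rt_window))
    sel_pol <- fr$polarity == pol
    for (g in unique(fr$group[sel_pol])) {
      for (tk in unique(fr$type_key[sel_pol & fr$group == g])) {
        rows <- which(sel_pol & fr$group == g & fr$type_key == tk)
        gmz <- stats::weighted.mean(fr$mz[rows], fr$intensity[rows])
        ftrace <- extract_eic(sp[[tk]], gmz, config$eic_tol, ms_level = 2L)
        cs <- correlate_traces(ftrace, prec_trace,
                               min_points = config$min_corr_points)
        scores[rows] <- cs$score
        valid[rows] <- cs$valid
        if (cs$valid) {
          unit_score <- c(unit_score, cs$score)
          unit_label <- c(unit_label, !is.na(fr$formula[rows[1]]))
        }
      }
    }
  }
  fr$score <- scores
  fr$valid <- valid
  res$frags <- fr
  if (length(unit_score) && length(unique(unit_label)) >= 1L) {
    res$cutoff <- determine_cutoff(unit_score, unit_label,
                                   scope = "compound", beta = config$beta,
                                   fallback = config$cutoff_fallback)
  } else {
    res$cutoff <- structure(
      list(threshold = config$cutoff_fallback, f_score = NA_real_,
           precision = NA_real_, recall = NA_real_, n_pos = 0L, n_neg = 0L,
           scope = "compound", provenance = "auto-degenerate"),
      class = "cutoff_result")
  }
  if (isTRUE(config$strict_reference) && cm$level == "1" &&
      res$cutoff$threshold < config$strict_threshold) {
    res$cutoff$threshold <- config$strict_threshold
    res$cutoff$provenance <- "strict-reference-preset"
  }
  finalize_compound(res, config)
}

#' Generate a synthetic batch on disk
#'
#' Writes an mzML run, the ground-truth TSV, a metadata CSV consistent
#' with the planted compounds, and the parameters as YAML, so the
#' output feeds straight into [run_curation()].
#'
#' @param params `synth_params()`; `seed` (if non-`NULL`) overrides the
#'   seed in `params`.
#' @param out_dir output directory.
#' @param seed optional integer seed override.
#' @return list of paths: `mzml`, `truth`, `metadata`, `params`, plus
#'   the in-memory `run`.
#' @export
run_synth <- function(params = synth_params(), out_dir, seed = NULL) {
  if (!is.null(seed)) params$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run <- generate_run(params)
  paths <- list(mzml = file.path(out_dir, "synthetic.mzML"),
                truth = file.path(out_dir, "truth.tsv"),
                metadata = file.path(out_dir, "metadata.csv"),
                params = file.path(out_dir, "params.yaml"))
  write_run(run$scans, paths$mzml)
  write_truth(run$truth, paths$truth)
  write_synth_metadata(params, paths$metadata)
  yaml::write_yaml(params[setdiff(names(params), "compounds")], paths$params)
  c(paths, list(run = run))
}
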