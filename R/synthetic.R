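# Ground-truthed synthetic LC-MS/MS acquisition generator. Emulates
# Gaussian elution peaks sampled by interleaved MS1/dd-MS2 cycles over
# the full 36-cell spectrum-type grid, NCE-dependent fragment
# intensities, a smooth m/z-dependent ppm mass-error field plus noise,
# a co-eluting interference compound inside the isolation window, and
# random noise peaks. Every generated MS2 peak carries a ground-truth
# label so each pipeline stage can be scored.

#' Synthetic acquisition parameters
#'
#' Defaults emulate the targeted Orbitrap acquisition this pipeline
#' curates: full MS1 scans interleaved with dd-MS2 scans over a grid of
#' 9 collision energies x 2 ionization modes x 2 scan-range modes (36
#' spectrum types), with enough chromatographic cycles across each
#' Gaussian elution peak to give 5-15 replicates per type; a smooth
#' mass-error field of 2 + 0.01 (m/z - 100) ppm with 0.5 ppm white
#' noise; and an interference compound co-isolated 0.4 Da from the
#' target precursor, eluting 2 peak-sigma later.
#'
#' @param seed integer random seed; the same seed reproduces the run
#'   bit for bit.
#' @param compounds list of compound specs (`id`, `name`, `formula`,
#'   `smiles`, `rt` min, `sigma` min, `apex` counts, `adducts`,
#'   `level`, `authors`); `NULL` for the two built-in compounds.
#' @param nce_list,polarities,modes acquisition grid (defaults: 9 NCEs,
#'   pos+neg, auto+fixed40 = 36 types).
#' @param n_fragments true fragments planted per compound and polarity.
#' @param cycle_time MS cycle spacing, min.
#' @param trigger_frac dd-MS2 trigger: MS2 acquired while the precursor
#'   is above this fraction of its apex (default 0.1, giving ~11
#'   replicates per type at the default sigma and cycle time).
#' @param rt_pad run extends this far beyond the first/last compound RT.
#' @param error_intercept,error_slope,error_noise_sd planted ppm error
#'   field `intercept + slope * (mz - 100) + N(0, noise_sd)`.
#' @param noise_rate expected random noise peaks per MS2 scan (Poisson).
#' @param interference list: `enabled`, `delta_rt_sigma` (RT offset in
#'   units of the target's peak sigma), `mz_offset` (Da, inside the
#'   1 Da isolation window), `n_fragments`, `intensity_frac` (apex
#'   relative to target), `shared_frac` (fraction of interference
#'   fragments reusing a true fragment m/z; default 0).
#' @param intensity_floor peaks below this intensity are not written.
#' @param ms1_window MS1 scan window, Da.
#' @return `synth_params` list.
#' @export
synth_params <- function(seed = 42, compounds = NULL,
                         nce_list = c(15, 20, 25, 30, 40, 50, 60, 70, 80),
                         polarities = c("pos", "neg"),
                         modes = c("auto", "fixed40"),
                         n_fragments = 8,
                         cycle_time = 0.02, trigger_frac = 0.1,
                         rt_pad = 0.35,
                         error_intercept = 2, error_slope = 0.01,
                         error_noise_sd = 0.5,
                         noise_rate = 2,
                         interference = list(enabled = TRUE,
                                             delta_rt_sigma = 2,
                                             mz_offset = 0.4,
                                             n_fragments = 5,
                                             intensity_frac = 0.6,
                                             shared_frac = 0),
                         intensity_floor = 100,
                         ms1_window = c(100, 1000)) {
  if (is.null(compounds)) {
    # peptide-like natural-product masses (>615 Da) so the automatic
    # scan range (first mass = precursor/15) stays above the fixed-40
    # window and the two scan modes are genuinely distinct
    compounds <- list(
      list(id = "SYN1", name = "synthetigrin A", formula = "C32H48N6O8",
           smiles = "CC(C)CC(NC(=O)C1CCCN1C(=O)CNC(=O)C(CC(C)C)NC(=O)C(C)N)C(=O)O",
           rt = 3.0, sigma = 0.05,
           apex = 1e6, adducts = c("[M+H]+", "[M-H]-"), level = "2b",
           authors = "Synthetic Benchmark Team"),
      list(id = "SYN2", name = "synthetigrin B", formula = "C36H50N6O8",
           smiles = "CC(C)CC(NC(=O)C1CCCN1C(=O)CNC(=O)C(CC2=CC=CC=C2)NC(=O)C(C)N)C(=O)O",
           rt = 3.6, sigma = 0.05,
           apex = 8e5, adducts = c("[M+H]+", "[M-H]-"), level = "1",
           authors = "Synthetic Benchmark Team"))
  }
  structure(list(seed = as.integer(seed), compounds = compounds,
                 nce_list = nce_list, polarities = polarities, modes = modes,
                 n_fragments = n_fragments, cycle_time = cycle_time,
                 trigger_frac = trigger_frac, rt_pad = rt_pad,
                 error_intercept = error_intercept, error_slope = error_slope,
                 error_noise_sd = error_noise_sd, noise_rate = noise_rate,
                 interference = interference,
                 intensity_floor = intensity_floor, ms1_window = ms1_window),
            class = "synth_params")
}

# random subformulas of `pool` (element_counts) with ion m/z >= mass_min,
# strictly smaller than the pool, all distinct
.sample_fragments <- function(pool, n, polarity, mass_min = 50) {
  pool_v <- unclass(pool)
  out <- list()
  seen <- character(0)
  tries <- 0L
  while (length(out) < n && tries < 500L) {
    tries <- tries + 1L
    p <- stats::runif(1, 0.3, 0.9)
    cnt <- vapply(pool_v, function(k) stats::rbinom(1L, k, p), integer(1))
    names(cnt) <- names(pool_v)
    cnt <- cnt[cnt > 0L]
    if (!length(cnt)) next
    if (all(names(pool_v) %in% names(cnt)) &&
        all(cnt[names(pool_v)] == pool_v)) next  # not the full precursor
    f <- as_element_counts(cnt)
    key <- format_formula(f)
    if (key %in% seen) next
    mz <- ion_formula_mz(f, polarity)
    if (mz < mass_min) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(
      formula = key, mz = mz,
      amp = stats::runif(1, 0.15, 0.9),
      center = stats::runif(1, 18, 55))
  }
  out
}

.logistic <- function(x) 1 / (1 + exp(-x))

# interference fragment m/z: random within range but, by construction,
# not explainable as a subformula of `pool` (incl. gas adducts) within
# `guard_ppm` — interference emulates fragments of an unrelated
# co-isolated species, so its peaks must not alias a true subformula at
# either the wide (15 ppm) or the strict assignment tolerance
.sample_interference_mz <- function(pool, n, polarity, lo, hi,
                                    guard_ppm = 20) {
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n && tries < 1000L) {
    tries <- tries + 1L
    mz <- stats::runif(1, lo, hi)
    if (nrow(enumerate_subformulas(pool, mz, guard_ppm, polarity,
                                   gas_adducts = TRUE)) == 0L)
      out <- c(out, mz)
  }
  out
}

#' Generate a ground-truthed synthetic run
#'
#' @param params `synth_params`.
#' @return list with `scans` (list of `ms_scan`), `truth` (data.frame:
#'   one labeled row per MS2 peak, columns `scan_id`, `compound_id`,
#'   `type_key`, `mz` (observed), `true_mz`, `intensity`, `label`
#'   (`true_fragment` / `interference` / `noise`), `formula`,
#'   `ppm_planted`), and `params`.
#' @export
generate_run <- function(params = synth_params()) {
  set.seed(params$seed)
  err_field <- function(mz) params$error_intercept +
    params$error_slope * (mz - 100)
  perturb <- function(mz) {
    e <- err_field(mz) + stats::rnorm(length(mz), 0, params$error_noise_sd)
    list(mz = mz * (1 + e / 1e6), ppm = e)
  }
  # per-compound ion models
  models <- lapply(params$compounds, function(cm) {
    neutral <- parse_formula(cm$formula)
    ions <- lapply(cm$adducts, function(a) {
      spec <- parse_adduct(a)
      pool <- ion_formula(neutral, spec)
      frags <- .sample_fragments(pool, params$n_fragments, spec$polarity)
      shared_n <- 0L
      interf <- NULL
      if (isTRUE(params$interference$enabled)) {
        prec_mz <- ion_mz(neutral, spec)
        n_if <- params$interference$n_fragments
        shared_n <- round(params$interference$shared_frac * n_if)
        own <- n_if - shared_n
        if_mz <- .sample_interference_mz(pool, own, spec$polarity,
                                         60, prec_mz - 20)
        if (shared_n > 0L && length(frags) >= shared_n)
          if_mz <- c(if_mz, vapply(frags[seq_len(shared_n)], `[[`,
                                   numeric(1), "mz"))
        interf <- list(prec_mz = prec_mz + params$interference$mz_offset,
                       frag_mz = if_mz,
                       amp = stats::runif(length(if_mz), 0.2, 0.8),
                       rt = cm$rt + params$interference$delta_rt_sigma * cm$sigma,
                       apex = cm$apex * params$interference$intensity_frac)
      }
      list(spec = spec, pool = pool, prec_mz = ion_mz(neutral, spec),
           frags = frags, interf = interf)
    })
    list(cm = cm, ions = ions)
  })
  rts <- vapply(params$compounds, `[[`, numeric(1), "rt")
  t_grid <- seq(min(rts) - params$rt_pad, max(rts) + params$rt_pad,
                by = params$cycle_time)
  gauss <- function(t, rt, sigma) exp(-(t - rt)^2 / (2 * sigma^2))
  scans <- list()
  truth <- list()
  sid <- 0L
  add_truth <- function(scan_id, compound_id, type_key, mz, true_mz,
                        intensity, label, formula, ppm) {
    truth[[length(truth) + 1L]] <<- data.frame(
      scan_id = scan_id, compound_id = compound_id, type_key = type_key,
      mz = mz, true_mz = true_mz, intensity = intensity, label = label,
      formula = formula, ppm_planted = ppm, stringsAsFactors = FALSE)
  }
  for (t in t_grid) {
    n_slots <- 2L * (1L + length(params$nce_list) * length(params$modes) *
                       length(params$compounds))
    dt <- params$cycle_time / (n_slots + 1L)
    slot <- 0L
    for (pol in params$polarities) {
      # --- MS1 full scan ---
      slot <- slot + 1L
      mzs <- numeric(0); ints <- numeric(0)
      for (md in models) {
        for (ion in md$ions) {
          if (ion$spec$polarity != pol) next
          g <- md$cm$apex * gauss(t, md$cm$rt, md$cm$sigma)
          if (g >= params$intensity_floor) {
            mzs <- c(mzs, ion$prec_mz); ints <- c(ints, g)
          }
          if (!is.null(ion$interf)) {
            gi <- ion$interf$apex * gauss(t, ion$interf$rt, md$cm$sigma)
            if (gi >= params$intensity_floor) {
              mzs <- c(mzs, ion$interf$prec_mz); ints <- c(ints, gi)
            }
          }
        }
      }
      n_noise <- stats::rpois(1, params$noise_rate)
      if (n_noise > 0L) {
        mzs <- c(mzs, stats::runif(n_noise, params$ms1_window[1],
                                   params$ms1_window[2]))
        ints <- c(ints, stats::rlnorm(n_noise, log(500), 0.7))
      }
      if (length(mzs)) {
        sid <- sid + 1L
        pp <- perturb(mzs)
        scans[[sid]] <- new_ms_scan(sid, 1L, t + slot * dt, pol, pp$mz, ints,
                                    scan_lo = params$ms1_window[1],
                                    scan_hi = params$ms1_window[2])
      }
      # --- dd-MS2 scans ---
      for (md in models) {
        g_rel <- gauss(t, md$cm$rt, md$cm$sigma)
        if (g_rel < params$trigger_frac) next
        g <- md$cm$apex * g_rel
        for (ion in md$ions) {
          if (ion$spec$polarity != pol) next
          for (nce in params$nce_list) for (mode in params$modes) {
            slot <- slot + 1L
            win_lo <- if (mode == "fixed40") 40 else ion$prec_mz / 15
            win_hi <- ion$prec_mz + 10
            tk <- sprintf("%s/NCE%g/%s", pol, nce, mode)
            mzs <- numeric(0); ints <- numeric(0)
            tmz <- numeric(0); lab <- character(0); forms <- character(0)
            # residual precursor
            surv <- g * .logistic((35 - nce) / 8)
            if (surv >= params$intensity_floor && ion$prec_mz >= win_lo) {
              mzs <- c(mzs, ion$prec_mz); ints <- c(ints, surv)
              tmz <- c(tmz, ion$prec_mz); lab <- c(lab, "true_fragment")
              forms <- c(forms, format_formula(ion$pool))
            }
            # true fragments with NCE breakdown curves
            for (fr in ion$frags) {
              fi <- g * fr$amp * .logistic((nce - fr$center) / 8)
              if (fi < params$intensity_floor || fr$mz < win_lo ||
                  fr$mz > win_hi) next
              mzs <- c(mzs, fr$mz); ints <- c(ints, fi)
              tmz <- c(tmz, fr$mz); lab <- c(lab, "true_fragment")
              forms <- c(forms, fr$formula)
            }
            # co-isolated interference fragments (shifted elution)
            if (!is.null(ion$interf)) {
              gi <- ion$interf$apex * gauss(t, ion$interf$rt, md$cm$sigma)
              for (j in seq_along(ion$interf$frag_mz)) {
                fi <- gi * ion$interf$amp[j] * .logistic((nce - 30) / 8)
                fmz <- ion$interf$frag_mz[j]
                if (fi < params$intensity_floor || fmz < win_lo ||
                    fmz > win_hi) next
                mzs <- c(mzs, fmz); ints <- c(ints, fi)
                tmz <- c(tmz, fmz); lab <- c(lab, "interference")
                forms <- c(forms, NA_character_)
              }
            }
            # random noise peaks
            n_noise <- stats::rpois(1, params$noise_rate)
            if (n_noise > 0L) {
              nz <- stats::runif(n_noise, win_lo, win_hi)
              ni <- stats::rlnorm(n_noise, log(500), 0.7)
              mzs <- c(mzs, nz); ints <- c(ints, ni)
              tmz <- c(tmz, nz); lab <- c(lab, rep("noise", n_noise))
              forms <- c(forms, rep(NA_character_, n_noise))
            }
            if (length(mzs)) {
              sid <- sid + 1L
              pp <- perturb(mzs)
              scans[[sid]] <- new_ms_scan(sid, 2L, t + slot * dt, pol,
                                          pp$mz, ints,
                                          scan_lo = win_lo, scan_hi = win_hi,
                                          precursor_mz = ion$prec_mz,
                                          isolation_width = 1.0, nce = nce)
              add_truth(sid, md$cm$id, tk, pp$mz, tmz, ints, lab, forms, pp$ppm)
            }
          }
        }
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(scan_id = integer(0), compound_id = character(0),
               type_key = character(0), mz = numeric(0), true_mz = numeric(0),
               intensity = numeric(0), label = character(0),
               formula = character(0), ppm_planted = numeric(0))
  # truth rows must follow each scan's m/z sort order used in ms_scan
  truth <- truth[order(truth$scan_id, truth$mz), ]
  rownames(truth) <- NULL
  list(scans = scans, truth = truth, params = params)
}

#' Write a metadata CSV consistent with the planted compounds
#'
#' @param params `synth_params`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_synth_metadata <- function(params, path) {
  rows <- lapply(params$compounds, function(cm) {
    data.frame(id = cm$id, name = cm$name, smiles = cm$smiles,
               formula = cm$formula, rt_min = cm$rt,
               adducts = paste(cm$adducts, collapse = "|"),
               level = cm$level, authors = cm$authors,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write the ground-truth table as TSV
#'
#' @param truth truth data.frame from [generate_run()].
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Score pipeline output against the generator's ground truth
#'
#' Exported consensus peaks are matched to the planted true fragments of
#' their compound by theoretical ion m/z (within `match_tol_da`); a
#' peak matching no true fragment is a false positive (interference or
#' noise that leaked through). Fragment identity is per (compound,
#' polarity, formula).
#'
#' @param truth truth data.frame.
#' @param records list of `massbank_record` exported by the pipeline.
#' @param match_tol_da m/z match tolerance (default 0.002 Da; consensus
#'   m/z are recalibrated so residuals are sub-mDa).
#' @return list: `precision`, `recall`, `n_exported`, `n_true_matched`,
#'   `n_planted`, `interference_leakage` (fraction of exported peaks
#'   matching a planted interference m/z).
#' @export
score_pipeline_result <- function(truth, records, match_tol_da = 0.002) {
  if (!nrow(truth)) stop("empty ground truth cannot be scored")
  true_tab <- unique(truth[truth$label == "true_fragment",
                           c("compound_id", "formula")])
  pol_of <- function(r)
    if (any(grepl("ION_MODE POSITIVE", r$ac$mass_spectrometry))) "pos" else "neg"
  true_mz_for <- function(cid, pol) {
    forms <- true_tab$formula[true_tab$compound_id == cid]
    mzv <- vapply(forms, function(f) ion_formula_mz(parse_formula(f), pol),
                  numeric(1))
    names(mzv) <- forms
    mzv
  }
  interf_mz <- unique(truth$true_mz[truth$label == "interference"])
  tp <- 0L; fp <- 0L; leak <- 0L
  matched <- character(0)
  for (r in records) {
    cid <- sub("^ID ", "", grep("^ID ", r$comments, value = TRUE)[1])
    pol <- pol_of(r)
    ref <- true_mz_for(cid, pol)
    for (i in seq_len(nrow(r$pk))) {
      d <- abs(ref - r$pk$mz[i])
      if (length(d) && min(d) <= match_tol_da) {
        tp <- tp + 1L
        matched <- union(matched, paste(cid, pol, names(ref)[which.min(d)]))
      } else {
        fp <- fp + 1L
        if (length(interf_mz) && min(abs(interf_mz - r$pk$mz[i])) <= 0.01)
          leak <- leak + 1L
      }
    }
  }
  # planted identities per polarity actually acquired
  planted <- unique(truth[truth$label == "true_fragment",
                          c("compound_id", "type_key", "formula")])
  planted$pol <- sub("/.*$", "", planted$type_key)
  planted_keys <- unique(paste(planted$compound_id, planted$pol,
                               planted$formula))
  n_exported <- tp + fp
  list(precision = if (n_exported) tp / n_exported else NA_real_,
       recall = length(matched) / length(planted_keys),
       n_exported = n_exported, n_true_matched = length(matched),
       n_planted = length(planted_keys),
       interference_leakage = if (n_exported) leak / n_exported else NA_real_)
}
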