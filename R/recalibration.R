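# Fragment formula assignment at tiered wide tolerance, mass-error
# recalibration curve fitting, spectrum recalibration and strict
# reassignment.

#' Wide-tolerance tier for a given m/z
#'
#' Assignment before recalibration uses a wider window in the low-mass
#' range, where relative (ppm) calibration errors are largest:
#' +/-15 ppm for m/z <= `boundary` (default 120, inclusive) and
#' +/-10 ppm above.
#'
#' @param mz m/z values.
#' @param tol_low ppm tolerance for the low-mass tier (default 15).
#' @param tol_high ppm tolerance above the boundary (default 10).
#' @param boundary tier boundary in Da (default 120, inclusive low).
#' @return ppm tolerance per m/z.
#' @export
wide_tolerance <- function(mz, tol_low = 15, tol_high = 10, boundary = 120) {
  ifelse(mz <= boundary, tol_low, tol_high)
}

#' Assign candidate subformulas to every fragment of an MS2 scan
#'
#' Runs [enumerate_subformulas()] per peak. With `tol_ppm = NULL` the
#' tiered wide tolerance is used (first-pass assignment); a scalar
#' `tol_ppm` applies one strict window everywhere (post-recalibration
#' reassignment).
#'
#' @param scan `ms_scan` (MS level 2).
#' @param precursor_ion `element_counts` of the full precursor ion.
#' @param tol_ppm `NULL` for the tiered wide window, else scalar ppm.
#' @param gas_adducts try N2/O/N2O collision-gas addition for peaks that
#'   have no plain subformula candidate.
#' @param dbe_min optional RDBE lower bound for candidates.
#' @param tol_low,tol_high,boundary tier parameters, see
#'   [wide_tolerance()].
#' @return data.frame (class `fragment_assignment`) with one row per
#'   peak: `mz`, `intensity`, `n_candidates`, `formula` (best candidate
#'   or `NA`), `theo_mz`, `ppm`, `gas`. Attributes: `scan_id`,
#'   `polarity`, `type_key`, `rt`.
#' @export
assign_fragments <- function(scan, precursor_ion, tol_ppm = NULL,
                             gas_adducts = FALSE, dbe_min = NULL,
                             tol_low = 15, tol_high = 10, boundary = 120) {
  stopifnot(scan$ms_level == 2L)
  n <- length(scan$mz)
  res <- data.frame(mz = scan$mz, intensity = scan$intensity,
                    n_candidates = integer(n), formula = NA_character_,
                    theo_mz = NA_real_, ppm = NA_real_,
                    gas = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tol <- if (is.null(tol_ppm))
      wide_tolerance(scan$mz[i], tol_low, tol_high, boundary) else tol_ppm
    cand <- enumerate_subformulas(precursor_ion, scan$mz[i], tol,
                                  polarity = scan$polarity,
                                  gas_adducts = FALSE, dbe_min = dbe_min)
    gas_used <- "none"
    if (nrow(cand) == 0L && gas_adducts) {
      cand <- enumerate_subformulas(precursor_ion, scan$mz[i], tol,
                                    polarity = scan$polarity,
                                    gas_adducts = TRUE, dbe_min = dbe_min)
      cand <- cand[cand$gas != "none", , drop = FALSE]
    }
    res$n_candidates[i] <- nrow(cand)
    if (nrow(cand) > 0L) {
      res$formula[i] <- cand$formula[1]
      res$theo_mz[i] <- cand$mz[1]
      res$ppm[i] <- cand$ppm[1]
      res$gas[i] <- cand$gas[1]
    }
  }
  attr(res, "scan_id") <- scan$scan_id
  attr(res, "polarity") <- scan$polarity
  attr(res, "rt") <- scan$rt
  tp <- attr(scan, "type")
  attr(res, "type_key") <- if (!is.null(tp)) spectrum_type_key(tp) else NA_character_
  class(res) <- c("fragment_assignment", "data.frame")
  res
}

#' Collect calibration points from wide-tolerance assignments
#'
#' A peak qualifies as a calibration point when it was assigned exactly
#' one candidate formula at the wide tolerance (unambiguous identity)
#' and its intensity is at least `min_intensity` (default 1e3; weak
#' peaks have poorly determined centroids).
#'
#' @param assignments list of `fragment_assignment` (one per spectrum).
#' @param min_intensity counts threshold, inclusive (default 1000).
#' @return data.frame `mz`, `ppm`, `intensity`, `scan_id`, `polarity`;
#'   one row per qualifying peak per spectrum.
#' @export
collect_calibration_points <- function(assignments, min_intensity = 1000) {
  rows <- lapply(assignments, function(a) {
    sel <- a$n_candidates == 1L & a$intensity >= min_intensity &
      !is.na(a$gas) & a$gas == "none"
    if (!any(sel)) return(NULL)
    data.frame(mz = a$mz[sel], ppm = a$ppm[sel], intensity = a$intensity[sel],
               scan_id = attr(a, "scan_id"), polarity = attr(a, "polarity"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(mz = numeric(0), ppm = numeric(0),
                      intensity = numeric(0), scan_id = integer(0),
                      polarity = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit a mass-error recalibration curve
#'
#' Models the systematic ppm error as a smooth function of m/z, one
#' model per ionization mode. With at least `min_points` calibration
#' points a robust locally weighted regression (`loess`, symmetric
#' family, degree 1, span 0.5) is used; with 1 to `min_points - 1`
#' points a constant median model; with none, the identity model
#' (predicts 0 everywhere) with a warning. Prediction outside the
#' observed m/z range clamps to the boundary value.
#'
#' @param points data.frame from [collect_calibration_points()] (only
#'   rows of `polarity` are used).
#' @param polarity `"pos"` or `"neg"`.
#' @param min_points minimum points for the local regression (default 10).
#' @param span loess span (default 0.5).
#' @return `recal_model`: list with `polarity`, `method` (`"loess"`,
#'   `"linear"` — robust-line fallback for unstable local fits —,
#'   `"median"` or `"identity"`), `n`, `sigma` (residual spread, ppm)
#'   and `predict(mz)`.
#' @export
fit_recal_curve <- function(points, polarity, min_points = 10, span = 0.5) {
  pts <- points[points$polarity == polarity, , drop = FALSE]
  n <- nrow(pts)
  if (n == 0L) {
    warning("no calibration points for polarity ", polarity,
            "; using identity recalibration")
    model <- list(polarity = polarity, method = "identity", n = 0L,
                  sigma = NA_real_, predict = function(mz) rep(0, length(mz)))
    class(model) <- "recal_model"
    return(model)
  }
  med <- stats::median(pts$ppm)
  median_model <- function() {
    model <- list(polarity = polarity, method = "median", n = n,
                  sigma = stats::mad(pts$ppm),
                  predict = function(mz) rep(med, length(mz)))
    class(model) <- "recal_model"
    model
  }
  if (n < min_points) return(median_model())
  # Collapse near-duplicate m/z (the same fragment species recurs in
  # every replicate spectrum, the residual precursor ion hundreds of
  # times): cluster within 0.005 Da and take the median error per
  # species, weighting by replicate count. Local regression on the raw
  # points would see a design dominated by a few duplicated abscissae.
  o <- order(pts$mz)
  gap <- c(TRUE, diff(pts$mz[o]) > 0.005)
  grp <- cumsum(gap)
  coll <- data.frame(
    mz = as.numeric(tapply(pts$mz[o], grp, stats::median)),
    ppm = as.numeric(tapply(pts$ppm[o], grp, stats::median)),
    w = as.numeric(tapply(pts$ppm[o], grp, length)))
  # calibration species must recur across replicate spectra: a peak that
  # is intense and "uniquely assigned" in a single scan is more often a
  # mis-assigned noise or interference hit than a real fragment
  recurrent <- coll[coll$w >= 3, , drop = FALSE]
  if (nrow(recurrent) >= 2L) coll <- recurrent
  rng <- range(pts$mz)
  srng <- range(coll$mz)
  interp_ok <- function(pred) {
    p <- pred(coll$mz)
    all(is.finite(p)) &&
      max(abs(p - coll$ppm)) < max(5, 2 * max(abs(coll$ppm)))
  }
  if (nrow(coll) >= 5L) {
    fit <- tryCatch(
      stats::loess(ppm ~ mz, data = coll, weights = coll$w,
                   span = span, degree = 1, family = "symmetric",
                   control = stats::loess.control(surface = "direct")),
      warning = function(w) NULL, error = function(e) NULL)
    if (!is.null(fit)) {
      # predictions clamp to the species range: the local fit is only
      # trusted where species exist
      pred <- function(mz) {
        mz_cl <- pmin(pmax(mz, srng[1]), srng[2])
        as.numeric(stats::predict(fit, newdata = data.frame(mz = mz_cl)))
      }
      # the smooth curve must also stay inside a margin around the span
      # of the observed errors: oscillating local fits between sparse
      # species are rejected, not applied
      grid_p <- pred(seq(srng[1], srng[2], length.out = 200))
      band <- range(coll$ppm)
      if (interp_ok(pred) && all(is.finite(grid_p)) &&
          min(grid_p) > band[1] - 2 && max(grid_p) < band[2] + 2) {
        model <- list(polarity = polarity, method = "loess", n = n,
                      sigma = stats::mad(stats::residuals(fit)),
                      predict = pred)
        class(model) <- "recal_model"
        return(model)
      }
    }
  }
  # straight line as intermediate fallback (few distinct species or an
  # unstable local fit); extrapolates across the full observed range
  lfit <- tryCatch(stats::lm(ppm ~ mz, data = coll, weights = coll$w),
                   error = function(e) NULL)
  if (!is.null(lfit) && nrow(coll) >= 2L) {
    cf <- stats::coef(lfit)
    pred <- function(mz) {
      mz_cl <- pmin(pmax(mz, rng[1]), rng[2])
      as.numeric(cf[1] + cf[2] * mz_cl)
    }
    if (interp_ok(pred)) {
      model <- list(polarity = polarity, method = "linear", n = n,
                    sigma = stats::mad(stats::residuals(lfit)),
                    predict = pred)
      class(model) <- "recal_model"
      return(model)
    }
  }
  median_model()
}

#' @export
print.recal_model <- function(x, ...) {
  cat(sprintf("<recal_model %s> method=%s, n=%d, residual spread=%.2f ppm\n",
              x$polarity, x$method, x$n,
              if (is.na(x$sigma)) NA else x$sigma))
  invisible(x)
}

#' Recalibrate the fragment m/z of an MS2 scan
#'
#' Each m/z is corrected by the model-predicted ppm error:
#' `mz_corrected = mz / (1 + predicted_ppm/1e6)`. Intensities and peak
#' order are untouched; the precursor m/z is left as acquired.
#'
#' @param scan `ms_scan`.
#' @param model `recal_model` of matching polarity.
#' @return Recalibrated `ms_scan` (attribute `recalibrated = TRUE`).
#' @export
apply_recalibration <- function(scan, model) {
  if (model$polarity != scan$polarity)
    stop("recalibration model polarity (", model$polarity,
         ") does not match scan polarity (", scan$polarity, ")")
  if (length(scan$mz)) {
    corr <- model$predict(scan$mz)
    scan$mz <- scan$mz / (1 + corr / 1e6)
  }
  attr(scan, "recalibrated") <- TRUE
  scan
}

#' Strict-tolerance subformula reassignment after recalibration
#'
#' Discards the wide-tolerance assignment and reruns the enumeration
#' with a strict window (`|error| < tol_ppm`, default 5 ppm, strict
#' inequality). Fragments still unassigned are then checked allowing
#' addition of N2 and/or O picked up from the collision gas.
#'
#' @param scan recalibrated `ms_scan`.
#' @param precursor_ion `element_counts` of the full precursor ion.
#' @param tol_ppm strict tolerance, ppm (default 5).
#' @param dbe_min optional RDBE lower bound.
#' @return `fragment_assignment` data.frame (see [assign_fragments()]).
#' @export
reassign_tight <- function(scan, precursor_ion, tol_ppm = 5, dbe_min = NULL) {
  assign_fragments(scan, precursor_ion, tol_ppm = tol_ppm,
                   gas_adducts = TRUE, dbe_min = dbe_min)
}
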