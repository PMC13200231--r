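# Orthogonal quality control by fragment-to-precursor co-elution:
# extracted-ion chromatograms, cosine correlation, automatic
# F-score-maximizing cutoff selection and fragment categorization.

#' Extract an ion chromatogram
#'
#' Sums, per qualifying scan, the intensity of all peaks within
#' `mz * (1 +/- tol_ppm/1e6)`. Scans with no matching peak contribute
#' intensity 0, so the trace has one point per qualifying scan.
#'
#' @param scans list of `ms_scan`.
#' @param mz target m/z, Da.
#' @param tol_ppm extraction tolerance, ppm.
#' @param ms_level restrict to this MS level (1 or 2).
#' @param restrict optional `spectrum_type`: only MS2 scans of that
#'   type qualify.
#' @param rt_range optional `c(lo, hi)` minutes.
#' @param polarity optional polarity filter (used for MS1 traces).
#' @return data.frame `rt`, `intensity` (class `eic_trace`), sorted by
#'   RT, with attributes `mz` and `tol_ppm`.
#' @export
extract_eic <- function(scans, mz, tol_ppm, ms_level = 1L, restrict = NULL,
                        rt_range = NULL, polarity = NULL) {
  stopifnot(tol_ppm > 0)
  lo <- mz * (1 - tol_ppm / 1e6)
  hi <- mz * (1 + tol_ppm / 1e6)
  rts <- numeric(0); ints <- numeric(0)
  for (sc in scans) {
    if (sc$ms_level != ms_level) next
    if (!is.null(polarity) && sc$polarity != polarity) next
    if (!is.null(rt_range) && (sc$rt < rt_range[1] || sc$rt > rt_range[2])) next
    if (!is.null(restrict)) {
      if (sc$ms_level != 2L) next
      tp <- attr(sc, "type")
      if (is.null(tp)) tp <- classify_spectrum_type(sc)
      if (tp$polarity != restrict$polarity || tp$nce != restrict$nce ||
          tp$mode != restrict$mode) next
    }
    sel <- sc$mz >= lo & sc$mz <= hi
    rts <- c(rts, sc$rt)
    ints <- c(ints, if (any(sel)) sum(sc$intensity[sel]) else 0)
  }
  o <- order(rts)
  out <- data.frame(rt = rts[o], intensity = ints[o])
  attr(out, "mz") <- mz
  attr(out, "tol_ppm") <- tol_ppm
  class(out) <- c("eic_trace", "data.frame")
  out
}

#' Co-elution score of a fragment trace against its precursor trace
#'
#' The precursor trace (MS1) is linearly interpolated onto the fragment
#' trace's retention times; the score is the cosine (normalized dot
#' product) of the two non-negative intensity vectors. Cosine rather
#' than Pearson is the default because the short fragment traces (5-15
#' points) make mean-centering unstable. Traces with fewer than
#' `min_points` fragment points inside the precursor's RT range, or a
#' zero-norm vector, score 0 and are flagged invalid.
#'
#' @param fragment `eic_trace` built from MS2 scans of one spectrum type.
#' @param precursor `eic_trace` built from MS1 scans.
#' @param min_points minimum usable points (default 3).
#' @param method `"cosine"` (default) or `"pearson"`.
#' @return list (class `correlation_score`): `score` in \[0, 1\], `n`
#'   (matched RT points), `valid` (FALSE when flagged).
#' @export
correlate_traces <- function(fragment, precursor, min_points = 3,
                             method = c("cosine", "pearson")) {
  method <- match.arg(method)
  if (nrow(fragment) == 0L || nrow(precursor) < 2L)
    return(structure(list(score = 0, n = 0L, valid = FALSE),
                     class = "correlation_score"))
  inside <- fragment$rt >= min(precursor$rt) & fragment$rt <= max(precursor$rt)
  n <- sum(inside)
  if (n < min_points)
    return(structure(list(score = 0, n = as.integer(n), valid = FALSE),
                     class = "correlation_score"))
  f <- fragment$intensity[inside]
  p <- stats::approx(precursor$rt, precursor$intensity,
                     xout = fragment$rt[inside], rule = 2)$y
  if (method == "cosine") {
    nf <- sqrt(sum(f^2)); np <- sqrt(sum(p^2))
    if (nf == 0 || np == 0)
      return(structure(list(score = 0, n = as.integer(n), valid = FALSE),
                       class = "correlation_score"))
    s <- sum(f * p) / (nf * np)
  } else {
    if (stats::sd(f) == 0 || stats::sd(p) == 0)
      return(structure(list(score = 0, n = as.integer(n), valid = FALSE),
                       class = "correlation_score"))
    s <- max(0, stats::cor(f, p))
  }
  structure(list(score = min(max(s, 0), 1), n = as.integer(n), valid = TRUE),
            class = "correlation_score")
}

#' F-beta score
#'
#' `F_beta = (1 + beta^2) P R / (beta^2 P + R)`; 0 when the denominator
#' is 0. `beta = 1.5` weights recall above precision, so the selected
#' cutoff prefers keeping genuine fragments over discarding dubious
#' ones.
#'
#' @param precision,recall values in \[0, 1\].
#' @param beta recall weight (default 1.5).
#' @return F-beta score.
#' @export
f_beta <- function(precision, recall, beta = 1.5) {
  den <- beta^2 * precision + recall
  ifelse(den == 0, 0, (1 + beta^2) * precision * recall / den)
}

#' Automatically select the EIC-correlation quality cutoff
#'
#' Treats "score >= t implies formula match" as a binary classifier of
#' the formula-assignment labels and picks the threshold t maximizing
#' the F-beta score (beta = 1.5). Candidate thresholds are the
#' midpoints between consecutive sorted unique scores, plus 0 and 1;
#' ties are broken toward the smallest t (retains more fragments). When
#' all labels are identical the classifier is undefined and a fallback
#' threshold is returned with provenance `"auto-degenerate"`.
#'
#' @param scores numeric vector of EIC correlation scores in \[0, 1\].
#' @param has_formula logical vector: fragment has an assigned formula.
#' @param scope `"compound"` or `"spectrum"` (bookkeeping only).
#' @param beta F-score recall weight (default 1.5).
#' @param fallback threshold when labels are degenerate (default 0.5).
#' @return `cutoff_result`: `threshold`, `f_score`, `precision`,
#'   `recall`, `n_pos`, `n_neg`, `scope`, `provenance`.
#' @export
determine_cutoff <- function(scores, has_formula, scope = "compound",
                             beta = 1.5, fallback = 0.5) {
  stopifnot(length(scores) == length(has_formula), length(scores) >= 1L)
  n_pos <- sum(has_formula); n_neg <- sum(!has_formula)
  if (n_pos == 0L || n_neg == 0L) {
    return(structure(list(threshold = fallback, f_score = NA_real_,
                          precision = NA_real_, recall = NA_real_,
                          n_pos = n_pos, n_neg = n_neg, scope = scope,
                          provenance = "auto-degenerate"),
                     class = "cutoff_result"))
  }
  u <- sort(unique(scores))
  cand <- sort(unique(c(0, 1, if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2)))
  best <- NULL
  for (t in cand) {
    pred <- scores >= t
    tp <- sum(pred & has_formula)
    fp <- sum(pred & !has_formula)
    fn <- sum(!pred & has_formula)
    p <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0L) 0 else tp / (tp + fn)
    f <- f_beta(p, r, beta)
    if (is.null(best) || f > best$f_score + 1e-12) {
      best <- list(threshold = t, f_score = f, precision = p, recall = r)
    }
  }
  structure(c(best, list(n_pos = n_pos, n_neg = n_neg, scope = scope,
                         provenance = "auto")),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("<cutoff %s/%s> t=%.3f F=%.3f P=%.3f R=%.3f (%d pos/%d neg)\n",
              x$scope, x$provenance, x$threshold,
              x$f_score, x$precision, x$recall, x$n_pos, x$n_neg))
  invisible(x)
}

#' Categorize fragments by formula assignment and EIC quality
#'
#' The four categories partition each spectrum's fragments:
#' \describe{
#'   \item{A}{formula assigned, good EIC match — exported.}
#'   \item{B}{no formula, good EIC match — exported, flagged for review
#'     (second precursor in the isolation window, or below the
#'     well-calibrated mass range).}
#'   \item{C}{formula assigned, poor EIC match — removed (spurious
#'     formula match, typically a low-mass fragment).}
#'   \item{D}{no formula, poor EIC match — removed (noise).}
#' }
#' Fragments whose correlation was invalid (too few trace points)
#' default to the poor-EIC side unless a formula was assigned, in which
#' case they are kept in A with the review flag set.
#'
#' @param has_formula logical per fragment.
#' @param scores numeric per fragment.
#' @param valid logical per fragment: correlation score usable.
#' @param cutoff `cutoff_result` (or a bare numeric threshold).
#' @return data.frame `category` (factor A/B/C/D), `keep` (A or B),
#'   `review` (B, or invalid-score A).
#' @export
categorize_fragments <- function(has_formula, scores, valid = NULL, cutoff) {
  t <- if (inherits(cutoff, "cutoff_result")) cutoff$threshold else cutoff
  n <- length(has_formula)
  if (is.null(valid)) valid <- rep(TRUE, n)
  stopifnot(length(scores) == n, length(valid) == n)
  good <- scores >= t
  cat_ <- character(n)
  review <- logical(n)
  for (i in seq_len(n)) {
    if (!valid[i]) {
      if (has_formula[i]) { cat_[i] <- "A"; review[i] <- TRUE }
      else cat_[i] <- "D"
    } else if (has_formula[i]) {
      cat_[i] <- if (good[i]) "A" else "C"
    } else {
      if (good[i]) { cat_[i] <- "B"; review[i] <- TRUE }
      else cat_[i] <- "D"
    }
  }
  data.frame(category = factor(cat_, levels = c("A", "B", "C", "D")),
             keep = cat_ %in% c("A", "B"), review = review)
}
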