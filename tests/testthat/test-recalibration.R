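fake_assignment <- function(mz, intensity, n_candidates, ppm = 0,
                            scan_id = 1L, polarity = "pos") {
  a <- data.frame(mz = mz, intensity = intensity,
                  n_candidates = as.integer(n_candidates),
                  formula = ifelse(n_candidates > 0, "C2H5O", NA),
                  theo_mz = mz, ppm = ppm,
                  gas = ifelse(n_candidates > 0, "none", NA))
  attr(a, "scan_id") <- scan_id
  attr(a, "polarity") <- polarity
  attr(a, "rt") <- 1.0
  a
}

test_that("the tiered wide tolerance is 15 ppm up to m/z 120 inclusive, 10 above", {
  expect_equal(wide_tolerance(c(50, 119.9, 120, 120.0001, 500)),
               c(15, 15, 15, 10, 10))
})

test_that("calibration points require unique assignment and intensity >= 1e3", {
  a <- fake_assignment(mz = c(100, 200, 300, 400),
                       intensity = c(5000, 999, 1000, 5000),
                       n_candidates = c(1, 1, 1, 2),
                       ppm = c(2, 3, 4, 5))
  pts <- collect_calibration_points(list(a), min_intensity = 1000)
  # 2 candidates excluded; intensity 999 excluded; 1000 is the boundary, kept
  expect_setequal(pts$mz, c(100, 300))
  expect_true(300 %in% pts$mz)
})

test_that("a constant error field is recovered to better than 0.1 ppm", {
  set.seed(2)
  pts <- data.frame(mz = stats::runif(60, 100, 900), ppm = 8.0,
                    intensity = 1e4, scan_id = 1L, polarity = "pos")
  m <- fit_recal_curve(pts, "pos")
  expect_lt(max(abs(m$predict(seq(100, 900, by = 50)) - 8.0)), 0.1)
})

test_that("degenerate point sets degrade to median and identity models", {
  none <- data.frame(mz = numeric(0), ppm = numeric(0),
                     intensity = numeric(0), scan_id = integer(0),
                     polarity = character(0))
  expect_warning(m0 <- fit_recal_curve(none, "pos"), "identity")
  expect_identical(m0$method, "identity")
  expect_equal(m0$predict(c(100, 500)), c(0, 0))
  few <- data.frame(mz = c(200, 400, 600), ppm = c(3, 5, 4),
                    intensity = 1e4, scan_id = 1L, polarity = "neg")
  mf <- fit_recal_curve(few, "neg")
  expect_identical(mf$method, "median")
  expect_equal(mf$predict(123), 4)
})

test_that("a planted linear drift field is recovered within 1 ppm", {
  set.seed(77)
  mz <- stats::runif(200, 100, 900)
  pts <- data.frame(mz = mz, ppm = 2 + 0.01 * (mz - 100) +
                      stats::rnorm(200, 0, 0.5),
                    intensity = 1e4, scan_id = 1L, polarity = "pos")
  m <- fit_recal_curve(pts, "pos")
  grid <- seq(min(mz), max(mz), length.out = 50)
  expect_lt(max(abs(m$predict(grid) - (2 + 0.01 * (grid - 100)))), 1)
})

test_that("fitting is deterministic for identical point sets", {
  set.seed(4)
  pts <- data.frame(mz = stats::runif(80, 100, 900),
                    ppm = stats::rnorm(80, 5, 1), intensity = 1e4,
                    scan_id = 1L, polarity = "pos")
  m1 <- fit_recal_curve(pts, "pos")
  m2 <- fit_recal_curve(pts, "pos")
  grid <- seq(100, 900, by = 25)
  expect_identical(m1$predict(grid), m2$predict(grid))
})

test_that("recalibration rescales m/z, keeps intensities and order", {
  sc <- new_ms_scan(1, 2, 1.0, "pos", c(100.001, 500.0050), c(10, 20),
                    scan_lo = 40, scan_hi = 600, precursor_mz = 500, nce = 30)
  ident <- structure(list(polarity = "pos", method = "identity", n = 0L,
                          sigma = NA_real_,
                          predict = function(mz) rep(0, length(mz))),
                     class = "recal_model")
  expect_identical(apply_recalibration(sc, ident)$mz, sc$mz)
  plus10 <- structure(list(polarity = "pos", method = "median", n = 5L,
                           sigma = 0,
                           predict = function(mz) rep(10, length(mz))),
                      class = "recal_model")
  out <- apply_recalibration(sc, plus10)
  expect_equal(out$mz[2], 500.0, tolerance = 1e-5)
  expect_identical(out$intensity, sc$intensity)
  wrong <- plus10; wrong$polarity <- "neg"
  expect_error(apply_recalibration(sc, wrong), "polarity")
})

test_that("strict reassignment uses an exclusive 5 ppm window", {
  pool <- ion_formula("C6H12O6", "[M+H]+")
  frag <- as_element_counts(c(C = 4, H = 7, O = 2))
  mz_true <- ion_formula_mz(frag, "pos")
  mk <- function(mz) new_ms_scan(1, 2, 1.0, "pos", mz, 1e4, scan_lo = 40,
                                 scan_hi = 200, precursor_mz = 181.07,
                                 nce = 30)
  at1ppm <- reassign_tight(mk(mz_true * (1 + 1e-6)), pool)
  expect_identical(at1ppm$formula, "C4H7O2")
  exactly5 <- reassign_tight(mk(mz_true * (1 + 5e-6)), pool)
  expect_true(is.na(exactly5$formula))
  just_under <- reassign_tight(mk(mz_true * (1 + 4.99e-6)), pool)
  expect_identical(just_under$formula, "C4H7O2")
})

test_that("unassigned fragments are rechecked with collision-gas adducts", {
  pool <- as_element_counts(c(C = 5, H = 10, O = 2))
  withN2 <- as_element_counts(c(C = 3, H = 6, N = 2, O = 1))
  sc <- new_ms_scan(1, 2, 1.0, "pos", ion_formula_mz(withN2, "pos"), 1e4,
                    scan_lo = 40, scan_hi = 200, precursor_mz = 103, nce = 30)
  a <- reassign_tight(sc, pool)
  expect_identical(a$formula, "C3H6N2O")
  expect_identical(a$gas, "N2")
})

test_that("wide assignment honors the low/high-mass tier boundary", {
  # a 12 ppm deviation is inside the window at m/z <= 120, outside above
  lowf <- as_element_counts(c(C = 5, H = 9, O = 2))   # ion ~101.06
  highf <- as_element_counts(c(C = 9, H = 17, O = 2)) # ion ~157.12
  pool <- as_element_counts(c(C = 10, H = 19, O = 3))
  mk <- function(mz) new_ms_scan(1, 2, 1.0, "pos", mz, 1e4, scan_lo = 40,
                                 scan_hi = 300, precursor_mz = 187.1, nce = 30)
  low <- assign_fragments(mk(ion_formula_mz(lowf, "pos") * (1 + 12e-6)), pool)
  expect_gt(low$n_candidates, 0)
  high <- assign_fragments(mk(ion_formula_mz(highf, "pos") * (1 + 12e-6)), pool)
  expect_false(identical(high$formula, "C9H17O2"))
})
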