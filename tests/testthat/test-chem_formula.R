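test_that("formula parsing handles Hill notation, repeats, and errors", {
  expect_equal(unclass(parse_formula("C6H12O6"))[c("C", "H", "O")],
               c(C = 6L, H = 12L, O = 6L))
  expect_equal(unclass(parse_formula("C49H74N10O12"))[["N"]], 10L)
  expect_equal(format_formula(parse_formula("C2H3NO")), "C2H3NO")
  # repeated symbols accumulate, counts of one may be omitted
  expect_equal(format_formula(parse_formula("CH3CH2OH")), "C2H6O")
  expect_error(parse_formula("C6H12X2"), "unknown element")
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("C6h12"), "malformed|unknown")
})

test_that("parse -> serialize -> parse is the identity", {
  set.seed(5)
  els <- supported_elements()
  for (rep in 1:25) {
    n <- sample(1:6, 1)
    syms <- sample(els, n)
    counts <- sample(1:40, n, replace = TRUE)
    f <- as_element_counts(stats::setNames(counts, syms))
    s <- format_formula(f)
    expect_identical(format_formula(parse_formula(s)), s)
    expect_equal(unclass(parse_formula(s)), unclass(f))
  }
})

test_that("monoisotopic masses match the independent mass-table oracle", {
  expect_identical(monoisotopic_mass(as_element_counts(NULL)), 0)
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("C6H12O6"), 180.063388, tolerance = 1e-6)
  set.seed(9)
  for (rep in 1:20) {
    syms <- sample(supported_elements(), sample(1:5, 1))
    counts <- stats::setNames(sample(1:30, length(syms), replace = TRUE), syms)
    expect_equal(monoisotopic_mass(as_element_counts(counts)),
                 oracle_mass(counts), tolerance = 1e-5)
  }
})

test_that("ion m/z includes the electron mass and handles multiply charged ions", {
  expect_equal(ion_mz("H2O", "[M+H]+"), 19.017841, tolerance = 1e-5)
  expect_equal(ion_mz("H2O", "[M-H]-"), 17.003289, tolerance = 1e-5)
  expect_equal(ion_mz("C49H74N10O12", "[M+2H]2+"), 498.281660,
               tolerance = 1e-5)
  expect_equal(ion_mz("C6H12O6", "[M+H]+"), 181.070665, tolerance = 1e-5)
  # same neutral: [M+H]+ minus [M-H]- is two protons minus two electrons
  for (f in c("C6H12O6", "C49H74N10O12", "C2H3NO")) {
    expect_equal(ion_mz(f, "[M+H]+") - ion_mz(f, "[M-H]-"),
                 2 * (1.00782503207 - 0.000548579909), tolerance = 1e-6)
  }
  expect_error(ion_mz("H2O", "[M+3H]3"), "cannot parse")
  expect_error(ion_mz("C2H2", "[M-H2O+H]+"), "removes atoms")
})

test_that("adduct labels parse to polarity, charge and atom delta", {
  a <- parse_adduct("[M+2H]2+")
  expect_equal(a$z, 2L)
  expect_equal(a$polarity, "pos")
  expect_equal(a$delta[["H"]], 2L)
  b <- parse_adduct("[M−H]−")  # typographic minus accepted
  expect_equal(b$polarity, "neg")
  expect_equal(b$delta[["H"]], -1L)
  na <- parse_adduct("[M+Na]+")
  expect_equal(na$delta[["Na"]], 1L)
  loss <- parse_adduct("[M+H-H2O]+")
  expect_equal(loss$delta[["O"]], -1L)
  expect_equal(loss$delta[["H"]], -1L)
})

test_that("ppm error is signed relative deviation", {
  expect_identical(ppm_error(100, 100), 0)
  expect_equal(ppm_error(181.072100, 181.070665), 7.93, tolerance = 0.01)
  expect_equal(ppm_error(119.999, 120.0), -8.33, tolerance = 0.01)
})

test_that("subformula enumeration finds the self-match and known fragments", {
  pool <- ion_formula("C6H12O6", "[M+H]+")  # [C6H13O6]+
  mz <- ion_mz("C6H12O6", "[M+H]+")
  cand <- enumerate_subformulas(pool, mz, 5, "pos")
  expect_true("C6H13O6" %in% cand$formula)
  expect_equal(cand$ppm[cand$formula == "C6H13O6"], 0, tolerance = 1e-6)
  # [C2H7O]+ pool at 31.017841 admits exactly the methanol cation CH3O+
  cand2 <- enumerate_subformulas(as_element_counts(c(C = 2, H = 7, O = 1)),
                                 31.017841, 5, "pos")
  expect_identical(cand2$formula, "CH3O")
})

test_that("enumeration equals the brute-force lattice oracle (<= 40 atoms)", {
  set.seed(21)
  pools <- list(c(C = 6, H = 13, O = 6), c(C = 10, H = 12, N = 2, O = 3),
                c(C = 8, H = 10, N = 4, O = 2), c(C = 5, H = 9, Cl = 1, O = 2),
                c(C = 7, H = 16, N = 1, O = 4, S = 1))
  for (pv in pools) {
    pool <- as_element_counts(pv)
    for (rep in 1:6) {
      observed <- stats::runif(1, 40, oracle_mass(pv))
      tol <- sample(c(5, 10, 15), 1)
      pol <- sample(c("pos", "neg"), 1)
      got <- sort(enumerate_subformulas(pool, observed, tol, pol)$formula)
      want <- oracle_subformulas(pv, observed, tol, pol)
      expect_identical(got, want,
                       label = sprintf("pool %s mz %.4f tol %g %s",
                                       format_formula(pool), observed, tol, pol))
    }
  }
})

test_that("widening the tolerance never removes candidates", {
  pool <- as_element_counts(c(C = 10, H = 16, N = 2, O = 4))
  set.seed(3)
  for (rep in 1:10) {
    observed <- stats::runif(1, 50, 220)
    narrow <- enumerate_subformulas(pool, observed, 5, "pos")$formula
    wide <- enumerate_subformulas(pool, observed, 15, "pos")$formula
    expect_true(all(narrow %in% wide))
  }
})

test_that("gas-adduct candidates are flagged and not duplicated", {
  pool <- as_element_counts(c(C = 5, H = 10, O = 2))
  frag <- as_element_counts(c(C = 3, H = 6, O = 1))
  target <- as_element_counts(c(C = 3, H = 6, N = 2, O = 1))  # frag + N2
  mz <- ion_formula_mz(target, "pos")
  none <- enumerate_subformulas(pool, mz, 5, "pos", gas_adducts = FALSE)
  expect_false("C3H6N2O" %in% none$formula)
  with_gas <- enumerate_subformulas(pool, mz, 5, "pos", gas_adducts = TRUE)
  hit <- with_gas[with_gas$formula == "C3H6N2O", ]
  expect_equal(nrow(hit), 1L)
  expect_identical(hit$gas, "N2")
  # a plain subformula keeps gas = "none" even when gas pools are active
  mz2 <- ion_formula_mz(frag, "pos")
  both <- enumerate_subformulas(pool, mz2, 5, "pos", gas_adducts = TRUE)
  expect_identical(both$gas[both$formula == "C3H6O"], "none")
})

test_that("the optional RDBE filter drops impossible candidates", {
  # H-saturated beyond valence: RDBE below -0.5
  pool <- as_element_counts(c(C = 2, H = 8, O = 2))
  mz <- ion_formula_mz(as_element_counts(c(C = 1, H = 6, O = 1)), "pos")
  no_filter <- enumerate_subformulas(pool, mz, 5, "pos")
  filtered <- enumerate_subformulas(pool, mz, 5, "pos", dbe_min = -0.5)
  expect_true("CH6O" %in% no_filter$formula)
  expect_false("CH6O" %in% filtered$formula)
})
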