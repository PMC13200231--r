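make_meta_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

test_that("mzML write -> read round trip preserves scans and metadata", {
  run <- generate_run(small_synth_params(seed = 31))
  path <- tempfile(fileext = ".mzML")
  write_run(run$scans, path)
  scans <- read_raw_scans(path)
  expect_length(scans, length(run$scans))
  for (i in sample(seq_along(scans), 25)) {
    expect_equal(scans[[i]]$mz, run$scans[[i]]$mz, tolerance = 1e-9)
    expect_equal(scans[[i]]$intensity, run$scans[[i]]$intensity,
                 tolerance = 1e-6)
    expect_identical(scans[[i]]$ms_level, run$scans[[i]]$ms_level)
    expect_identical(scans[[i]]$polarity, run$scans[[i]]$polarity)
    expect_equal(scans[[i]]$rt, run$scans[[i]]$rt, tolerance = 1e-6)
    if (scans[[i]]$ms_level == 2L) {
      expect_equal(scans[[i]]$precursor_mz, run$scans[[i]]$precursor_mz,
                   tolerance = 1e-5)
      expect_equal(scans[[i]]$nce, run$scans[[i]]$nce)
      expect_equal(scans[[i]]$scan_lo, run$scans[[i]]$scan_lo,
                   tolerance = 1e-3)
    }
  }
})

test_that("MS2 scans without precursor metadata are skipped with a warning", {
  run <- generate_run(small_synth_params(seed = 32))
  idx2 <- which(vapply(run$scans, `[[`, integer(1), "ms_level") == 2L)
  path <- tempfile(fileext = ".mzML")
  write_run(run$scans[c(idx2[1], idx2[2])], path)
  txt <- readLines(path)
  # strip the whole precursorList of the first MS2 spectrum only
  i <- grep("<precursorList", txt)[1]
  txt[i] <- sub("<precursorList.*?</precursorList>", "", txt[i], perl = TRUE)
  broken <- tempfile(fileext = ".mzML")
  writeLines(txt, broken)
  expect_warning(scans <- read_raw_scans(broken), "precursor")
  expect_length(scans, 1L)
})

test_that("profile-mode data are refused with centroiding advice", {
  run <- generate_run(small_synth_params(seed = 33))
  path <- tempfile(fileext = ".mzML")
  write_run(run$scans[1:2], path)
  txt <- gsub('accession="MS:1000127" name="centroid spectrum"',
              'accession="MS:1000128" name="profile spectrum"', readLines(path),
              fixed = TRUE)
  profile <- tempfile(fileext = ".mzML")
  writeLines(txt, profile)
  expect_error(read_raw_scans(profile), "centroid")
})

test_that("compound table parsing validates levels and computes ion m/z", {
  path <- make_meta_csv(data.frame(
    id = "CM1", name = "glucoside", smiles = "OCC1OC(O)C(O)C(O)C1O",
    formula = "C6H12O6", rt_min = 5.0, adducts = "[M+H]+", level = "2b",
    authors = "Team A"))
  entries <- read_compound_table(path)
  expect_length(entries, 1L)
  expect_equal(entries[[1]]$expected_ions[[1]]$mz, 181.070665,
               tolerance = 1e-5)
  expect_identical(entries[[1]]$level, "2b")

  bad <- make_meta_csv(data.frame(
    id = "CM2", name = "x", smiles = "C", formula = "C6H12O6", rt_min = 1,
    adducts = "[M+H]+", level = "4", authors = "t"))
  expect_error(read_compound_table(bad), "level")

  iso <- make_meta_csv(data.frame(
    id = "CM3", name = "isoA|isoB", smiles = "C", formula = "C6H12O6",
    rt_min = 1, adducts = "[M+H]+|[M-H]-", level = "3", authors = "t"))
  e <- read_compound_table(iso)[[1]]
  expect_identical(e$names, c("isoA", "isoB"))
  expect_length(e$expected_ions, 2L)

  nocol <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(id = "x", name = "y"), nocol, row.names = FALSE)
  expect_error(read_compound_table(nocol), "required column")
})

test_that("spectrum-type classification applies the fixed-40 window rule", {
  sc_fixed <- new_ms_scan(1, 2, 1.0, "pos", 100, 10, scan_lo = 40,
                          scan_hi = 1000, precursor_mz = 500, nce = 30)
  tp <- classify_spectrum_type(sc_fixed)
  expect_identical(tp$mode, "fixed40")
  expect_identical(spectrum_type_key(tp), "pos/NCE30/fixed40")
  sc_auto <- new_ms_scan(2, 2, 1.0, "neg", 100, 10, scan_lo = 66.4,
                         scan_hi = 996, precursor_mz = 996, nce = 80)
  expect_identical(classify_spectrum_type(sc_auto)$mode, "auto")
  sc_ms1 <- new_ms_scan(3, 1, 1.0, "pos", 100, 10)
  expect_error(classify_spectrum_type(sc_ms1), "MS2")
})

test_that("the default acquisition grid enumerates 36 distinct types", {
  grid <- spectrum_type_grid()
  keys <- vapply(grid, spectrum_type_key, character(1))
  expect_length(grid, 36L)
  expect_length(unique(keys), 36L)
})

test_that("targeted extraction groups replicates by type and is order-stable", {
  params <- small_synth_params(seed = 34)
  run <- generate_run(params)
  cm <- compound_entry("T1", "testin A", "C", params$compounds[[1]]$formula,
                       params$compounds[[1]]$rt, "[M+H]+", "2b", "t")
  sp <- extract_compound_spectra(run$scans, cm)
  expect_length(sp, 6L)  # 3 NCE x 2 modes, positive only
  expect_true(all(lengths(sp) >= 5 & lengths(sp) <= 15))
  # every extracted precursor matches a declared expected ion
  for (lst in sp) for (sc in lst)
    expect_lt(abs(ppm_error(sc$precursor_mz, cm$expected_ions[[1]]$mz)), 10)
  # shuffling the scan list changes nothing
  set.seed(1)
  sp2 <- extract_compound_spectra(sample(run$scans), cm)
  expect_identical(names(sp2), names(sp))
  ids <- function(x) lapply(x, function(l) vapply(l, `[[`, integer(1), "scan_id"))
  expect_identical(ids(sp2), ids(sp))
})

test_that("extraction of an absent compound yields an empty result", {
  run <- generate_run(small_synth_params(seed = 35))
  cm <- compound_entry("NONE", "ghost", "C", "C32H48N6O8", 99, "[M+H]+",
                       "2b", "t")
  expect_length(extract_compound_spectra(run$scans, cm), 0L)
})

test_that("co-isolated precursors 0.5 Da apart separate at 10 ppm", {
  sc <- function(id, prec) new_ms_scan(id, 2, 1.0, "pos", c(100, 150),
                                       c(10, 20), scan_lo = 40, scan_hi = 700,
                                       precursor_mz = prec, nce = 30)
  mzA <- ion_mz("C32H48N6O8", "[M+H]+")
  scans <- list(sc(1, mzA), sc(2, mzA + 0.5))
  cmA <- compound_entry("A", "a", "C", "C32H48N6O8", 1.0, "[M+H]+", "2b", "t")
  spA <- extract_compound_spectra(scans, cmA)
  got <- unlist(lapply(spA, function(l) vapply(l, `[[`, integer(1), "scan_id")))
  expect_identical(as.integer(got), 1L)
})
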