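make_consensus <- function(compound_id = "CM1", type_key = "pos/NCE30/auto",
                           n_peaks = 3) {
  peaks <- data.frame(
    mz = seq(120.05, by = 60.03, length.out = n_peaks),
    intensity = seq(1000, by = 500, length.out = n_peaks),
    rel_int = NA_integer_,
    formula = c("C4H10N", rep(NA_character_, n_peaks - 1)),
    gas = c("none", rep(NA_character_, n_peaks - 1)),
    review = rep(FALSE, n_peaks),
    n_obs = rep(3L, n_peaks))
  peaks$rel_int <- pmax(1L, as.integer(round(999 * peaks$intensity /
                                               max(peaks$intensity))))
  structure(list(compound_id = compound_id, type_key = type_key,
                 n_replicates = 5L, precursor_mz = 450.2345,
                 precursor_type = "[M+H]+",
                 cutoff = structure(list(threshold = 0.72, f_score = 0.95,
                                         precision = 1, recall = 0.9,
                                         n_pos = 10L, n_neg = 4L,
                                         scope = "compound",
                                         provenance = "auto"),
                                    class = "cutoff_result"),
                 peaks = peaks),
            class = "consensus_spectrum")
}

make_compound <- function(level = "2b", names = "examplin A") {
  compound_entry("CM1", names, "CCO", "C22H31N3O6", 4.2, "[M+H]+", level,
                 "Team X", citation = if (level == "2b") "Doe et al. 2020")
}

acq <- list(instrument = "Orbitrap bench", instrument_type = "LC-ESI-QFT",
            resolution = 15000)

# minimal record stub for batch summaries
stub_record <- function(id, level, polarity) {
  structure(list(
    accession = paste0("MSBNK-X-", id, "-", polarity),
    comments = c(paste0("CONFIDENCE Level ", level), paste0("ID ", id)),
    ac = list(mass_spectrometry = paste0(
      "ION_MODE ", if (polarity == "pos") "POSITIVE" else "NEGATIVE")),
    pk = data.frame(mz = 100.1, intensity = 10, rel_int = 999L)),
    class = "massbank_record")
}

test_that("record titles mark non-reference levels TENTATIVE", {
  r2b <- build_record(make_consensus(), make_compound("2b"), acq,
                      make_accession("X", 1))
  expect_match(r2b$title, "TENTATIVE")
  expect_match(r2b$title, "NCE 30%")
  r1 <- build_record(make_consensus(), make_compound("1"), acq,
                     make_accession("X", 2))
  expect_false(grepl("TENTATIVE", r1$title))
})

test_that("level-3 records carry one CH$NAME line per isomer name", {
  cmp <- make_compound("3", names = c("isoA", "isoB", "isoC"))
  r <- build_record(make_consensus(), cmp, acq, make_accession("X", 3))
  txt <- serialize_record(r)
  expect_equal(length(grep("^CH\\$NAME: ", strsplit(txt, "\n")[[1]])), 3L)
})

test_that("missing required metadata is a named error", {
  expect_error(
    build_record(make_consensus(), make_compound(),
                 list(instrument_type = "LC-ESI-QFT"), "MSBNK-X-1"),
    "instrument")
})

test_that("serialization is canonical and parse inverts it", {
  r <- build_record(make_consensus(n_peaks = 1), make_compound(), acq,
                    make_accession("X", 7))
  txt <- serialize_record(r)
  lines <- strsplit(txt, "\n")[[1]]
  expect_true("PK$NUM_PEAK: 1" %in% lines)
  expect_identical(lines[length(lines)], "//")
  # peak m/z printed with at least 4 decimals
  pk_line <- lines[grep("^PK\\$PEAK", lines) + 1L]
  expect_match(pk_line, "^  [0-9]+\\.[0-9]{4}")
  # round trip: serialize(parse(serialize(r))) reproduces the text
  expect_identical(serialize_record(parse_record(txt)), txt)
})

test_that("round trips hold for a variety of generated records", {
  set.seed(8)
  for (lvl in c("1", "2a", "2b", "3")) {
    r <- build_record(make_consensus(n_peaks = sample(1:6, 1)),
                      make_compound(lvl), acq,
                      make_accession("X", sample(1e4, 1)))
    txt <- serialize_record(r)
    expect_identical(serialize_record(parse_record(txt)), txt)
  }
})

test_that("parsing validates the peak count and the accession", {
  r <- build_record(make_consensus(n_peaks = 2), make_compound(), acq,
                    "MSBNK-X-A1")
  txt <- serialize_record(r)
  broken <- sub("PK\\$NUM_PEAK: 2", "PK$NUM_PEAK: 3", txt)
  expect_error(parse_record(broken), "does not match")
  no_acc <- sub("ACCESSION: MSBNK-X-A1\n", "", txt)
  expect_error(parse_record(no_acc), "ACCESSION")
})

test_that("unknown tags survive a parse -> serialize round trip", {
  r <- build_record(make_consensus(n_peaks = 1), make_compound(), acq,
                    "MSBNK-X-B1")
  lines <- strsplit(serialize_record(r), "\n")[[1]]
  i <- grep("^MS\\$FOCUSED_ION", lines)[1]
  lines <- append(lines, "MS$DATA_PROCESSING: RECALIBRATE loess", after = i)
  reparsed <- parse_record(paste(lines, collapse = "\n"))
  expect_true("MS$DATA_PROCESSING: RECALIBRATE loess" %in% reparsed$extras)
  expect_match(serialize_record(reparsed), "MS\\$DATA_PROCESSING: RECALIBRATE",
               fixed = FALSE)
})

test_that("batch summary reproduces the per-level and polarity partitions", {
  # fixture mirroring a library release with 49/37/54/10 compounds on
  # levels 1/2a/2b/3
  counts <- c(`1` = 49, `2a` = 37, `2b` = 54, `3` = 10)
  recs <- list()
  k <- 0
  for (lvl in names(counts)) for (i in seq_len(counts[[lvl]])) {
    k <- k + 1
    id <- sprintf("CMPD%03d", k)
    recs[[length(recs) + 1L]] <- stub_record(id, lvl, "pos")
    if (k %% 3 == 0)  # a third also measured in negative mode
      recs[[length(recs) + 1L]] <- stub_record(id, lvl, "neg")
  }
  s <- summarize_batch(recs)
  expect_equal(s$n_compounds, 150L)
  expect_equal(unname(s$per_level), unname(counts), ignore_attr = TRUE)
  expect_equal(sum(s$per_level), s$n_compounds)
  expect_equal(sum(s$per_polarity), s$n_compounds)
  expect_equal(unname(s$per_polarity[["both"]]), 50)
  # empty batch: all-zero summary
  s0 <- summarize_batch(list())
  expect_equal(s0$n_records, 0L)
  expect_equal(sum(s0$per_level), 0L)
})

test_that("random record fixtures partition exactly", {
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(10:40, 1)
    ids <- sprintf("C%02d", seq_len(n))
    lvls <- sample(c("1", "2a", "2b", "3"), n, replace = TRUE)
    recs <- list()
    pols_by_id <- list()
    for (i in seq_len(n)) {
      pols <- sample(list("pos", "neg", c("pos", "neg")), 1)[[1]]
      pols_by_id[[ids[i]]] <- pols
      for (p in pols)
        recs[[length(recs) + 1L]] <- stub_record(ids[i], lvls[i], p)
    }
    s <- summarize_batch(recs)
    expect_equal(s$n_compounds, n)
    expect_equal(sum(s$per_level), n)
    expect_equal(unname(s$per_polarity[["both"]]),
                 sum(vapply(pols_by_id, length, integer(1)) == 2))
  }
})
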