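# Shared synthetic fixtures. The full default benchmark (36 spectrum
# types, two compounds, interference, ~850 scans) is generated and
# curated once per test session and reused by every test that needs it.

# small, fast configuration for unit tests: one compound, positive mode,
# 3 collision energies, both scan modes
small_synth_params <- function(seed = 11, ...) {
  synth_params(
    seed = seed,
    compounds = list(
      list(id = "T1", name = "testin A", formula = "C32H48N6O8",
           smiles = "CC(C)CC(N)C(=O)O", rt = 2.0, sigma = 0.05,
           apex = 1e6, adducts = "[M+H]+", level = "2b",
           authors = "Unit Test Team")),
    nce_list = c(20, 40, 60), polarities = "pos",
    rt_pad = 0.25, ...)
}

.bench_env <- new.env(parent = emptyenv())

# default benchmark: generated, written to mzML, read back and curated
# once; returns list(run, dir, result)
default_benchmark <- function() {
  if (is.null(.bench_env$bench)) {
    dir <- file.path(tempdir(), "ms2curate-bench")
    dir.create(dir, showWarnings = FALSE)
    params <- synth_params(seed = 20240101)
    run <- generate_run(params)
    mzml <- file.path(dir, "bench.mzML")
    meta <- file.path(dir, "bench-meta.csv")
    write_run(run$scans, mzml)
    write_synth_metadata(params, meta)
    result <- run_curation(mzml, meta, out_dir = NULL)
    .bench_env$bench <- list(run = run, dir = dir, mzml = mzml,
                             meta = meta, result = result)
  }
  .bench_env$bench
}

# join a per-compound fragment table (post-curation) to the ground
# truth by (scan id, observed m/z): fragment m/z are recalibrated, so
# the match window must absorb the planted (removed) error
join_truth <- function(frags, truth, tol_da = 0.02) {
  frags$label <- NA_character_
  frags$true_formula <- NA_character_
  for (i in seq_len(nrow(frags))) {
    cand <- truth[truth$scan_id == frags$spectrum[i], ]
    if (!nrow(cand)) next
    j <- which.min(abs(cand$mz - frags$mz[i]))
    if (abs(cand$mz[j] - frags$mz[i]) < tol_da) {
      frags$label[i] <- cand$label[j]
      frags$true_formula[i] <- cand$formula[j]
    }
  }
  frags
}
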