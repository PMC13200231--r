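# Independent oracles: deliberately separate code paths (own mass
# constants, exhaustive loops) against which the package's algorithms
# are checked.

# own copy of the monoisotopic mass table (IUPAC/CIAAW)
oracle_masses <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                   O = 15.9949146196, S = 31.97207100, P = 30.97376163,
                   Cl = 34.96885268, Br = 78.9183371, Na = 22.9897692809,
                   K = 38.96370668)
oracle_e <- 0.000548579909

oracle_mass <- function(counts) {
  if (!length(counts)) return(0)
  sum(oracle_masses[names(counts)] * counts)
}

# brute-force subformula enumeration over the full element-count
# lattice (no pruning, no caching): returns sorted formula strings of
# all candidates within tol_ppm of observed_mz
oracle_subformulas <- function(pool_counts, observed_mz, tol_ppm, polarity) {
  grids <- lapply(pool_counts, function(n) 0:n)
  grid <- do.call(expand.grid, grids)
  names(grid) <- names(pool_counts)
  esign <- if (polarity == "pos") -1 else 1
  hits <- character(0)
  for (i in seq_len(nrow(grid))) {
    cnt <- unlist(grid[i, , drop = TRUE])
    cnt <- cnt[cnt > 0]
    mz <- oracle_mass(cnt) + esign * oracle_e
    if (mz <= 0) next
    if (abs((observed_mz - mz) / mz * 1e6) < tol_ppm)
      hits <- c(hits, format_formula(as_element_counts(cnt)))
  }
  sort(hits)
}

# exhaustive F-beta threshold search over every unique score, all
# midpoints, and {0, 1}; smallest maximizer wins
oracle_best_threshold <- function(scores, labels, beta = 1.5) {
  u <- sort(unique(scores))
  cand <- sort(unique(c(0, 1, u, if (length(u) > 1)
    (u[-1] + u[-length(u)]) / 2)))
  best_f <- -1; best_t <- NA
  for (t in cand) {
    pred <- scores >= t
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    fn <- sum(!pred & labels)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (beta^2 * p + r == 0) 0 else (1 + beta^2) * p * r / (beta^2 * p + r)
    if (f > best_f + 1e-12) { best_f <- f; best_t <- t }
  }
  list(threshold = best_t, f = best_f)
}

# count-and-threshold multiplicity oracle: which (spectrum, key) rows
# survive when each key must occur in >= min_count distinct spectra
oracle_multiplicity_keep <- function(spectrum, key, min_count) {
  counts <- sapply(split(spectrum, key), function(s) length(unique(s)))
  key %in% names(counts)[counts >= min_count]
}
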