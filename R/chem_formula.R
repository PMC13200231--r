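# Elemental-formula arithmetic, ion m/z computation and subformula
# enumeration. All masses are monoisotopic (most abundant isotope).

# Monoisotopic atomic masses, Da. Source: IUPAC/CIAAW 2021 atomic mass
# evaluation (AME2020), truncated to 1e-7 Da.
.MONO_MASS <- c(
  C  = 12.0000000,
  H  = 1.0078250,
  N  = 14.0030740,
  O  = 15.9949146,
  S  = 31.9720712,
  P  = 30.9737620,
  Cl = 34.9688527,
  Br = 78.9183376,
  Na = 22.9897693,
  K  = 38.9637065
)

# CODATA 2018 electron mass, Da
.ELECTRON_MASS <- 0.00054858

#' Supported element symbols
#'
#' @return Character vector of the element symbols the formula parser and
#'   mass calculator accept.
#' @export
supported_elements <- function() names(.MONO_MASS)

#' Parse a Hill-notation molecular formula
#'
#' Parses strings such as `"C6H12O6"` into a named integer vector of
#' element counts. Only the elements returned by [supported_elements()]
#' are accepted; anything else is a parse error rather than a silent
#' guess, because a wrong element implies a wrong mass.
#'
#' @param text A single non-empty formula string (Hill notation; counts
#'   of one may be omitted).
#' @return Named integer vector of element counts (class
#'   `element_counts`), in Hill order.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  text <- gsub("[[:space:]]", "", text)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (paste(toks, collapse = "") != text)
    stop("malformed formula: ", sQuote(text))
  counts <- integer(0)
  for (tok in toks) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% names(.MONO_MASS))
      stop("unknown element symbol ", sQuote(sym), " in formula ", sQuote(text))
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  as_element_counts(counts)
}

#' Construct element counts from a named vector
#'
#' @param x Named numeric/integer vector (element -> count) or NULL/empty
#'   for the empty formula.
#' @return `element_counts` object in Hill order with zero counts dropped.
#' @export
as_element_counts <- function(x) {
  if (is.null(x) || length(x) == 0L) {
    out <- integer(0)
    class(out) <- "element_counts"
    return(out)
  }
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("element counts must be a named vector")
  bad <- setdiff(names(x), names(.MONO_MASS))
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  x <- tapply(as.integer(x), names(x), sum)
  x <- x[x != 0L]
  if (any(x < 0L))
    stop("negative element count")
  if (length(x) == 0L) {
    out <- integer(0)
    class(out) <- "element_counts"
    return(out)
  }
  nm <- .hill_order(names(x))
  out <- as.integer(x[nm])
  names(out) <- nm
  class(out) <- "element_counts"
  out
}

.hill_order <- function(symbols) {
  symbols <- unique(symbols)
  if ("C" %in% symbols) {
    rest <- sort(setdiff(symbols, c("C", "H")))
    c("C", intersect("H", symbols), rest)
  } else {
    sort(symbols)
  }
}

#' Serialize element counts to a Hill-notation string
#'
#' @param f An `element_counts` object.
#' @return Canonical Hill-order formula string (`""` for the empty
#'   formula).
#' @export
format_formula <- function(f) {
  f <- as_element_counts(f)
  if (length(f) == 0L) return("")
  paste0(names(f), ifelse(unclass(f) == 1L, "", unclass(f)), collapse = "")
}

#' @export
format.element_counts <- function(x, ...) format_formula(x)

#' @export
print.element_counts <- function(x, ...) {
  cat("<formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

# elementwise sum of two count vectors (values may be negative for deltas)
.counts_add <- function(a, b) {
  nm <- union(names(a), names(b))
  av <- ifelse(nm %in% names(a), unclass(a)[nm], 0L)
  bv <- ifelse(nm %in% names(b), unclass(b)[nm], 0L)
  v <- as.integer(ifelse(is.na(av), 0L, av) + ifelse(is.na(bv), 0L, bv))
  names(v) <- nm
  v[v != 0L]
}

#' Monoisotopic mass of a formula
#'
#' @param f `element_counts` (or a named count vector). The empty formula
#'   has mass 0.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(parse_formula("H2O"))
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  f <- unclass(f)
  if (length(f) == 0L) return(0)
  sum(.MONO_MASS[names(f)] * f)
}

#' Parse an adduct label
#'
#' Understands the MassBank `MS$FOCUSED_ION: PRECURSOR_TYPE` dialect,
#' e.g. `"[M+H]+"`, `"[M-H]-"`, `"[M+2H]2+"`, `"[M+Na]+"`,
#' `"[M+H-H2O]+"`. The ASCII hyphen and the typographic minus are both
#' accepted.
#'
#' @param label Adduct string.
#' @return List with `label`, `polarity` (`"pos"`/`"neg"`), `z`
#'   (charge magnitude, >= 1) and `delta` (signed element-count vector
#'   added to the neutral molecule). Class `ion_spec`.
#' @export
parse_adduct <- function(label) {
  if (!is.character(label) || length(label) != 1L)
    stop("adduct label must be a single string")
  lab <- gsub("−|–", "-", trimws(label))
  m <- regmatches(lab, regexec("^\\[M((?:[+-][0-9]*[A-Za-z0-9]+)*)\\]([0-9]*)([+-])$", lab))[[1]]
  if (length(m) == 0L)
    stop("cannot parse adduct label ", sQuote(label))
  terms <- m[2]; zs <- m[3]; sign_ch <- m[4]
  z <- if (nzchar(zs)) as.integer(zs) else 1L
  polarity <- if (sign_ch == "+") "pos" else "neg"
  delta <- integer(0)
  if (nzchar(terms)) {
    tok <- regmatches(terms, gregexpr("[+-][0-9]*[A-Za-z0-9]+", terms))[[1]]
    for (t in tok) {
      sgn <- if (substr(t, 1, 1) == "+") 1L else -1L
      body <- substring(t, 2)
      mult <- 1L
      mm <- regmatches(body, regexec("^([0-9]+)([A-Za-z].*)$", body))[[1]]
      if (length(mm)) { mult <- as.integer(mm[2]); body <- mm[3] }
      part <- unclass(parse_formula(body))
      delta <- .counts_add(delta, sgn * mult * part)
    }
  }
  out <- list(label = lab, polarity = polarity, z = z, delta = delta)
  class(out) <- "ion_spec"
  out
}

#' m/z of an ion formed from a neutral molecule
#'
#' The electron mass is included: for positive ions `z` electrons are
#' removed, for negative ions added. At 10 ppm below m/z 120 the
#' electron term (0.000549 Da per charge) is larger than the tolerance,
#' so it cannot be neglected.
#'
#' @param neutral `element_counts` of the neutral molecule (or formula
#'   string).
#' @param ion An `ion_spec` from [parse_adduct()], or an adduct label.
#' @return m/z in Da.
#' @examples
#' ion_mz("C6H12O6", "[M+H]+")
#' @export
ion_mz <- function(neutral, ion) {
  if (is.character(neutral)) neutral <- parse_formula(neutral)
  if (is.character(ion)) ion <- parse_adduct(ion)
  cnt <- .counts_add(unclass(neutral), ion$delta)
  if (any(cnt < 0L))
    stop("adduct ", ion$label, " removes atoms the molecule does not have")
  m <- sum(.MONO_MASS[names(cnt)] * cnt)
  esign <- if (ion$polarity == "pos") -1 else 1
  (m + esign * ion$z * .ELECTRON_MASS) / ion$z
}

#' Element counts of the full ion (neutral plus adduct atoms)
#'
#' @inheritParams ion_mz
#' @return `element_counts` of the ion; this is the pool from which
#'   fragment subformulas are drawn.
#' @export
ion_formula <- function(neutral, ion) {
  if (is.character(neutral)) neutral <- parse_formula(neutral)
  if (is.character(ion)) ion <- parse_adduct(ion)
  cnt <- .counts_add(unclass(neutral), ion$delta)
  if (any(cnt < 0L))
    stop("adduct ", ion$label, " removes atoms the molecule does not have")
  as_element_counts(cnt)
}

#' m/z of an ion given its ion formula directly
#'
#' @param f ion `element_counts` (charge carriers already included).
#' @param polarity `"pos"` or `"neg"`.
#' @param z charge magnitude (default 1; fragment ions are treated as
#'   singly charged).
#' @return m/z in Da, electron mass included.
#' @export
ion_formula_mz <- function(f, polarity, z = 1L) {
  esign <- if (polarity == "pos") -1 else 1
  (monoisotopic_mass(f) + esign * z * .ELECTRON_MASS) / z
}

#' Signed ppm mass error
#'
#' @param observed Observed m/z (Da).
#' @param theoretical Theoretical m/z (Da), > 0.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  (observed - theoretical) / theoretical * 1e6
}

#' Ring-plus-double-bond equivalents of an ion formula
#'
#' `RDBE = C + 1 - (H + Cl + Br + Na + K)/2 + (N + P)/2`. Used by the
#' optional candidate filter (off by default).
#'
#' @param f element counts.
#' @return RDBE (may be half-integer for even-electron ions).
#' @export
rdbe <- function(f) {
  g <- function(s) if (s %in% names(f)) unclass(f)[[s]] else 0L
  g("C") + 1 - (g("H") + g("Cl") + g("Br") + g("Na") + g("K")) / 2 +
    (g("N") + g("P")) / 2
}

# Cache of fully enumerated subformula lattices, keyed by pool formula.
# Small pools (<= .POOL_TABLE_LIMIT combinations) are enumerated once and
# reused for every peak of every spectrum of the same precursor.
.subformula_cache <- new.env(parent = emptyenv())
.POOL_TABLE_LIMIT <- 2e5

.pool_table <- function(pool) {
  pool <- unclass(pool)
  key <- paste0(names(pool), pool, collapse = "")
  hit <- get0(key, envir = .subformula_cache)
  if (!is.null(hit)) return(hit)
  grid <- do.call(expand.grid, c(lapply(pool, function(n) 0:n),
                                 KEEP.OUT.ATTRS = FALSE))
  names(grid) <- names(pool)
  mass <- as.numeric(as.matrix(grid) %*% .MONO_MASS[names(pool)])
  o <- order(mass)
  tab <- list(counts = as.matrix(grid)[o, , drop = FALSE], mass = mass[o])
  assign(key, tab, envir = .subformula_cache)
  tab
}

.enumerate_via_table <- function(pool, lo, hi) {
  tab <- .pool_table(pool)
  i1 <- findInterval(lo - 1e-9, tab$mass) + 1L
  i2 <- findInterval(hi + 1e-9, tab$mass)
  if (i2 < i1) return(list())
  lapply(i1:i2, function(i) {
    v <- tab$counts[i, ]
    v <- v[v > 0L]
    storage.mode(v) <- "integer"
    v
  })
}

# Depth-first enumeration of all sub-count vectors of `pool` whose
# monoisotopic mass lies in [lo, hi]. Elements are processed in order of
# decreasing mass with residual-mass bounds for pruning, so large pools
# (e.g. peptide precursors) stay tractable.
.enumerate_mass_window <- function(pool, lo, hi) {
  pool <- unclass(pool)
  if (length(pool) == 0L) {
    return(if (lo <= 0 && 0 <= hi) list(integer(0)) else list())
  }
  ord <- order(.MONO_MASS[names(pool)], decreasing = TRUE)
  syms <- names(pool)[ord]
  nmax <- as.integer(pool[ord])
  masses <- as.numeric(.MONO_MASS[syms])
  k <- length(syms)
  # max mass attainable from elements i..k
  maxrest <- rev(cumsum(rev(nmax * masses)))
  maxrest <- c(maxrest, 0)
  res <- new.env(parent = emptyenv())
  res$out <- vector("list", 64L); res$n <- 0L
  counts <- integer(k)
  recurse <- function(i, acc) {
    if (i > k) {
      if (acc >= lo - 1e-9 && acc <= hi + 1e-9) {
        res$n <- res$n + 1L
        if (res$n > length(res$out)) res$out <- c(res$out, vector("list", length(res$out)))
        v <- counts[counts > 0L]
        names(v) <- syms[counts > 0L]
        res$out[[res$n]] <- v
      }
      return(invisible())
    }
    mi <- masses[i]
    for (ci in 0:nmax[i]) {
      sub <- acc + ci * mi
      if (sub > hi + 1e-9) break
      if (sub + maxrest[i + 1L] < lo - 1e-9) next
      counts[i] <<- ci
      recurse(i + 1L, sub)
    }
    counts[i] <<- 0L
  }
  recurse(1L, 0)
  res$out[seq_len(res$n)]
}

#' Enumerate candidate fragment subformulas for an observed m/z
#'
#' Finds all ion formulas drawn elementwise from the precursor-ion
#' formula pool whose singly-charged ion m/z lies within `tol_ppm` of
#' `observed_mz`. When `gas_adducts = TRUE`, fragments explainable only
#' with N2 and/or O added from the collision gas are also returned,
#' flagged with the gas adduct used; a candidate that fits without gas
#' atoms is never duplicated under a gas flag.
#'
#' @param precursor_ion `element_counts` of the full precursor ion
#'   (neutral molecule plus adduct atoms).
#' @param observed_mz Observed fragment m/z (Da).
#' @param tol_ppm Tolerance in ppm (> 0). Matching is strict:
#'   `|error| < tol_ppm`.
#' @param polarity `"pos"` or `"neg"` (sets the electron-mass sign).
#' @param gas_adducts Also consider N2 / O / N2O collision-gas addition.
#' @param dbe_min If non-`NULL`, drop candidates with RDBE below this
#'   value (conventional cutoff -0.5); default `NULL` (off).
#' @return data.frame with columns `formula` (Hill string), `mz`
#'   (theoretical), `ppm` (signed error), `gas` (`"none"`, `"N2"`,
#'   `"O"`, `"N2O"`), sorted by `abs(ppm)`.
#' @export
enumerate_subformulas <- function(precursor_ion, observed_mz, tol_ppm,
                                  polarity = "pos", gas_adducts = FALSE,
                                  dbe_min = NULL) {
  stopifnot(tol_ppm > 0, observed_mz > 0)
  if (is.character(precursor_ion)) precursor_ion <- parse_formula(precursor_ion)
  esign <- if (polarity == "pos") -1 else 1
  # target ion mass window -> candidate formula (neutral-atom) mass window
  lo_mz <- observed_mz * (1 - tol_ppm / 1e6)
  hi_mz <- observed_mz * (1 + tol_ppm / 1e6)
  lo <- lo_mz - esign * .ELECTRON_MASS
  hi <- hi_mz - esign * .ELECTRON_MASS
  gas_deltas <- list(none = integer(0))
  if (gas_adducts) {
    gas_deltas$N2 <- c(N = 2L)
    gas_deltas$O <- c(O = 1L)
    gas_deltas$N2O <- c(N = 2L, O = 1L)
  }
  seen <- character(0)
  rows <- list()
  for (gas in names(gas_deltas)) {
    pool <- .counts_add(unclass(precursor_ion), gas_deltas[[gas]])
    cands <- if (prod(as.numeric(pool) + 1) <= .POOL_TABLE_LIMIT)
      .enumerate_via_table(pool, lo, hi)
    else
      .enumerate_mass_window(pool, lo, hi)
    for (cnt in cands) {
      f <- as_element_counts(cnt)
      key <- format_formula(f)
      if (key %in% seen) next
      seen <- c(seen, key)
      mz_th <- ion_formula_mz(f, polarity)
      err <- ppm_error(observed_mz, mz_th)
      # strict window (|err| < tol) after exact recompute; the 1e-6 ppm
      # guard keeps an error of exactly tol outside despite rounding
      if (abs(err) >= tol_ppm - 1e-6) next
      if (!is.null(dbe_min) && rdbe(f) < dbe_min) next
      rows[[length(rows) + 1L]] <- data.frame(
        formula = key, mz = mz_th, ppm = err, gas = gas,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(formula = character(0), mz = numeric(0),
                      ppm = numeric(0), gas = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(abs(out$ppm)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
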