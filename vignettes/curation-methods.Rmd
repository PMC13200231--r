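---
title: "Curating MS2 reference spectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating MS2 reference spectra: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ms2curate)
```

This vignette documents the models and numerical choices behind
`ms2curate`: what each stage assumes, which parameters matter, what the
synthetic benchmark does and does not emulate, and where the design was
genuinely open.

## The curation problem

A reference MS2 library entry should contain only fragment peaks that
genuinely derive from the target compound, with m/z accurate enough for
subformula annotation. Raw targeted acquisitions violate both
requirements: Orbitrap-class instruments show a smooth, m/z-dependent
systematic mass error of several ppm; data-dependent isolation (1 Da
window) co-fragments whatever else elutes under the target; and
centroided spectra carry sporadic noise peaks. The workflow therefore
combines three orthogonal kinds of evidence per fragment: elemental
plausibility (subformula of the precursor ion), reproducibility
(occurrence in at least two spectra), and chromatographic coherence
(co-elution with the precursor).

## Formula arithmetic

Fragment candidates are ion formulas drawn elementwise from the
precursor-ion formula (neutral molecule plus adduct atoms), not
neutral-loss differences; charge is the adduct's for the precursor and
1 for fragments. The electron mass (0.000549 Da per charge) is always
included: below m/z 120 it exceeds a 5 ppm window on its own.
Monoisotopic masses are IUPAC/CIAAW values hard-coded to 1e-7 Da for
C, H, N, O, S, P, Cl, Br, Na, K.

Enumeration uses a cached full-lattice table for pools up to 2e5
combinations (one table per precursor serves every peak of every
replicate spectrum) and a mass-bounded depth-first search above that.
Matching is strict (`|error| < tol`), with a 1e-6 ppm guard so a
deviation of exactly the tolerance stays outside.

An optional ring-double-bond-equivalent filter (`dbe_min = -0.5`)
exists but is **off** by default: it was an open question whether a
valence filter belongs in assignment, and the multiplicity and EIC
filters already remove most chemically impossible matches, so the
default avoids silently discarding exotic but real ions (e.g. radical
fragments).

## Assignment tolerances

First-pass assignment is deliberately loose so that the not yet
recalibrated data still hit the true formula: ±15 ppm at m/z ≤ 120
(inclusive) and ±10 ppm above. After recalibration, assignment reruns
at < 5 ppm (strict), and only then are still-unassigned peaks retried
with N₂ / O / N₂O added, modelling adduct formation with the collision
gas; a candidate that fits without gas atoms is never flagged as a gas
adduct.

## Recalibration

Calibration points are fragments that are (a) uniquely assigned at the
wide tolerance and (b) at least 10³ counts — weak centroids have poorly
determined positions. Two practical complications shape the fit:

* The same fragment species recurs in every replicate spectrum, so the
  raw points pile up at a handful of m/z values (the residual precursor
  ion alone contributes hundreds). Points are therefore collapsed to
  **species** (clusters within 0.005 Da; median error; replicate count
  as weight) before fitting; a local regression on the raw points would
  face a nearly singular design.
* A peak that is intense and "uniquely assigned" in a *single* scan is
  more often a mis-assigned noise or interference hit than a real
  fragment. Species observed fewer than 3 times are dropped when at
  least two recurrent species remain.

The curve itself is a robust locally weighted regression (`loess`,
symmetric family, degree 1, span 0.5) per ionization mode, fitted on
the collapsed species and clamped to the species range. The fit is
accepted only if it interpolates the species to within
`max(5, 2·max|error|)` ppm and stays inside a 2 ppm margin around the
observed error span across a dense grid; an oscillating fit between
sparse species is rejected rather than applied. Rejected or
under-determined fits degrade to a weighted straight line (which is
allowed to extrapolate across the observed m/z range), then to the
median error, then to identity (with a warning). One model per
ionization mode per batch pools all compounds — per-compound fits would
be badly under-determined.

Only fragment m/z are corrected; the precursor m/z is left as acquired
and recorded both raw and corrected in the record comments. MS1 traces
are not recalibrated (the EIC extraction tolerance of 10 ppm absorbs
the drift).

## EIC correlation and the F₁.₅ cutoff

For each fragment group and spectrum type, an extracted-ion
chromatogram over that type's replicate scans is compared with the MS1
precursor trace, interpolated linearly onto the fragment's retention
times. The score is the **cosine** of the two non-negative vectors;
Pearson correlation is available but not default because traces of
5–15 points make mean-centering unstable. Correlations with fewer than
3 usable points are invalid: such fragments default to the poor-EIC
side unless a formula was assigned, in which case they are kept but
flagged for review.

The cutoff is selected per compound (pooling all spectrum types, since
fragment intensity varies strongly with NCE while co-elution does not)
by maximizing F_β with β = 1.5 for predicting "formula assigned" from
"score ≥ t". β was taken as the recall-weighted F-score; the candidate
grid is the midpoints of consecutive sorted unique scores plus {0, 1},
and ties break toward the smallest threshold — both were open details,
chosen to make the search exact (the optimum of a step function lies on
this grid) and to retain more fragments on ties. Degenerate label sets
(all assigned or none) fall back to 0.5 with provenance
`auto-degenerate`. A stricter preset (0.9) can be applied to Level-1
reference materials via `strict_reference = TRUE`.

Categorization is monotone by construction: raising the threshold can
only move fragments from kept (A/B) to dropped (C/D).

## Multiplicity and consensus

Fragments are matched across spectra by assigned formula when present,
else by m/z within `max(5 ppm, 0.002 Da)`; groups seen in fewer than
two spectra of the compound (within one polarity) are removed
everywhere. Counting is across collision energies — the literal
reading of "at least two spectra", and the more permissive choice.
Consensus peaks use the intensity-weighted mean of recalibrated m/z
(robust to low-intensity centroid jitter; a median variant exists
behind the config), the arithmetic mean intensity over the replicates
containing the fragment, and MassBank relative intensities
`max(1, round(999·I/I_max))`.

## MassBank export

Records follow the flat-file dialect: `CH$` compound block (one
`CH$NAME` per isomer name for Level-3 entries), `AC$` acquisition
block (`COLLISION_ENERGY NCE <n> % (HCD)`, resolution), `MS$FOCUSED_ION`
with precursor m/z and type, `PK$` peak block with 4-decimal m/z, and
`COMMENT` lines carrying the Schymanski confidence level, the EIC
cutoff with provenance, review flags and the raw/recalibrated precursor
m/z. Titles are
`<name>; <instrument type>; MS2; NCE <n>%; <precursor type>`, with
`; TENTATIVE` appended for every non-Level-1 record. Accessions are
`MSBNK-<contributor>-<prefix><seq>`; the scheme is configurable since
no canonical scheme is mandated. `serialize_record()` and
`parse_record()` are exact inverses for canonical records; unknown tags
are preserved verbatim.

## The synthetic benchmark

`synth_params()` describes a targeted acquisition: per compound a
Gaussian elution peak (σ = 0.05 min) sampled by MS cycles every
0.02 min; per cycle one MS1 scan per polarity plus, while the precursor
exceeds 10% of its apex, one MS2 scan per (NCE, scan-mode) cell — this
yields ~11 replicates per each of the 36 spectrum types, i.e. ~400 MS2
spectra per compound. Fragment intensities follow logistic breakdown
curves in NCE (precursor survival decays around NCE 35; each fragment
appears around its own random center), emulating energy-dependent
fragmentation without claiming a mechanistic model. All m/z are
perturbed by a planted error field `2 + 0.01·(m/z − 100) ppm` plus
0.5 ppm white noise.

The default compounds are two peptide-like formulas of 644 and 694 Da.
The mass matters: the automatic scan-range mode starts at
precursor/15, which is distinct from the fixed-40 mode only above
~615 Da — lighter compounds would collapse the 36-cell grid to 18.

Interference is a second species co-isolated 0.4 Da from the target
precursor, eluting 2 peak-σ later with 60% intensity, whose fragment
m/z are rejection-sampled to have **no** subformula explanation within
20 ppm (gas adducts included). This models fragments of an unrelated
compound; without the guard, uniformly random m/z alias subformulas of
a 650 Da CHNO pool often enough to contaminate both the calibration
points and the cutoff labels — an artifact of the random sampler, not
of real chimeric spectra. The `shared_frac` parameter deliberately
plants aliasing interference when that failure mode is wanted. Noise
peaks are Poisson per scan with lognormal intensities around 500
counts, near the detection floor, as centroided Orbitrap noise is.

What the generator does **not** emulate: profile peak shapes, isotope
envelopes, chromatographic tailing, intensity saturation, multiply
charged fragments, and real fragmentation chemistry (fragments are
random subformulas). Passing the benchmark therefore demonstrates the
pipeline's filtering and calibration logic under controlled violations,
not instrument-grade realism.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full default
benchmark — two compounds, both polarities, 36 spectrum types, ~850
scans, ~11,000 labeled MS2 peaks — once per session and reuse it; unit
tests use a reduced single-polarity, 3-NCE configuration. All
randomness flows from a single integer seed; the same seed reproduces
the mzML byte for byte, and `run_curation()` itself contains no
randomness (the loess fit, cutoff search and merging are
deterministic), so records are byte-identical across reruns.

## Known limitations

* Fragments are assumed singly charged; multiply charged fragment
  series of large peptides would need per-charge enumeration.
* The multiplicity filter counts across collision energies; a fragment
  genuinely unique to one energy *and* one scan mode must appear in
  both scan-mode replicates to survive.
* Cross-polarity consensus is out of scope by design; each polarity
  exports its own records.
* `parse_record()` round-trips records in canonical field order;
  exotic MassBank dialects re-serialize with reordered known fields.
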