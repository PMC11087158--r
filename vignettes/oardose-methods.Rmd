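---
title: "Methods: dosimetric evaluation of autosegmented organs-at-risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosimetric evaluation of autosegmented organs-at-risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oardose)
```

## The problem

Autosegmentation of organs-at-risk (OARs) is usually audited geometrically —
Dice similarity coefficient (DSC), sensitivity, surface distances. Those
scores are generalizable but clinically indirect: a contour error changes
patient risk only insofar as it changes the *dose statistics* used for plan
evaluation, and in highly conformal brain radiotherapy the dose is nearly
homogeneous over most of the head. Geometric errors translate into
dosimetric errors only where they overlap steep dose gradients, which for
arc deliveries cluster at the planning target volume (PTV) boundary.
`oardose` implements the dosimetric half of a model audit: DVH statistics
and dose deltas on shared voxel grids, headroom-based clinical-significance
classification, cohort statistics, and geometric–dosimetric correlation —
plus a synthetic cohort generator so that every stage can be validated end
to end without patient data.

## Data model and conventions

All fields live on regular, axis-aligned voxel lattices with fixed axis
order (z, y, x), voxel-center coordinates and mm spacing. Doses are stored
and reported in **cGy** throughout; any Gy values are converted at the
boundary. A structure mask is binary occupancy on the same lattice with an
explicit `present` flag: a model that produced *no* structure is a
**failed** segmentation (`status = "failed"`), which is deliberately kept
distinct from a grossly mislocated structure whose DSC is 0 — the two say
different things about a model, and both are preserved downstream (failed
cases carry no geometry or delta and are tallied as `n_failed`;
`N* = cohort size − n_failed`).

Grid compatibility requires equal shapes, spacing within 1e-6 mm and
origins within 1e-3 mm — tolerances that absorb floating-point header
round-trips but reject any real mismatch. A same-orientation resampler
(trilinear for dose, nearest-neighbor only for masks, so masks stay binary)
stands in for the upstream rigid CT→MRI registration, which is
planning-system-internal and out of scope here; trilinear interpolation is
an assumption, not a claim about any vendor's implementation.

## DVH statistics

`D_x%` is the minimum dose received by the most exposed x% of the structure
volume. We use the discrete rule: sort the mask's voxel doses descending and
take the `ceiling(x/100 · n)`-th value — "the dose of the voxel at which the
cumulative hottest-voxel volume first reaches x%". No sub-voxel DVH
interpolation is applied: the discrete rule matches the verbal clinical
definition, is exactly checkable against a brute-force oracle, and avoids
inventing an interpolation scheme a treatment planning system may not use.
`Dmax` is the single hottest voxel (a small-volume near-max alternative
would be a config extension, off by default).

Percent dose change defaults to the **gold-relative** normalization
`100·(auto − gold)/gold` — required for very large percentages (>100%) to be
possible on low-dose organs — with a prescription-relative option
(`percent_norm = "prescription"`) exposed because reporting conventions
differ. A gold metric of exactly 0 cGy (possible on synthetic data with zero
background) leaves the percent undefined and excluded from percent
aggregates while the absolute delta is still reported.

## Geometric metrics

DSC and sensitivity are voxel-count ratios. Mean distance-to-agreement (MDA)
is the **symmetric** mean surface distance: surface voxels are occupied
voxels with at least one face-adjacent unoccupied neighbor (outside the
grid counts as unoccupied); for every surface voxel of each mask the
distance to the nearest surface voxel of the other mask is computed between
voxel centers with mm spacing applied; the MDA pools both directed sets.
Directionality is a genuine design choice — a directed variant is an easy
extension — but the symmetric form is the common default and is what the
tests' O(n²) oracle checks exactly. No sub-voxel surface meshing is used:
voxel-center distances are deterministic and oracle-checkable, at the cost
of a ~half-voxel bias versus meshed surfaces. Internal unit is mm; convert
to cm at the reporting boundary if needed.

## Clinical significance by dose headroom

A fixed percent tolerance is the wrong instrument: a 2–3% change matters
when an organ is at tolerance and is noise when it is 30% below. The
headroom approach scales the criterion per organ and protocol:
`headroom = tolerance − gold dose` per case, then

- **first-order organs** (brainstem D5%, orbits, optic chiasm, optic nerves
  D1% — hard planning limits with near-maximal statistics): threshold =
  `0.5 · mean(headroom)` over the protocol's cases; a case is clinically
  significant when its dose change exceeds the threshold *in either
  direction* (dose reductions can mask an undertreated tumor margin as much
  as increases can overdose the organ);
- **second-order mean-dose-like organs** (cochlea D50%): threshold =
  `0.5 · min(headroom)` — half the worst-case headroom in the cohort;
- **other second-order organs** (lenses, lacrimal glands, pituitary):
  these are often treated above their optimal tolerance, which would make
  the threshold negative, so they are excluded from threshold
  classification and compared descriptively between models.

Thresholds are computed separately per protocol (different prescriptions
produce different gold doses) and never pool protocols. Gold doses from
cases whose autosegmentation failed still enter the threshold (gold
contours always exist). Any organ whose computed threshold is ≤ 0 is
excluded with reason `"negative headroom"` rather than silently flagged.
Boundary convention: strict inequality — "more than half the headroom" —
so a tie is not flagged. For worst-case-mode organs the phrase "more than
half of this threshold" is ambiguous between `|Δ| > T` and `|Δ| > T/2` once
T is already half the headroom; `|Δ| > T` is the default (consistent with
treating T as *the* threshold) and `mean_like_rule = "T/2"` switches to the
stricter reading.

## Cohort statistics

Model comparisons use the classical paired two-tailed Student t-test on
per-case percent dose changes, with pairwise-complete deletion (a failed
segmentation drops that pair, not the case's other organs). The Bonferroni
corrected level is `alpha / family_size` exactly — for three models compared
pairwise at alpha 0.05 that is 0.0167, not the rounded 0.01 sometimes
printed; a fixed `alpha_override` reproduces rounded conventions when
needed. Fewer than two complete pairs, or zero-variance differences
(e.g. two identical models), make the test *unavailable* — never a silent
p of 0 or 1. The effect size reported is the difference of the two models'
median percent changes.

Geometric–dosimetric correlations are Pearson r between each geometric
metric and absolute percent dose change, pooled across organs and cases
within one model (one r per model per metric; a per-organ breakdown is a
trivial extension but the pooled value is the headline). p-values use the
t transform with n − 2 degrees of freedom for n ≥ 3; zero variance in
either coordinate (e.g. an identity cohort where every delta is 0) leaves
the correlation undefined and flagged, with a machine-readable warning code
in the run log.

## The synthetic cohort: what it emulates, and what it does not

The generator stands in for a glioma VMAT test cohort. Its stated world:

- **Dose**: `D(x) = Rx·[b + (1−b)·σ((R − d(x))/w)]·(1 + ε)` with σ the
  logistic function and d(x) the distance from the PTV center. Defaults:
  R = 25 mm, w = 5 mm (the dose falls across roughly 4w ≈ 2 cm around the
  PTV boundary, a realistic arc-therapy penumbra at this scale), b = 0.05
  (a ~5% scatter bath), ε multiplicative Gaussian with 1% s.d. This is the
  simplest field with a controllable gradient location; it is radially
  symmetric and ignores beam geometry entirely.
- **Protocols**: A = 6000 cGy/30#, B = 5400 cGy/30#, drawn per case with
  P(A) = 0.6, near the A:B mix of a small glioma test cohort.
- **Anatomy**: 13 OARs as geometric primitives on a 135×180×180 mm grid at
  2.5 mm isotropic spacing, placed so the superior brainstem, optic chiasm
  and posterior optic nerves straddle the dose gradient while lenses,
  lacrimal glands, cochleae and most of the orbits sit in the low-dose
  bath. The chiasm sits almost at its tolerance (tiny headroom) and the
  pituitary above it (negative headroom) — deliberately reproducing the
  clinical situations that motivate the most-flagged organ and the
  negative-headroom exclusion. Per-case anatomy varies by jittering the PTV
  center (s.d. 3 mm) and radius (s.d. 2 mm), so gold doses and headrooms
  vary across the cohort; the OARs themselves are fixed.
- **Errors**: per model × organ, one perturbation drawn from a profile over
  {none, dilate, erode, translate, truncate, mislocate, fail}. The default
  "edited"/"unedited" profiles bracket curated vs un-curated training:
  the unedited model errs more often, more grossly (5% mislocation) and
  fails more (10% vs 5%). Profiles are user configuration, not a
  calibration to any published per-organ error distribution — none exists
  at that granularity.

A green test on this cohort establishes that the *pipeline* behaves as
specified — metric definitions, exclusion rules, failure bookkeeping, sign
structure of the correlations — under a controlled world where ground truth
is known. It does **not** establish anything about a particular clinical
model's accuracy: the phantom has no image appearance, no inter-observer
contour variability, no real beam geometry, and its error profiles are
stylized. Mislocation is implemented as a guaranteed-disjoint translation
(deterministic DSC = 0), trading realism for reproducibility of that
failure class.

## Numerical and degenerate-input choices

- D_x% ties: the descending sort may order equal doses arbitrarily; the
  selected value is a dose, so tie order cannot change the result (asserted
  against a brute-force oracle on ~1000 random fields).
- Erosion or truncation that empties a mask returns a non-present mask with
  the distinct status `"eroded-away"`, so an aggressive perturbation cannot
  masquerade as a model that produced nothing.
- Resampling beyond the source extent (plus a configurable mm margin)
  errors as non-overlapping; within the half-voxel border, edge values are
  clamped.
- All randomness flows through explicit integer seeds
  (`simulate_cohort(seed = )` restores the caller's RNG state); cohort
  generation is a pure function of (spec, seed) and pipeline runs are
  byte-deterministic given cohort + config.
- The run log records a 64-bit FNV-1a fingerprint of every
  threshold-relevant config field, so reports from silently different
  configurations cannot be confused.

## Known limitations

- NIfTI support is a minimal, axis-aligned single-file NIfTI-1 subset
  (diagonal sform); oblique acquisitions and compressed `.nii.gz` are not
  read. DICOM RT-Dose/RTSTRUCT import is not implemented.
- MDA uses voxel-center surface distances, not meshed surfaces; values
  carry a sub-voxel bias relative to mesh-based tools.
- The paired t-test assumes approximately normal paired differences; no
  non-parametric alternative is provided.
- The dose model is radially symmetric: steep gradients far from the PTV
  (fixed-beam geometries) are outside the generator's world, though the
  evaluation pipeline itself is agnostic to where gradients lie.
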