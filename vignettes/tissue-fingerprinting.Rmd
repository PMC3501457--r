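---
title: "Electrochemical tissue fingerprinting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrochemical tissue fingerprinting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltfinger)
```

## The problem

The Brdicka reaction — catalytic hydrogen evolution at a mercury electrode in
a cobalt/ammonia electrolyte — is the standard direct electrochemical assay
for metallothionein (MT), a small cysteine-rich metal-binding protein. A
differential pulse voltammetry (DPV) sweep of a heat-treated tissue extract
yields a current-versus-potential curve with a handful of characteristic
catalytic peaks (Co1, RS₂Co, Cat1, Cat2). Different rat tissues produce
curves of recognizably different shape, which raises a classification
question: can the tissue of origin be identified from the voltammogram
alone?

`voltfinger` implements that analysis end to end: compact curve
representations (named local extremes; Haar-wavelet step attributes),
decision-tree classification under stratified 10-fold cross-validation, and
a geometric characterization of the near-linear curve segment between the
Cat2 minimum and the last maximum (Max3), whose per-tissue line fits share a
common intersection point. Because the original rat measurements are not
publicly deposited, the package ships a synthetic-data module that emulates
the study design; all tests and the acceptance script run on it.

## Conventions

* **Acquisition order.** Samples are stored in sweep order from −0.7 V
  toward the most negative potential (−1.8 V); potentials are equidistant
  and strictly decreasing. All index-based operations assume this order.
* **Sign.** Stored currents are the negated plotted curve, so the catalytic
  peaks RS₂Co, Cat1, Cat2 are local *minima* of the stored values.
  Biochemical plots mirror the current axis, which is why these peaks are
  conventionally drawn as maxima.
* **Units.** Potentials in volts; currents in arbitrary (instrument) units;
  MT levels in µg/g.

## Extreme detection

Local extremes are found by the discrete chain

1. first difference `y[n] = x[n] − x[n−1]` (zero-padded to keep the length),
2. signum-like normalization (≥ 0 → +0.5, < 0 → −0.5),
3. a second first-difference; non-zero entries mark sign changes of the
   slope, i.e. extremes, whose values are read off the original signal.

Mapping zero differences to +0.5 fixes the tie rule on flat runs: an
interior sample `e` is a maximum iff `x[e] ≥ x[e−1]` and `x[e] > x[e+1]`, a
minimum iff `x[e] < x[e−1]` and `x[e] ≤ x[e+1]`. The test suite holds the
implementation to exact agreement with a brute-force neighbour-comparison
oracle under this rule, ties included. Endpoints are never extremes.

Measured curves are not perfectly smooth, so insignificant extreme pairs can
appear within a few samples of each other. `merge_close_extremes()` removes,
for each pair of neighbouring extremes closer than `min_distance` (default 5
samples ≙ 10 mV at the 2 mV step), the member whose current deviates less
from the mean of its flanking extremes — keeping the more prominent feature —
and finally restores strict min/max alternation. The operation is idempotent.
No further smoothing or denoising is applied; the merge rule is deliberately
the only defence, mirroring the simplicity of the original procedure.

Named peaks are assigned within configurable potential windows (defaults:
Co1 ∈ (−0.95, −0.70), RS₂Co ∈ (−1.35, −1.10), Cat1 ∈ (−1.48, −1.30),
Cat2 ∈ (−1.62, −1.45) V for the minima, plus windows for Max1–Max3). The
minima windows genuinely overlap — catalytic peak positions vary — so each
extreme is assigned to at most one name, most specific window first, by
largest prominence; only a window that fully contains another window of the
same kind is rejected as a misconfiguration.

## Wavelet step attributes

Each 518-sample curve is truncated to 512 = 2⁹ samples by dropping the six
samples nearest −0.7 V (the flat head of the sweep, essentially identical
across curves). The Haar decomposition is computed in its mean/difference
normalization: the first coefficient is the global mean and every refinement
coefficient is the difference between a half-interval's mean and its
parent's mean. The *inverse* transform at level *k* yields the quantity
actually used downstream: the 2ᵏ equal-width step heights of the piecewise-
constant approximation, each exactly the mean of the signal over its block
(`w5coef0 … w5coef31` at level 5; 16 attributes at level 4). Because the
derived attributes are block means, they are invariant to the choice of
coefficient normalization; the tests pin them to a direct block-averaging
oracle at 1e−10. Blocks are indexed in acquisition order, which is the only
convention under which `w5coef24 … w5coef27` cover the stretch between Cat2
and Max3 (about −1.53 to −1.67 V).

## Classification

Three attribute sets are compared:

| mode | attributes | tissues |
|------|-----------|---------|
| `minima3` | potential + current of RS₂Co, Cat1, Cat2 (6) | 7 (blood, muscle excluded) |
| `extremes6` | potential + current of all six named extremes (12) | 7 |
| `wavelet32` | level-5 step attributes (32) | all 9 |

Blood and muscle curves never reach six extremes and are excluded from the
extreme-based modes, as in the original analysis.

Trees are induced with a *minimal leaf size* of 10 so that no leaf can
specialize to the five replicates of a single subject. Induction is
delegated to `rpart` with an entropy ("information") split criterion,
complexity pruning disabled (`cp = 0`) and `minbucket` carrying the
minimal-leaf rule; tree learning is a standard step here, not this
package's contribution, so the well-tested recursive-partitioning
implementation is preferred over a bespoke learner. (The original tool's
criterion was gain-ratio-like; with continuous attributes and binary splits
the entropy criterion selects essentially the same thresholds.)

Evaluation is stratified 10-fold cross-validation: folds are disjoint,
per-class counts differ by at most one between folds, and all test
predictions are pooled into a single confusion matrix (predicted tissue in
rows, true tissue in columns) whose per-class precision and recall are
reported together with the mean ± sample standard deviation of the ten fold
accuracies. Folds are stratified by tissue only, *not* grouped by subject:
the five replicates of one rat can land in different folds. This matches
the original evaluation (its confusion-matrix totals equal the full dataset
size) but is a known optimistic bias — replicate leakage — worth remembering
when reading the accuracies.

## The Cat2 → Max3 segment and its line families

Between the Cat2 minimum and the last maximum Max3 the curve is close to
linear. Each curve is characterized there by:

1. the inflection point — the sign change of the discrete second difference
   within the open Cat2–Max3 interval; among several candidates the one
   with the steepest slope is taken (the curvature zero is a stable anchor,
   the steepest-slope tie-break resolves noise-induced multiplicity);
2. an ordinary least-squares line `y = kx + q` over the m = 11 samples
   centred on the inflection (5 to each side).

Within one tissue the (k, q) pairs of replicate curves are collinear,
`q = αk + β`. Substituting into `y = kx + q` gives
`y = k(x + α) + β`: every line of the family passes through the single
point ⟨−α, β⟩, the family intersection, which lies close to the inflection
point itself. α and β are estimated by OLS of q on k (the printed regression
formulas of the original method are ordinary normal-equation least squares;
orthogonal regression was considered and rejected as an unwarranted
embellishment). Pearson correlation relates −α to the per-tissue MT level.

A practical caveat the package documents rather than hides: the intercept
β is estimated by extrapolating the q-on-k regression to k = 0, far outside
the observed k range, so any error ε in α̂ propagates as ≈ ε·k̄ into β̂.
Horizontal (peak-position) replicate jitter therefore inflates β̂ scatter by
an order of magnitude relative to α̂; α̂ is the robust family parameter, and
the parameter-recovery tests treat the vertical family-noise experiment as
the canonical one.

## RadViz

The four attributes `w5coef24 … w5coef27` are projected by the spring
(Hooke-law) rule: each attribute is min-max scaled to [0, 1] **over the
whole dataset**, anchors sit equally spaced on the unit circle, and a row
maps to the weighted centroid of the anchors (weights = scaled attribute
values; a zero-weight row maps to the origin). Projections are invariant to
a common positive rescaling of an un-normalized row and always lie in the
anchors' convex hull.

The whole-dataset normalization is load-bearing: if a single tissue's
amplitude family were normalized on its own, all four scaled coordinates
would collapse to the same affine function of the amplitude and every curve
of that tissue would project to the origin. Normalized across tissues, each
tissue's family traces a projective line segment — the "tissues form lines"
phenomenon the projection is meant to exhibit.

## The synthetic-data generator

The generator emulates the study design: 9 tissues × 8 subjects × 5
replicates = 360 curves of 518 samples over (−1.8, −0.7) V, with 8
corrupted replicates (~2%) spread over six (tissue, subject) groups of rats
r6 and r8 in gonad, heart, blood and muscle — so cleaning leaves 352 curves
overall and 275 in the seven six-extreme tissues.

**Signal model.** A stored curve is the negative of (exponential
hydrogen-evolution wall `A·exp((u−1.8)/τ)` + a gentle linear ramp + 3–4
Gaussian catalytic peaks). The bell-on-exponential form was chosen for
smoothness and controllable extreme counts, not electrochemical realism.
Blood and muscle carry RS₂Co only as a weak shoulder (no extreme pair),
giving exactly 4 extremes; the other seven tissues have exactly 6 (Co1,
where present, is likewise a weak shoulder — the only reading under which
"four peaks" and "six extremes" coexist). Amplitude bands encode three
shape groups — {liver, kidney, brain, gonad} high, {blood, muscle} low,
{heart, eye, spleen} mid — so the tree's top split separates the groups and
misclassifications concentrate within them; liver/kidney and heart/eye have
near-identical minima coordinates and differ mainly in wall decay, which is
what makes the minima-only attribute set genuinely weaker than the wavelet
set.

**Variability.** Subjects vary by a relative amplitude factor (sd 0.08) and
a small common peak-position shift (sd 2.5 mV); replicates add amplitude
(sd 0.025), position (sd 2 mV), a bounded vertical family offset (uniform
on ±1% of |β|) and smooth measurement noise (sd 0.003, white noise smoothed
with a 5-sample Gaussian kernel). Correlated noise is used instead of
i.i.d. noise deliberately: the flat head of the curve rises by only ~7e−4
per sample, so independent noise of any visible magnitude would strew
spurious extremes far apart — contradicting the six-extreme structure of
real curves, which are almost all smooth.

**Line families by construction.** Each profile fixes a pivot (x_piv,
y_piv) on the tangent of the base curve at its inflection (x_piv within
4 mV of the inflection), and all amplitude variation scales the curve about
y_piv: `s = y_piv + G·(s0 − y_piv)`. OLS being linear, the segment fit of
such a curve satisfies `q = αk + β` *exactly* with α = −x_piv, β = y_piv —
the exact-sharing property — and the family intersection automatically sits
near the inflection. Cat2 centres (−1.484 … −1.536 V) co-vary loosely with
the tissue MT reference levels, so −α correlates strongly and positively
with MT level (r ≈ 0.9 at the design level; ≈ 0.6 after estimation noise on
a default dataset). Only four MT levels are published measurements (kidney
67.0, liver 48.7, brain 50.5, spleen 41.5 µg/g); the rest are synthetic
plausible values consistent with heart and muscle being about half the
detoxifying organs' level.

**Outliers and cleaning.** Corrupted curves are amplitude-collapsed (or,
configurably, frozen mid-sweep). The pipeline removes them by the explicit
flag list — the synthetic counterpart of curation by visual inspection.
The automatic alternative (root-mean-square distance to the group's
pointwise median curve, flag beyond 5× the median distance) detects gross
corruption reliably, but the max/median ratio over five replicates has a
heavy enough tail that a fixed factor occasionally flags a healthy curve;
exact 360 − 8 arithmetic is therefore a property of the curated route, not
of the distance rule.

**What passing tests do and do not show.** The generator reproduces the
*structure* the analysis assumes — extreme counts, group separability,
collinear (k, q) families, amplitude-dominated replicate scatter. Real
voltammograms have asymmetric peaks, potential-dependent noise, electrode
drift, and no reason to obey an exact pivot construction; accuracies and
correlations obtained here therefore validate the pipeline's correctness,
not its field performance, and the published headline accuracies
(80.77/86.56/96.31%) are matched only in their qualitative ordering.

## Numerical choices and degenerate inputs

* Equidistance of potentials is enforced at 1e−9 V; curve files are written
  with 15 significant digits so round trips preserve currents to 1e−12.
* `find_inflection` treats exact zeros of the second difference as
  candidates directly; for strict sign flips it takes the flank sample with
  the smaller |second difference|. No sign change → explicit error.
* A pure (single-class) training table yields a single-leaf tree; an empty
  table, a class smaller than the fold count, fewer than 3 family fits, or
  an all-equal slope family (vertical line in (k, q)) raise named errors.
* Stage seeds are derived from the master seed per stage name
  (`derive_seed`), so changing the CV seed cannot perturb data generation;
  all derived seeds stay below 2³¹.
* Problem sizes used throughout the tests: the default 360-curve dataset,
  1000 random signals for the extreme-detection oracle, 20 seeds × 40
  replicates for parameter recovery — all chosen to exercise the design at
  the study's own scale.

## Known limitations

* Replicate leakage in CV (see above) — kept for fidelity, documented.
* The minima windows are a judgment call; the reported peak-position ranges
  in the source material are partly garbled, so windows are configurable.
* The β intercept of a line family is lever-arm sensitive (see above).
* The generator's outlier modes (collapse, truncation) are crude stand-ins
  for real measurement failures.
* No GPES instrument-format import; CSV/TSV dialects defined by
  `write_curves()` are the interchange contract.
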