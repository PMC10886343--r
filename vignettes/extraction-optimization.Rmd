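---
title: "Response-surface optimization of ultrasound-assisted polyphenol extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-surface optimization of ultrasound-assisted polyphenol extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uaeopt)
```

## The problem

Extracting polyphenols from plant material by ultrasound is governed by a
handful of process variables — here the ethanol concentration of the
solvent (40–80 %), the sonication time (15–45 min) and the bath
temperature (40–60 °C) — whose joint effect on the yields of total
phenolics (TPC, mg gallic-acid equivalents per g) and total flavonoids
(TFC, mg catechin equivalents per g) is smooth, curved and interacting.
`uaeopt` implements the standard design-of-experiments workflow for this
situation: a three-factor Box–Behnken design (BBD), a second-order
polynomial response-surface model (RSM) with full ANOVA diagnostics,
Derringer desirability optimization of several responses at once, a small
neural-network regressor for the customary RSM-vs-ANN comparison, and the
validation and annotation arithmetic that accompanies such studies. The
packaged data are the 17-run seed-extraction experiment accessible through
`ums_design()` / `ums_responses()` and the 104-compound negative-mode
metabolite library of the optimized extract (`ums_compound_library()`).

## The design

A three-factor BBD places 12 runs at the midpoints of the factor-cube
edges — each run fixes one factor at its center and the other two at
their extremes — plus replicated center runs (five in the packaged
study). Factors are *coded* so that low/center/high map to −1/0/+1:

$$x_j = \frac{X_j - \mathrm{center}_j}{\mathrm{half\mbox{-}range}_j}.$$

Coded levels of design runs are stored as exact integers, so column sums
and sums of squares ($\sum x_j^2 = 8$ per linear column, 4 per
interaction column) are computed without float drift. The canonical run
order is by factor pair with centers last; `bbd_design()` accepts a
permutation to reproduce an externally published run sheet, which is how
`ums_design()` recreates the packaged study's printed order.

## The quadratic model and its ANOVA panel

Each response is fit by ordinary least squares to

$$Y = \beta_0 + \sum_i \beta_i x_i + \sum_i \beta_{ii} x_i^2 +
      \sum_{i<j} \beta_{ij} x_i x_j,$$

ten coefficients on coded factors. The diagnostic panel follows the
conventions of the commercial DOE packages this workflow is usually run
in, because those are the numbers practitioners expect to compare:

* **Per-term sums of squares** are partial (type III): the increase in
  residual SS when the term is dropped and the model refit. For terms
  orthogonal to the rest (linear and interaction columns of a BBD) this
  equals the closed form $\beta^2 \sum x^2$; for the pure quadratics,
  which are not orthogonal to the intercept, the drop-term refit is what
  reproduces the published panel, and the test suite checks both routes.
* **Lack of fit vs pure error**: the residual SS is split into pure error
  (squared deviations of replicate groups from their means; 4 df with
  five center replicates) and lack of fit (3 df), with an F test of the
  quadratic's adequacy.
* **Predicted R²** uses PRESS computed from the hat matrix,
  $\mathrm{PRESS} = \sum (e_i/(1-h_{ii}))^2$; a brute-force leave-one-out
  refit gives the same number to 1e−8 on the packaged study.
* **Adequate precision** is the signal-to-noise convention
  $(\max \hat y - \min \hat y)/\sqrt{p\,\mathrm{MSE}/n}$ over the design
  points with $p = 10$ parameters; this choice reproduces the published
  25.0494 for TPC.
* **CV%** divides the root residual MSE by the mean of all experimental
  responses.
* Significance verdicts use 0.05 / 0.01 / 0.001 thresholds.

On the packaged data the TPC panel reproduces the published statistics
essentially exactly (R² 0.9928, model F 107.80, lack-of-fit p 0.1772,
CV 1.21 %, adequate precision 25.0494, predicted R² 0.9192). The TFC
panel agrees to within the published rounding (model F recomputes to
46.70 against a printed 46.54; the printed value inherits rounding of the
printed SS chain). A handful of printed TFC equation coefficients differ
from the exact refit in the third decimal for the same reason; the tests
therefore compare at the published precision plus that rounding margin.

## Desirability optimization

Each fitted response is mapped to $[0,1]$ by a linear ramp and the ramps
are combined as a weighted geometric mean
$D = (\prod d_i^{w_i})^{1/\sum w_i}$, which is zero whenever any response
is unacceptable. Defaults, all overridable:

* **Anchors**: the observed minimum and maximum of each experimental
  response column. The study this emulates does not state its anchors;
  the observed range is the conventional default and places the joint
  optimum at 61.4 % ethanol, 29.6 min, 50.2 °C — within rounding of the
  published optimum. The *location* of the optimum is robust to the
  anchor choice; the absolute value of $D$ is not (we obtain 0.933
  against a published 0.953), which is why only the location should be
  compared across software.
* **Weights** equal, **shape exponents** 1.
* **Search**: a dense grid over the coded cube (step 0.01) followed by
  Nelder–Mead refinement clamped to the cube, keeping the refined point
  only if it improves on the grid. Ties prefer the smallest coded norm.
  No extrapolation outside the validated factor ranges is attempted.

## The neural-network comparison

The customary comparison model is a single-hidden-layer perceptron: tanh
hidden units (default 5), linear output, inputs and response min–max
scaled to $[-1,1]$. Data are split 70/15/15 into training, validation
and test sets (12/2/3 of 17 runs; `round`/`floor`/remainder allocation),
the split and the initial weights deriving from one seed. Hidden weights
are initialized Nguyen–Widrow style (active regions spread across the
input cube) and the output layer starts at zero, so the network begins as
a constant and gains curvature only as training demands. The default
trainer is Levenberg–Marquardt on the training-set residuals — damping
×10 on a rejected step, ÷10 on an accepted one — with the validation MSE
checked every epoch, weights returned from the best validation epoch, and
training stopped after six checks without improvement. A BFGS trainer is
available as an alternative, and a cascade variant with input-to-output
skip connections as a flag. Because two validation points make stopping
noisy on a 17-run design, `train_mlp_best()` sweeps seeds and keeps the
network with the best overall R².

A limitation worth stating plainly: with 12 training points, replicated
center runs whose scatter bounds any model's R² at about 0.998, and
held-out edge runs at genuinely unvisited factor settings, the
holdout-inclusive R² of an unregularized perceptron typically lands at
0.95–0.98 over a seed sweep. The published per-run network predictions
for the packaged study recompute to R² = 0.972 — the same quality class —
even though the accompanying summary table claims 0.9963; the two
published figures are mutually inconsistent, and the test suite records
the per-run value.

## Comparison and validation metrics

`compare_predictions()` reports R² (1 − SSE/SStot), RMSE, AAD% and SEP%
(100·RMSE/mean observed). The AAD denominator is the *predicted* value,
following the formula convention this workflow standardizes on; some
literature divides by the observed value instead. The published
comparison table's RSM RMSE and SEP entries are not reproducible from the
printed per-run values (direct recomputation of the TPC RSM RMSE gives
0.60, not 6.71) and are treated as unusable. `validate_optimum()`
implements the confirmatory-run statistics: RSE% = 100·(actual −
predicted)/predicted, and RSD% using the two-value *sample* standard
deviation $|a-b|/\sqrt2$, which is the convention that reproduces the
published 1.80/2.59 pairing; thresholds 10 % and 5 %.

## Mass annotation

Elemental formulas over C, H, N, O, S (plus P, Na, Cl, K) are parsed from
Hill-style strings, tolerating the underscores and subscripts of typeset
tables. Monoisotopic masses use C = 12 exactly, H = 1.00782503,
N = 14.00307401, O = 15.99491462, S = 31.97207117. The default
deprotonated-adduct convention subtracts the hydrogen-*atom* mass
(electron neglected) because that is what reproduces the packaged
library's calculated-mass column (apigenin 269.045); the physically
stricter proton convention (+0.00055 Th) is a flag. Matching defaults to
5 ppm, appropriate for Orbitrap-class resolution; neutral-loss flagging
checks precursor/fragment differences against hexosyl 162.0528,
deoxyhexosyl 146.0579, galloyl 152.0110, sulfate 79.9568, CO₂ 43.9898
and H₂O 18.0106 Da within ±0.02 Da (fragment lists printed at two
decimals can drift further; the window is widenable per call). Of the
104 packaged rows, 100 reproduce the printed calculated mass within
0.0015 Th; the four exceptions (chrysoeriol, whose printed formula
duplicates another row's; lyoniresinol glucoside, printed with an
odd-electron formula; ribonic acid and dihydroxy-octadecadienoic acid,
off by <2 mDa) are transcription-level defects of the source table, kept
as printed rather than silently corrected. Self-matching the observed
masses against the formulas at 10 ppm succeeds for 92 rows; the 12
failures are the same class of defect. Confidence levels are user
metadata (1 reference standard, 2 literature MSⁿ, 3 tentative), never
inferred.

## Assay arithmetic

Percent inhibition is 100·(A − B)/A for control A and sample B, used
identically for radical scavenging and melanin production; out-of-range
values are kept but flagged. Calibration curves invert linear
absorbance-vs-concentration standards (the packaged slopes/intercepts are
in `ums_calibration_curves()`). IC50 interpolates inhibition linearly
against log₁₀(concentration) between the bracketing pair — chosen over
4-parameter-logistic fitting because the source workflow states no
fitting procedure, interpolation is exact on the fixtures, and it keeps
the module free of iterative optimization. On noise-free logistic curves
with Hill slopes 0.5–3 the interpolation recovers the true midpoint
within 5 %. A series never crossing 50 % reports "above range"/"below
range" instead of a number.

## Synthetic data

The generators produce inputs with the statistical structure each stage
assumes, so the pipeline is testable with no external data:

* `simulate_bbd_responses()`: a true 10-coefficient quadratic at the
  design points plus i.i.d. Gaussian noise. Noise is homoscedastic
  because the packaged study's replicate SDs (≈0.3–1.2) are roughly
  constant across runs; σ = 0.6 is the default scale for the same
  reason, with five center replicates as in the study. At σ = 0 the fit
  recovers the coefficients to 1e−9; at σ = 0.6 the pure-error mean
  square averages σ² and the lack-of-fit test holds its nominal 5 % size
  (checked over 500 seeded replicates).
* `simulate_peaklist()`: library masses perturbed by multiplicative
  N(0, ppm SD) error plus uniform decoys. At 2 ppm error and 5 ppm
  tolerance, recovery meets the normal-tail expectation
  P(|Z| < 2.5) ≈ 0.988.
* `simulate_dose_response()`: 4-parameter logistic inhibition with
  additive noise.

What they deliberately do not emulate: run-order drift, heteroscedastic
or correlated measurement error, isotope patterns or spectral noise, and
plate-reader optics. Passing tests therefore demonstrate correctness of
the arithmetic under the stated error model, not robustness to every
pathology of real instruments.

## Numerical and design choices

* Coded design levels are integers; all model fitting is on the coded
  scale, decoded only for reporting.
* The optimizer's grid step (0.01 coded) and the Nelder–Mead relative
  tolerance (1e−12) are fixed; refinement can only improve on the grid.
* Degenerate inputs fail loudly: rank-deficient designs, responses of
  zero variance, unreplicated designs (no pure error), leverages of 1
  (PRESS undefined), hydrogen-free formulas, non-bracketing dose series.
* Monte-Carlo problem sizes in the test suite (500 surface replicates,
  20 peak-list replicates, 300-replicate noise-scaling checks) were
  chosen to put the binomial/χ² sampling error of each check well inside
  its assertion band.
* Seeds: every stochastic function takes an explicit seed and restores
  the caller's RNG state; identical seeds give bit-identical output.

## Known limitations

Only three-factor Box–Behnken layouts are constructed (no general
k-factor, central-composite or D-optimal designs, and no
randomization/blocking schemes). Desirability handles box bounds only —
no nonlinear constraints or Pareto enumeration. The perceptron is a
comparison baseline, not a production learner: no hyperparameter search
beyond the seed sweep, no regularization, no deep variants. Mass
annotation does no spectral scoring, isotope-pattern evaluation,
retention-time modeling or database queries; it is formula arithmetic
plus ppm matching, which is exactly what the accompanying tables of such
studies contain.
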