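---
title: "Models and methods behind chemocal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chemocal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemocal)
```

# The analytical problem

Buscopan Plus tablets combine paracetamol (PAR, 500 mg) and hyoscine
butylbromide (HYO, 10 mg).  Pharmacopoeial practice requires both actives to
be quantified in the presence of four toxic synthesis/degradation
impurities: p-nitrophenol (PNP), p-chloroacetanilide (PCA), tropic acid
(TRO) and p-aminophenol (PAP).  Their UV spectra overlap heavily in the
230.0--266.0 nm window, so no single wavelength is selective for any one
analyte and univariate calibration fails.  `chemocal` implements the
complete multivariate (chemometric) alternative: an experimental design for
six-component calibration mixtures, four calibration models (PCR, PLS, a
linear feed-forward network, and MCR-ALS curve resolution), figures of
merit, method-comparison statistics, dosage-form assay arithmetic, and
analytical-greenness scoring.

Measured spectra are not distributed with the package; a synthetic
Beer--Lambert generator (below) stands in for the spectrophotometer, and all
statements in this vignette about model performance refer to that synthetic
system.

# The calibration design

Six factors (the analytes) are varied over five coded levels
$\{-2,\dots,+2\}$ in 25 mixtures.  Run 1 is the centre point; runs 2--25 are
generated by one length-24 level sequence, with factor $k$ reading the
sequence cyclically shifted by $k-1$ positions:

$$\mathrm{level}[i,k] = g[(i-2+k-1) \bmod 24],\qquad i = 2,\dots,25 .$$

Each level therefore occurs exactly five times per factor, and any two
factor columns are near-orthogonal -- the property that lets a single
mixture set calibrate six analytes at once.  The level-to-concentration
map is affine, `conc = center + level * step`, with centres/steps (in
ug/mL) PAR (6, 1), HYO (20, 2), PNP (3, 1), PCA (0.6, 0.1), TRO (8, 2),
PAP (4, 1), giving the ranges 4--8, 16--24, 1--5, 0.4--0.8, 4--12 and 2--6
ug/mL.  The generating sequence is not published anywhere as a sequence; it
was decoded cell-by-cell from the published 25-mixture concentration table
and is shipped as the constant `design_generator`, which turns that table
into a regression test (`concentration_design()` must reproduce all 150
cells exactly).  Eight fixed mixtures (`default_validation_ids`) form the
external validation set; the published partition is the default because it
makes every downstream number reproducible, and a seeded random split is
available for simulation studies.

```{r design}
d <- default_design()
d
head(calibration_set(d), 3)
```

# The synthetic spectra generator

The generator implements the bilinear Beer--Lambert model on the fixed grid
of 361 points, 230.0--266.0 nm in 0.1 nm steps (computed by index, never by
accumulation):

$$A = C\,S^{\top} + E,$$

with $C$ the design concentrations (ug/mL), $S$ the 361 x 6 pure-component
sensitivities (absorbance per ug/mL at 1 cm path; molar absorptivity and
path length are absorbed into $S$) and $E$ iid Gaussian noise.  Pure
spectra are sums of Gaussian bands (`gaussian_pure_spectrum()`).

## Design of the default library

The default library (`pure_spectra_library()`) gives each analyte

* a narrow *signature band* (width 1.6--1.7 nm) at a distinct centre
  (237.8, 243.2, 248.6, 254.0, 259.4, 264.8 nm), and
* a weak shared-shape *end-absorption band* centred at 214 nm (width 9 nm)
  whose tail enters the window at the 230 nm edge,

with per-analyte peak sensitivities 0.090 (PAR), 0.012 (HYO), 0.115 (PNP),
0.130 (PCA), 0.016 (TRO) and 0.105 (PAP) A mL/ug -- strong chromophores for
the phenolic species, weak ones for HYO and TRO, as in real UV practice.

This geometry is a deliberate compromise, and the design space around it is
genuinely constrained.  Non-negativity is the only constraint imposed in
the curve-resolution module, and a bilinear decomposition under
non-negativity alone is unique only insofar as each component retains a
near-selective channel.  We verified numerically that libraries with broad,
strongly correlated bands (pairwise Pearson correlation of pure spectra
0.5 and higher) leave a rotational-ambiguity set in which alternating least
squares converges to an exact fit (lack of fit below 1e-7 %) whose profiles
are *mixtures* of the true ones (correlations 0.67--0.98) -- no algorithm
can do better, because the data genuinely do not identify the profiles.
With the default library the ambiguity is small: MCR-ALS started from
SIMPLISMA recovers every pure spectrum with correlation at least 0.9996 at
zero noise.  The price is that the *pure* spectra are less mutually
correlated than heavily fused real drug spectra; overlap is still present
everywhere (no analyte has an exclusive channel at the 0.1 % level, and the
shared end-absorption tail puts several components on every short-wave
channel), which is what defeats univariate calibration.  Users who want a
harsher overlap regime can pass their own band sets; the direct calibration
models (PCR/PLS/ANN) tolerate far more collinearity than curve resolution
does.

The noise level is a free simulation parameter; the default
`noise_sd = 0.002` absorbance is a typical UV photometric repeatability.
No replicate structure, baseline drift, stray light or wavelength error is
simulated, so passing tests demonstrate correctness of the estimators under
the stated model, not robustness to instrument artefacts.

# Direct calibration models

All three direct models mean-centre spectra and concentrations and store
the centring vectors, so prediction is `(x - x_mean) B + y_mean`.

**PCR** regresses the centred responses on the first $h$ principal-component
scores of the centred spectra (components by decreasing singular value).
**PLS** is NIPALS PLS2 -- a single model for all six responses
simultaneously, matching how one latent-variable count is quoted for the
whole system; PLS1-per-analyte can be had by calling `calibrate()` with a
one-column `Y`.  At full rank both reproduce ordinary least squares, which
is the oracle the unit tests use.

The latent-variable count is chosen by leave-one-out cross-validation
(`select_ncomp()`), minimising the pooled

$$\mathrm{RMSECV}(h) = \sqrt{\tfrac{1}{nq}\sum_{i,k}(\hat y_{-i,k}(h)-y_{i,k})^2},$$

with ties broken towards the smaller $h$; per-analyte curves are also
returned.  On the synthetic system the curve drops steeply to the true
dimensionality (6) and is flat beyond it, so the selected count sits at 6
or just above depending on the noise realisation; with the real
instrument's error structure a slightly larger count (8 was quoted for the
original system) is plausible for the same reason.

**ANN.**  The network is 361 inputs, 6 linear hidden neurons, 6 linear
outputs ("purelin-purelin").  With linear transfer functions the composed
map is affine, so the network can never beat least squares in-sample (an
invariant the tests assert); its value here is fidelity to the published
architecture.  The original work trained with a second-order toolbox
optimiser; `chemocal` uses transparent full-batch gradient descent with an
automatic step size (the reciprocal largest eigenvalue of the centred Gram
matrix, halved whenever a step would increase the error) and seeded
$\mathcal N(0, 0.01^2)$ initial weights.  First-order descent needs more
iterations than second-order training: 100 epochs (the default, mirroring
the published setting) leaves the smallest spectral directions unconverged,
while a few thousand epochs reach the least-squares optimum to ~1e-3 ug/mL
(the examples and acceptance runs use 5000; an epoch costs two small matrix
products, so this is well under a second).  Divergence under a user-forced
oversized rate raises an error advising a smaller rate.

# Curve resolution (MCR-ALS)

`mcr_als()` alternately solves the two conditional least-squares problems

$$C = \arg\min_{C \ge 0}\;\lVert A - C S^\top\rVert^2, \qquad
  S = \arg\min_{S \ge 0}\;\lVert A - C S^\top\rVert^2$$

column-by-column with the fast non-negative least squares (fnnls)
active-set algorithm of Bro & De Jong, working on the Gram matrix so the
361 per-wavelength problems share one factorisation.  An implementation
shortcut solves each block unconstrained first and falls back to fnnls only
for columns with negative entries; the result is identical because fnnls
solves the same KKT system.  After every iteration the columns of $S$ are
rescaled to unit Euclidean norm (scale moved into $C$), fixing the bilinear
scale ambiguity and making lack-of-fit trajectories comparable between
runs.

Convergence is declared when the relative change of the percent lack of fit

$$\mathrm{lof} = 100\sqrt{\frac{\sum E^2}{\sum A^2}},\qquad
  R^2 = 100\Bigl(1-\bigl(\mathrm{lof}/100\bigr)^2\Bigr)$$

falls below `tol` (default 0.1 %, the conventional threshold), when the fit
is exact, or at `max_iter` (default 100).  At zero noise the lack of fit
decays geometrically and the relative-change rule never fires, so the
iteration cap is the effective stop; the resolved profiles are stable from
a few dozen iterations onward.  A profile column that collapses to zero is
flagged and warned about, not silently dropped.  The identity between
$R^2$ and lof holds exactly for every decomposition and is asserted in the
tests.

Initial spectra come from SIMPLISMA (`simplisma()`): channel purity
$p_j = \sigma_j/(\mu_j+\alpha)$ with offset $\alpha$ equal to 5 % of the
largest channel mean by default; later picks are weighted by the
determinant of the correlation-around-origin submatrix of the channels
already chosen, which suppresses channels collinear with earlier picks.
The initial profile matrix is the least-squares fit of the data on the
intensity vectors at the selected channels, clipped at zero.
Initialisation from known pure spectra is also supported (`S0=`); on exact
bilinear data that start is already the fixed point, which the tests use to
separate quantitation errors from rotational-ambiguity effects.

Quantitation (`mcr_quantify()`) resolves the augmented matrix (calibration
and unknown samples together), aligns components to analytes by maximum
absolute correlation between resolved and known calibration profiles
(aborting if two analytes claim one component), fits one straight line per
analyte (resolved vs known, calibration rows only) and inverts it for the
unknowns.  The output is invariant to permutation and positive rescaling of
the resolved pair $(C, S)$.

# Figures of merit

Per analyte: RMSEC over calibration rows and RMSEP over validation rows
(`sqrt(mean(err^2))`; no degrees-of-freedom correction, the common
toolbox convention -- documented because conventions differ); per-sample
recoveries `100 * pred / truth` with mean and RSD (sample sd, n-1); the
predicted-versus-actual straight line with Pearson r; and
`LOD = 3.3 s / S`, `LOQ = 10 s / S` with `S` the line's slope and `s` by
default its residual standard deviation (`sqrt(RSS/(n-2))`) -- the usual
reading of "standard deviation of the response"; any other `s` (e.g. an
intercept standard error) can be passed explicitly.  The LOQ/LOD ratio is
10/3.3 = 3.03 by construction; published tables that show an exact 3:1
ratio have applied a shortcut, not these formulas.

# Method-comparison statistics

`t_test_from_summary()` (pooled by default -- the natural companion of a
preceding variance-ratio check -- with Welch behind a flag),
`f_ratio_test()` (larger variance on top, one-sided upper-tail p, critical
value at the 95th percentile), `anova_from_summary()` (rebuilds MS, F, p
and the critical value from printed sums of squares) and `anova_oneway()`
(direct sum-of-squares arithmetic, exactly consistent with the
summary route and with `stats::aov`, and cheap enough for 10^4-replicate
size simulations).  Critical values come from `stats::qt`/`stats::qf`.
The classical identity $t^2 = F$ for two groups is asserted in the tests,
and the empirical size of the ANOVA at $\alpha = 0.05$ over 10^4 null
replicates (5 groups x 6 observations, the published comparison layout)
falls in [0.04, 0.06].

One caution for users comparing against printed summary tables: a pooled t
computed from printed means and SDs can disagree with a printed t if the
table's summary statistics and test statistics were produced at different
stages of rounding -- recompute from the summaries and say so, as the
package does.

# Dosage-form assay

The assay plan encodes the tablet work-up: stock 5000.00 ug/mL PAR +
100.00 ug/mL HYO, dilution 2.5 mL to 100 mL (125.00 / 2.50 ug/mL), then
1 mL to 25 mL (5.00 / 0.10 ug/mL), and a standard spike of 16.00 ug/mL
HYO.  The spike exists because 0.10 ug/mL is far below HYO's calibrated
range (16--24 ug/mL); adding a known 16.00 brings the measured level just
inside range, and the spike is subtracted from the prediction afterwards
(`spike_corrected_predict()`; a corrected value negative beyond tolerance
is flagged as failed spike accounting).

One arithmetic consequence deserves emphasis: subtracting a 16.00 spike
and dividing by the 0.10 nominal multiplies the *absolute* prediction
error by 160 when expressed as a HYO label-claim percentage.  With the
default noise (0.002 absorbance) and HYO's weak sensitivity this makes a
single-reading HYO label claim essentially noise; the within-range,
well-conditioned quantity is the recovery of total HYO in the spiked flask
(16.10 ug/mL), which is what the acceptance script reports.  Replicate
averaging, a stronger HYO chromophore or lower noise would all tame the
amplification; a published per-replicate HYO precision of under 1 %
implies an effective absolute error more than an order of magnitude below
this simulation's.

# Greenness scoring

`eco_scale()` subtracts itemised penalty points from 100 (ratings: 100
ideal, above 75 excellent, 50--75 acceptable, below 50 inadequate).  The
built-in ledgers (`ecoscale_ledger()`) hold the published itemisations:
the chemometric-UV method (methanol 6, waste 1 -> score 93) and the
reference HPLC method (methanol 6, energy 1, waste 5 -> score 88).
Penalty points are ledger *inputs*, not re-derived from hazard pictograms:
the published record supplies them itemised, and the derivation rules live
outside its text.  `agree_score()` is a weighted arithmetic mean of twelve
[0, 1] segment scores (the aggregation formula behind the published 0--1
score is not specified; the weighted mean is the simplest choice with the
documented invariances -- bounded by the extreme segments, invariant to
uniform weight rescaling).  Reproducing any particular published overall
value is out of scope because per-segment inputs are not published.
`gapi_profile()`/`gapi_compare()` treat the 15-field colour profile as
data entry and compute colour counts, with "greener" = fewer red fields
and ties reported as ties.

# Numerical choices and limitations

* Design concentrations are stored rounded to 2 decimals (the preparation
  precision); comparisons use a 1e-9 tolerance after rounding.
* fnnls satisfies the KKT conditions to 1e-10 and is tested against
  brute-force enumeration of all active sets on random small problems.
* LV-selection ties break to the smaller count; RMSECV pools all six
  analytes (divides by `n * q`).
* The ANN optimum is well-defined (affine map) but gradient descent
  approaches it only in the limit; epochs trade time for tolerance.
* Non-negativity is the only MCR constraint; unimodality, closure and
  equality constraints, and trilinear/multiset extensions, are out of
  scope.
* The synthetic generator emulates bilinear mixing with iid Gaussian
  noise only.  Conclusions about real spectrometer data -- including which
  latent-variable count is optimal and attainable lack-of-fit values --
  are data-dependent and not claimed here.

# Problem sizes used in tests

The shipped tests and the acceptance script use the 25-mixture design
(17/8 split) with 361-point spectra throughout, 500 random fnnls oracle
problems, 10^4 ANOVA null replicates, 5000 ANN epochs and MCR iteration
caps of 30--200; the full suite completes in well under a minute on a
single CPU.
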