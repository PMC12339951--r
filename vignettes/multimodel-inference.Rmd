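---
title: "Bayesian multimodel inference for ERK signaling models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian multimodel inference for ERK signaling models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erkmmi)
```

## The problem

Intracellular signaling pathways such as the EGF-to-ERK cascade are
modeled by many different systems of ODEs: published models differ in
which species they include, in kinetic formulation (mass action versus
Michaelis-Menten), and in structural features such as negative feedback or
noncanonical activation branches.  Calibrating any one model to sparse,
noisy data and predicting with it ignores this *model uncertainty*.
`erkmmi` implements Bayesian multimodel inference (MMI): every candidate
model is calibrated by Bayesian inference, and the per-model predictive
densities are combined into a consensus predictor

$$
p(q \mid d_{\mathrm{train}}) \;=\; \sum_{k=1}^{K} w_k\,
p(q_k \mid \mathcal{M}_k, d_{\mathrm{train}}),
\qquad w_k \ge 0,\; \textstyle\sum_k w_k = 1 ,
$$

with weights chosen by one of three methods: Bayesian model averaging
(BMA; weights proportional to marginal likelihood times prior model
probability), pseudo-BMA (softmax of estimated expected log pointwise
predictive densities, optionally averaged over Bayesian-bootstrap
reweightings of the data points), or stacking (weights maximizing the
leave-one-out log score of the mixture).

## The model set

Rather than transcribing many published ERK models, the package ships
three archetypes that span the main structural axes along which such
models differ; the MMI machinery itself is model-agnostic and accepts any
user-supplied `signaling_model`.

* **MA_CASCADE** (9 states): Raf-MEK-ERK with mass-action kinetics and
  distributive dual phosphorylation of MEK and ERK.  Dual phosphorylation
  makes the steady-state EGF-ERK dose-response ultrasensitive (Hill
  coefficient above 1), and the response to a sustained stimulus is
  sustained.
* **FB_CASCADE** (7 states): one-step Michaelis-Menten tiers with a
  divisive ERK-to-Raf negative-feedback factor $(1 + aERK/K_{fb})^{-1}$
  on Raf activation.  At nominal parameters the response is transient:
  active ERK peaks near 8 min and adapts to roughly 40% of peak,
  emulating cytoplasmic ERK activity.
* **RAP1_CASCADE** (11 states): FB_CASCADE plus an EGFR→C3G→Rap1→Raf
  branch that is *not* modulated by ERK feedback.  The branch sustains
  ERK activity (emulating plasma-membrane behavior), and setting the
  total Rap1 concentration to zero reduces the model *exactly* to
  FB_CASCADE — the construction used to simulate Rap1 inhibition
  (+Rap1GAP) in silico.

Every model carries EGF as a state with identically zero time derivative
(sustained stimulus), conserved totals per protein tier
(`Raf_tot`, `MEK_tot`, `ERK_tot`, ... in nM, fixed), and a free-parameter
mask over the kinetic rates.  Nominal rates were chosen once so that the
archetypes exhibit the qualitative phenomena above on the minute/nM
scales of the data; they are reconstructions, not transcriptions of any
published model.  The free masks cover the parameters that the package's
own Morris screening (`analysis/02_sensitivity.R`) classifies as
influential for the relevant quantity of interest, plus the Raf kinetics
that set trajectory timescales.

```{r models}
fb <- build_model("FB_CASCADE")
fb
tr <- simulate_model(fb, fb$params_nominal, seq(0, 40, by = 5), egf = 0.1)
round(active_erk(fb, tr), 1)
```

## Synthetic data generator

The generator emulates kinase-translocation-reporter microscopy data
(EKAR4-style emission ratios) and the standard preprocessing applied to
them:

* **Single-cell trajectories**: 76 cells by default, 0-40 min at 1-min
  spacing, 0.1 nM EGF.  Each cell simulates the model at the true
  parameters perturbed by i.i.d. lognormal factors with coefficient of
  variation 0.15 (mean 1), mapped to an emission-ratio scale
  $R(t) = r_0 + s\,(aERK/ERK_{tot} + \varepsilon)$ with additive Gaussian
  readout noise $\varepsilon$ of sd 0.05 (normalized units).  Per-cell
  random streams are derived deterministically from a root seed, so
  ensembles and their subsets are reproducible.
* **Dose-response curves**: 10 EGF levels log-spaced over 0.001-0.106 nM
  (the range spans two decades, so log spacing is the conventional
  choice), steady-state active ERK normalized to its maximum across
  levels, plus Gaussian noise of sd 0.1.
* **Preprocessing**: cell-wise min-max normalization; mean-max
  normalization (division by the pooled mean of cell-wise maxima across
  conditions, which preserves between-condition amplitude ratios);
  cell-wise mean and sample (n−1) standard deviation aggregation with an
  optional halving of the standard deviation for Rap1-inhibition data and
  a floor of 1e-6 to keep the Gaussian likelihood proper; truncation in
  time; seeded random cell subsets.

What the generator does *not* emulate: photobleaching and drift, temporal
noise correlation, cell segmentation artifacts, and non-Gaussian outlier
cells.  Passing tests therefore demonstrate the correctness of the
inferential machinery under the assumed noise model, not robustness to
every artifact of real microscopy data.  For the location studies the
emission-ratio mapping is the identity ($r_0 = 0$, $s = 1$), i.e. the
signal is treated as background-subtracted, because mean-max
normalization retains the baseline offset.

## Bayesian calibration

Priors are lognormal, centered (in log space) on the nominal value of
each free parameter, with a common scale chosen so 95% of the mass lies
within a factor $10^{\pm 2}$ of the nominal: $s = \ln(100)/z_{0.975} =
2.350$.  Sampling operates on log-parameters, where the prior is normal.
The likelihood is an independent Gaussian at each design point with the
data's per-point standard deviation; model predictions are normalized
exactly as the data are (trajectory-wise maximum for time courses,
curve-wise maximum for dose-response curves, and a location-wise shared
maximum for inhibition-paired condition data).  Solver failures at
extreme prior draws score $-\infty$ likelihood instead of aborting.

Posteriors and marginal likelihoods come from tempered sequential Monte
Carlo: the likelihood exponent rises from 0 to 1 in adaptive increments
chosen so the effective sample size of the incremental weights stays at
85% of the particle count; particles are resampled systematically and
mutated by an independent Metropolis-Hastings kernel whose Gaussian
proposal is moment-matched to the current particles, with passes
continuing until the correlation between pre- and post-mutation particle
coordinates drops below 0.01 (capped at a configurable number of passes).
The log marginal likelihood accumulates the log mean incremental weight
over stages, and per-chain estimates are averaged in log space across the
default four chains of at least 500 particles.  Averaging in log space
(rather than averaging evidences) is a deliberate choice; it is slightly
biased low but matches how chain estimates are conventionally pooled and
is what the BMA weights consume.

Numerical choices: the stiff ODE systems are integrated by `deSolve`'s
adaptive `lsoda` (automatic switching to a BDF method) at
`atol = rtol = 1e-6` and at most 6e6 steps, with compiled right-hand
sides.  Steady states use event-based integration (stop when
$\|dx/dt\|_2 \le 10^{-5} + 10^{-6}\|x\|_2$) followed by Newton
refinement; because conserved pools make the Jacobian singular, the
redundant equations are replaced by the conservation constraints.  Inside
dose sweeps each Newton solve is warm-started from the neighboring dose's
steady state, falling back to full integration if Newton fails or leaves
the positive orthant.

## ELPD estimation and weighting

The expected log pointwise predictive density (ELPD) is estimated three
ways: the in-sample LPD (known to be optimistic), brute-force
leave-one-out cross-validation (one SMC refit per held-out point, at a
reduced default budget of 2 chains x 250 particles), and PSIS-LOO —
importance sampling with the largest $M = \min(0.2S, 3\sqrt S)$ ratios
replaced by expected order statistics of a generalized Pareto
distribution fitted to the tail by the Zhang-Stephens profile-likelihood
method, truncated at the raw maximum.  The fitted shape $\hat k$ is
reported per point and values above 0.7 are flagged; ties in the ratios
are handled without a tail fit ($\hat k = 0$).  For dose-response data
the held-out point's prediction still uses the full dose design, because
the curve is normalized to its maximum across all doses.

Stacking maximizes the concave LOO log score over the simplex with an
EM-style fixed-point update from the uniform start (relative objective
tolerance 1e-10, at most 1e5 iterations); on flat objectives the uniform
start returns the symmetric solution.  The Bayesian bootstrap uses
Dirichlet(1, ..., 1) data-point weights and 1000 replicates by default.

## Predictions and metrics

Posterior draws are propagated forward as push-forward ensembles of the
quantity of interest or of the normalized observables; the posterior
predictive adds independent Gaussian measurement noise.  Mixtures are
realized by component resampling (draw a model with probability $w_k$,
then one of its rows), which is exact for all sample-based metrics used
downstream.  Error metrics: RMSE implemented literally as
$\sqrt{\sum_i r_i^2}\,/\,N$ (the form used throughout; a conventional
$\sqrt{\text{mean}}$ variant is provided as `rmse_conventional` for
comparison), relative error as a ratio of Euclidean norms, and
uncertainty as the mean width of the central 95% credible interval with
linear-interpolation percentiles.

## Experiment designs

`run_mmi` orchestrates calibration, ELPD estimation, weighting and
mixture scoring for a model set; `perturb_model_set` recomputes weights
after dropping the best- or worst-ELPD model while reusing cached
posteriors; `data_length_experiment` truncates trajectories at 10/20/30
min and scores the final 10 minutes; `data_quality_experiment` averages
40 replicate random subsets of 10/20/40/60 cells by default.
`hypothesis_comparison` fits parameter-sharing hypotheses jointly to
multi-location, multi-condition data: shared groups estimate one
posterior, location-specific groups duplicate their parameters per
location, Rap1-inhibited conditions zero the total Rap1 concentration,
and the pooled pointwise log-likelihoods feed PSIS-LOO.  The ELPD
standard error for comparing hypotheses is the standard deviation of
pointwise differences times $\sqrt N$.

A design note on the location study: with uninhibited data alone,
"stronger Rap1 at the membrane" and "weaker feedback at the membrane"
explain the data equally well — the hypotheses are confounded.  The
inhibition conditions break the tie: only a model with genuinely strong
membrane Rap1 predicts a large amplitude drop under Rap1 inhibition.
This is why `fit_hypothesis` normalizes predictions with a location-wise
shared maximum (mirroring mean-max-normalized data): per-trajectory
normalization would discard the between-condition amplitude ratio that
carries the inhibition signal.

## Problem sizes and reproducibility

The shipped analyses and tests run at desk scale: SMC budgets of 1-4
chains and 80-500 particles per chain, 6-20 cells or the full 76-cell
ensemble, and around 10 seeded replicates for recovery studies.  These
sizes were chosen as the smallest at which the studied effects (model
recovery, estimator agreement, hypothesis ranking) are decisively
resolved; all experiments accept larger budgets through `smc_settings`.
Every random quantity — cell ensembles, subsets, SMC chains, bootstrap
draws, mixtures — is derived deterministically from explicit integer
seeds, and identical seeds reproduce ensembles bit for bit.

## Known limitations

* The three archetypes are deliberately minimal; conclusions about any
  *specific* published ERK model require supplying that model.
* Chain-averaged log marginal likelihoods inherit SMC's variance;
  with few particles BMA weights are noisier than pseudo-BMA weights.
* PSIS-LOO is unreliable for points with $\hat k > 0.7$ (flagged but not
  corrected, e.g. by moment matching).
* The Gaussian likelihood takes the data's per-point standard deviation
  as known; no noise parameter is estimated.
* WAIC, K-fold CV, MCMC/NUTS samplers and structural identifiability
  analysis are out of scope.
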