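---
title: "Methods: activation, transmitted noise and channel capacity of promoters under a noisy master regulator"
author: "hillnoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activation, transmitted noise and channel capacity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

A single transcriptional activator A (measured per cell through a
fluorescent fusion, "RFP") drives a target promoter whose output B
("GFP") follows, at steady state, a Hill transfer curve

$$B(A) \;=\; b + V\,\frac{(A/K_d)^n}{1+(A/K_d)^n},$$

with amplitude $V$, basal level $b$, dissociation constant $K_d$ and Hill
coefficient $n$. $V$ and $b$ are ratios of production rates to the shared
degradation-and-dilution rate; snapshot (steady-state) data identify only
these ratios, which is why the package parameterizes the curve as
$(V, b, K_d, n)$ and never as separate production and degradation rates.

Three linked properties of a promoter follow from this curve:

* **Activation** — the curve itself, estimated from log-binned single-cell
  statistics.
* **Transmitted noise** — how strongly relative fluctuations in A appear
  in B. Empirically it is the ratio of coefficients of variation minus a
  floor, $\eta = (\sigma_B/\mu_B)/(\sigma_A/\mu_A) - S$; analytically it
  is the local log-log slope of the transfer curve,
  $\eta(A) = \mathrm{d}\ln B/\mathrm{d}\ln A$, which for $b = 0$ reduces
  to $n/(1+(A/K_d)^n)$ — equal to $n$ at low input, $n/2$ at $A = K_d$,
  and 0 at saturation. The floor $S$ collects intrinsic and extrinsic
  noise of the target that does not originate from the activator; it is
  treated as constant along the curve.
* **Channel capacity** — the maximum mutual information between input and
  output over input distributions supported on a physiologically relevant
  interval $[A_{\min}, A_{\max}]$. Under a small-noise Gaussian
  approximation with conditional output variance
  $\sigma^2(A) = B(A) + A_0\,A\,(\mathrm{d}B/\mathrm{d}A)^2$
  (Poisson-like output noise plus propagated Poisson-like input noise,
  $A_0$ a concentration-scaling term), the capacity is
  $\log_2(Z) + X$ with

  $$Z \;=\; \int_{A_\min}^{A_\max}
     \sqrt{\frac{(\mathrm{d}B/\mathrm{d}A)^2}
                {B(A) + A_0\,A\,(\mathrm{d}B/\mathrm{d}A)^2}}\;\mathrm{d}A .$$

  $X$ is an additive constant introduced by the approximation and
  independent of the promoter parameters. The package never evaluates
  $X$: all capacities are reported as `capacity_rel = log2(Z)` and
  compared only as differences. The claim that $X$ really is
  parameter-independent is *tested*, not assumed: a brute-force
  Blahut–Arimoto solver on a finely discretized version of the same
  Gaussian channel provides absolute capacities, and the offset
  `blahut_arimoto(...) - log2(Z)` is checked for constancy across a
  $(K_d, n)$ grid (see "Numerical choices").

Promoters fall into two qualitative classes. *Amplifying* promoters (low
$K_d$, high $n$) respond steeply at low activator and saturate within the
physiological range: they turn small input fluctuations into large output
fluctuations and transmit information best when inputs are low.
*Filtering* promoters (high $K_d$, low $n$) are flat at low activator:
they attenuate low-level fluctuations and transmit information only when
the input range is high. *Chimeric* promoters — the activator-binding box
of one class in the backbone of the other — have intermediate $(K_d, n)$
and consequently intermediate noise and capacity. An unregulated
*control* class closes the loop: its output ignores the activator, its
transmitted noise is zero, and its CV estimates the floor $S$
(`noise_floor_from_control()`).

# The synthetic-data generator

No public single-cell dataset accompanies this analysis, so the package
ships a generator (`generate_sweep()`, `generate_background()`) that
emulates the statistical structure the analysis assumes, and every claim
the test suite makes about "data" is a claim about this generator.

What it emulates:

* **Induction sweep.** Twelve conditions mimicking an IPTG titration
  (0–100 in steps of 10, plus 500 µM); condition means for the activator
  rise affinely with inducer (`default_induction_levels()`: basal 15,
  gain 4 per µM, in arbitrary fluorescence units), so the pooled sweep
  covers a broad, right-skewed activator range with the 500 µM condition
  far above the rest. At least 100 cells per condition (default 100).
* **Cell-to-cell variability.** Within a condition the activator is
  log-normal with CV `extrinsic_cv` (default 0.35). Log-normality is the
  standard model for extrinsic expression variability: right-skewed,
  strictly positive, multiplicative.
* **Reporter noise.** Multiplicative log-normal intrinsic noise with mean
  1 (`reporter_intrinsic_cv`, default 0.15) and an additive zero-mean
  Gaussian measurement floor (`measurement_floor_sd`, default 20 a.u.),
  truncated so fluorescence stays non-negative. The additive floor is the
  generator-side realization of the noise floor $S$: a noise source in B
  that does not come from A.
* **Backgrounds.** Two unimodal right-skewed activator distributions for
  reporter-only experiments: "wildtype" (mean 30) and "marAplus"
  (de-repressed, mean 600), CV 0.4, with validation enforcing
  wildtype < marAplus. The generator always draws the latent activator
  and can mask it (`mask_activator = TRUE`) to mimic reporter-only data
  while retaining the truth for validation.

What it does **not** emulate: image formation and segmentation errors,
cell-cycle and size effects, growth-rate coupling, plasmid copy-number
fluctuations, channel crosstalk, day effects. Passing tests therefore
demonstrate that the *estimators* are correct and well-calibrated under
the stated generative model, not that real microscopy data meet that
model.

Fixture parameters (`promoter_fixtures()`, `inst/extdata/promoters.yaml`)
are implementer-chosen synthetic values realizing the qualitative classes
— two amplifying ($K_d$ 70 and 90, $n$ 2.4 and 2.0), four filtering
($K_d$ 700–900, $n$ 0.9–1.2, with the inaA-like $K_d$ ten times the
micF-like one), two chimeras between the marRAB-like and acrAB-like
parents, one control. Amplitudes are a few thousand arbitrary units, the
scale at which Poisson-like fluorescence statistics give percent-level
CVs. No absolute calibration is attempted.

# Binning, bootstrap and the joint fit

Pooled cells are binned logarithmically between the smallest positive and
largest activator value (`n_bins = 20`); bins with 25 or fewer cells are
excluded — the conventional threshold below which per-bin CVs are too
unstable to use. The fitting abscissa is the per-bin *mean* of A, not the
geometric bin center. Per-bin dispersion of the noise curve comes from
bootstrap subsampling: one third of the pooled cells, drawn without
replacement, 100 times, re-binned on the *same* edges. Subsampling
(rather than a same-size resample with replacement) is used because a
one-third draw is a genuine subsample; the same estimator is applied to
simulation ensembles so that simulated and "experimental" error bars mean
the same thing.

One caveat is intrinsic to binned noise curves: the within-bin CV of A
depends on the bin width. The package fixes the log-bin width through
`n_bins` and documents it; for synthetic or simulated data where the
generating condition of every cell is known,
`transmitted_noise_by_condition()` reports the per-condition (fixed-input
ensemble) noise, which has no such dependence.

Because the analytic noise curve is the derivative of the activation
curve, both share one parameter set, and `fit_joint()` estimates
$(V, b, K_d, n, S)$ simultaneously: standardized squared residuals of the
bin means against the Hill curve (weights from per-bin standard errors)
plus, with a configurable balance factor defaulting to 1:1, standardized
squared residuals of the *raw* CV-ratio curve against
$\eta_{\text{analytic}}(A) + S$ (weights from the bootstrap SDs). The
noise curve handed to the fit must be computed with $S = 0$; the floor is
a fitted parameter, not a pre-subtraction. The optimizer is differential
evolution — population $15\times$ dimension, rand/1/bin, crossover 0.9,
mutation factor dithered in $[0.5, 1]$, at most 500 generations,
seed-deterministic — with $K_d$ searched on a log10 scale inside
$[\min A/10, \max A \times 10]$, $n \in (0.3, 6]$, $V$ and $b$ within the
observed output range and $S \in [0, \max \eta]$, followed by a bounded
L-BFGS-B polish. On noiseless data the fit recovers the generating
parameters to optimizer precision; on default-noise sweeps
(12 × 200 cells) the median $K_d$ error across seeds is well under 15%
and $n$ under 20% (the acceptance script reports both). Flat responses —
an unregulated control, or data whose dynamic range is indistinguishable
from bin noise (range below six median standard errors, about the
expected spread of twenty independent bin means) — are flagged `"flat"`
rather than reported as meaningful $(K_d, n)$.

# The stochastic cascade

`integrate_cascade()` and `run_sweep()` simulate

$$\dot A = \alpha_A - \beta A + I_A, \qquad
  \dot B_j = \alpha_j\,\mathrm{hill}_j(A) - \beta B_j,$$

with $I_A$ an Ornstein–Uhlenbeck process of stationary SD $\sigma_I$ and
correlation time $\tau = T_{\text{int}}/\ln 2$ ($T_{\text{int}} = 5$ min,
so the intrinsic noise decorrelates with a 5-minute half-time). Design
decisions:

* **Exact OU update.** The OU term uses its exact discrete-time solution
  ($I' = I e^{-\Delta t/\tau} + \sigma_I\sqrt{1-e^{-2\Delta t/\tau}}\,\xi$),
  so its stationary SD carries no discretization bias at any step size;
  A and the $B_j$ use Euler steps, with an explicit error (not silent
  inaccuracy) if $\Delta t$ exceeds $\tau/5$ or $0.2/\beta$.
* **Clipping.** A is clipped at zero after each step; the continuous
  model is silent about negativity and clipping is the minimal
  intervention.
* **$\sigma_I$.** The intrinsic-noise magnitude is an independent
  parameter, by default a fixed fraction (`sigma_frac = 0.1`) of
  $\alpha_A$ — input-proportional noise at 10%, a typical scale of
  cell-to-cell variability and small enough that the leading-order
  (small-noise) analytic comparison below is meaningful.
* **No intrinsic B noise.** Each $B_j$ is a deterministic ODE slaved to
  the stochastic A, so transmitted noise is the *only* noise source in B
  and the simulated CV ratio needs no floor ($S = 0$).
* **Quasi-static regime.** The analytic identity "transmitted noise =
  log-log slope" holds when B tracks the instantaneous Hill value of A,
  i.e. when relaxation is fast relative to the input noise
  ($\beta\tau \gg 1$). The sweep default is $\beta = 5\,/\text{min}$
  ($\beta\tau \approx 36$), the regime of actively degraded reporters.
  With slow, dilution-limited degradation B low-pass filters A and the
  CV ratio falls below the analytic curve by the filtering factor —
  a real effect users can explore by lowering `beta`, but not the regime
  in which the identity is being verified.
* **Sampling.** Per grid point, `n_replicates = 50` trajectories are
  integrated (vectorized across the whole grid), burn-in of ten slowest
  relaxation times is discarded, and 10 snapshots per replicate are
  collected three relaxation times apart — about 500 approximately
  decorrelated stationary samples per grid point. The sweep covers 30
  log-spaced input production rates, with per-point dispersion from the
  same one-third subsampling bootstrap as the data path.

With these defaults the ensemble CV ratio matches the analytic curve
within three bootstrap SDs at well over 90% of grid points, and the
unregulated control's transmitted noise is exactly zero (its B is
constant in every replicate).

# Information-theoretic estimates

**Input distributions.** Reporter-only measurements see only B; the
latent activator distribution is estimated by matching each reporter-only
cell to the activator/reporter sweep cell with the nearest B and
collecting that cell's A (ties broken by first occurrence after a stable
sort; values outside the sweep's B range match the nearest extreme cell,
with a warning when the ranges are fully disjoint). Matched A values are
pooled across the included promoters; the marRAB-like promoter is
excluded by default because in the de-repressed background its own
repressor is co-overexpressed and its reporter does not track the
activator faithfully. The 5th and 95th percentiles of the pooled sample
become $[A_{\min}, A_{\max}]$. This estimator inverts the transfer curve
implicitly, so it is only as good as the curve is informative: through a
monotone, low-noise, responsive mapping it recovers latent percentiles to
a few percent, but promoters that are flat over the relevant range
contribute noise-dominated matches, and estimates are generally sensitive
to the choice and noise of the mapping promoters — a sensitivity the
pipeline reports rather than hides.

**Capacity.** $Z$ is computed by adaptive quadrature (absolute tolerance
$10^{-8}$); an empty interval or a flat response yields $Z = 0$, reported
as a `-Inf` sentinel with an explanatory note rather than an error. The
oracle channel discretizes the same Gaussian model on a uniform input
grid with output bins spanning the conditional means ±6 SD (outer bins
extended to infinity so rows sum to one exactly), and Blahut–Arimoto
iterates until its upper and lower capacity bounds differ by less than
$10^{-7}$ bits. The oracle-constancy check uses a high-amplitude template
($V = 2\times 10^5$) because $X$ is *defined* by the small-noise limit:
at fixture-scale amplitudes (percent-level CVs) the approximation error
is visible as a slow drift of the offset, which is informative about the
regime of validity but not about the implementation. On the high-
amplitude grid the offset's SD is about 0.026 bits across a 3×3
$(K_d, n)$ grid.

**Mutual information.** Plug-in histogram estimator on an equal-count
(quantile) 20×20 grid with Miller–Madow bias correction; discrete inputs
with at most 20 distinct values are used as-is. The estimator warns when
fewer than $\text{bins}^2/10$ samples are supplied. Estimated MI is
always at most the matched oracle capacity (data-processing bound, up to
estimator tolerance), which the acceptance script verifies over several
bounded input distributions.

**$A_0$.** The input-noise scaling defaults to 1 in generator units and
is configurable; since it enters the conditional variance it shifts all
capacities, and results should be read as conditional on the chosen
$A_0$.

# Pipeline and reproducibility

`run_pipeline()` chains generate → bin/fit → noise → input estimation →
capacity (under both background bounds) → mutual information over a
promoter fixture set, writing CSV/JSON artifacts and a manifest with MD5
hashes, per-stage seeds (derived deterministically from one master seed)
and timings. Reruns with the same configuration are byte-identical; a
stage failure aborts with a stage-attributed error after writing a
partial manifest. Plots (`pipeline_report()`) are diagnostic artifacts,
never analysis surfaces.

Every stochastic function takes a seed and restores the caller's RNG
state; identical seeds give byte-identical outputs everywhere (generator,
simulation, bootstrap, optimizer, pipeline).

Problem sizes used by the shipped tests and the acceptance script — 12
conditions × 200 cells and 20 seeds for recovery studies, 30 grid points
× 50 replicates × 10 snapshots for the sweep, 3×3 parameter grids with
300×700 discretizations for the capacity oracle, 5000-sample MI
estimates — were chosen as the smallest sizes at which the statistical
tolerances above are comfortably resolved.

# Known limitations

* The floor $S$ is subtracted as a constant, as in the standard
  transmitted-noise decomposition; strictly, an independent additive
  noise source would enter in quadrature, so $S$ is an effective, not
  mechanistic, parameter.
* Binned CV ratios inherit a bin-width dependence on the input side
  (documented above).
* The capacity analysis is relative ($X$ unevaluated) and conditional on
  $A_0$ and on the small-noise Gaussian channel form.
* The generator and simulation exclude feedback, cell division and
  partitioning noise, discrete-molecule (Gillespie) effects, and
  repression; the analytic framework extends to repressors (the log-log
  slope argument is sign-agnostic) but the package does not implement
  them.
* Nearest-neighbour input estimation degrades for uninformative
  (flat-range) mapping promoters and is sensitive to the input
  distribution; treat pipeline input estimates as diagnostics unless the
  mapping promoter is responsive over the relevant range.
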