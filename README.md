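# hillnoise

Single upstream regulators of bacterial stress-response networks — MarA of
*E. coli* is the canonical example — control dozens of downstream genes
through one noisy signal. How each target *decodes* that signal is set by
the shape of its transfer curve: promoters with a low dissociation constant
and steep activation **amplify** the regulator's cell-to-cell fluctuations,
while promoters with a high dissociation constant and shallow activation
**filter** them, and these same parameters decide how much *information*
the physiological range of regulator levels can push through each promoter.

`hillnoise` packages that analysis for per-cell two-channel fluorescence
snapshot tables (activator channel "RFP", reporter channel "GFP"), for
R users working on gene-expression noise and information transmission:

* **Activation.** Steady-state Hill transfer curve
  `B(A) = b + V (A/Kd)^n / (1 + (A/Kd)^n)`, with log-binned single-cell
  statistics (`bin_cells()`, bins with more than 25 cells by default).
* **Transmitted noise.** Empirically the ratio of output to input
  coefficients of variation minus a regulation-independent floor `S`
  (`transmitted_noise_empirical()`); analytically the log-log slope of the
  transfer curve, `eta(A) = d ln B / d ln A`, which reduces to
  `n / (1 + (A/Kd)^n)` for zero basal level
  (`transmitted_noise_analytic()`). Dispersion by bootstrap subsampling of
  one third of the cells, 100 times (`bootstrap_eta()`).
* **Joint fitting.** Both curves share one parameter set `(V, b, Kd, n)`
  plus the floor `S`; `fit_joint()` estimates all five simultaneously by
  differential evolution (rand/1/bin, seed-reproducible) with an L-BFGS-B
  polish.
* **Stochastic simulation.** The cascade `dA = (alpha_A - beta A + I_A) dt`,
  `dB = alpha hill(A) - beta B dt`, with `I_A` an Ornstein–Uhlenbeck
  intrinsic-noise term (correlation time `T_int/ln 2`, `T_int` = 5 min),
  swept over 30 log-spaced input production rates
  (`sweep_spec()` / `run_sweep()`).
* **Information.** Bounded channel capacity under the small-noise
  approximation, `capacity_rel = log2(Z)` with
  `Z = ∫ sqrt((dB/dA)^2 / (B + A0 A (dB/dA)^2)) dA` over the 5th–95th
  percentile input range (`capacity_small_noise()`, `capacity_map()`);
  a Blahut–Arimoto brute-force oracle on the discretized channel
  (`blahut_arimoto()`); nearest-neighbour estimation of latent input
  distributions from reporter-only data (`estimate_input_distribution()`);
  and histogram mutual information with Miller–Madow bias correction
  (`mutual_information()`).
* **Synthetic data.** `generate_sweep()` / `generate_background()` emulate
  the 12-condition induction sweep and the wild-type / de-repressed
  ("MarA+") background strains with log-normal extrinsic variability,
  multiplicative intrinsic reporter noise and an additive measurement
  floor, so the whole pipeline is testable without microscopy data.
* **Pipeline.** `run_pipeline()` chains all stages over the shipped
  promoter fixture set and writes CSV/JSON artifacts plus a seed- and
  hash-carrying manifest; `pipeline_report()` summarizes and plots.

## Worked example

Fit one synthetic amplifying promoter and ask how much information it
transmits under low (wild-type-like) versus high (MarA+-like) input bounds:

```r
library(hillnoise)

micF <- promoter_fixtures()[["micF"]]          # V=2500, b=50, Kd=70, n=2.4
cfg  <- generator_config(cells_per_condition = 200, seed = 1)
cells <- generate_sweep(micF, cfg)             # 12 conditions x 200 cells

binned <- bin_cells(cells, n_bins = 20, min_count = 25)
eta_sd <- bootstrap_eta(cells, edges = attr(binned, "edges"), seed = 1)
noise  <- transmitted_noise_empirical(binned, S = 0, eta_sd = eta_sd)
fit    <- fit_joint(binned, noise, seed = 1)
fit
#> <fit_result>
#>   V = 2492, b = 47.79, Kd = 69.47, n = 2.38, S = 1.41
#>   fitness = 3.217 over 17 bins; 233 DE generations

mod <- channel_model(fit$params, A0 = 1)
capacity_small_noise(mod, 15, 52)$capacity_rel     # wild-type-like bounds
#> 2.72
capacity_small_noise(mod, 296, 1050)$capacity_rel  # MarA+-like bounds
#> 0.54
```

The fit recovers the generating parameters (true `Kd` 70, `n` 2.4) to a few
percent, plus the noise floor `S` contributed by the intrinsic and
measurement noise of the generator. The capacity numbers are `log2(Z)`
values — capacities *relative* to the additive small-noise constant, so
only their differences are meaningful: this steep low-`Kd` promoter
transmits about 2.2 bits *more* under low, wild-type-like inputs than under
high inputs, where it saturates and all input values map to the same
output. Filtering promoters (high `Kd`, low `n`; see
`promoter_fixtures()`) show the opposite ordering.

A thin command-line wrapper over these functions ships at
`inst/scripts/hillnoise-cli.R` (subcommands `generate`, `fit`, `noise`,
`simulate`, `capacity`, `run`).

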