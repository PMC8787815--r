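---
title: "Resource-limited kinetics of cell-free gene expression: model, inference and population analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resource-limited kinetics of cell-free gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 3.5)
library(cfekinetics)
library(dplyr)
```

## The model

Cell-free expression systems (CFES) such as the reconstituted PURE
system express a gene from a DNA or mRNA template until their finite
pools of substrates and active machinery run out. `cfekinetics`
describes this with a coarse-grained model in which two unitless
*resource* pools — a transcription resource TsR and a translation
resource TlR, both initialized at 1 — multiply the corresponding
fluxes, are consumed in proportion to them, and additionally decay
spontaneously. With `DNA` the (constant) template concentration, `R`
the transcript, and `R_tau = R(t - tau_d)` the delayed transcript seen
by the translation machinery:

$$
\begin{aligned}
v_{tx} &= k_r \, \mathrm{TsR} \, \frac{\mathrm{DNA}}{K_r + \mathrm{DNA}}, &
v_{tl} &= k_p \, \mathrm{TlR} \, \frac{R_\tau}{K_p + R_\tau},\\[2pt]
\dot R &= v_{tx} - \delta_r R, &
\dot{\mathrm{TsR}} &= -a\, v_{tx} - \delta_{TsR}\,\mathrm{TsR},\\[2pt]
\dot P_{dark} &= v_{tl} - k_{mat} P_{dark}, &
\dot{\mathrm{TlR}} &= -b\, v_{tl} -
  \delta_{TlR}\,\frac{\mathrm{TlR}}{K_l + \mathrm{TlR}},\\[2pt]
\dot P_{mat} &= k_{mat} P_{dark}. &&
\end{aligned}
$$

The observable channels are the transcript (an RNA aptamer reporter)
and the *mature* fluorescent protein; translation first produces a
dark protein that matures with first-order rate $k_{mat}$. The
translation delay $\tau_d$ reproduces the protein onset lag seen in
mRNA titrations, and a measurement lag $\tau_l$ maps data time $t$ to
model time $t - \tau_l$ (a pure reporting shift; observed channels are
zero for model times $\le 0$). The delay history is the constant
$R(s) = \mathrm{rna}_0$ for $s \le 0$, the simplest choice consistent
with experiments started by adding purified transcripts. DNA is
constant: the model has no template sink.

Seven structural variants of this family are candidates for model
selection (`model_variants()`): both fluxes may use Michaelis–Menten
or mass-action kinetics, TsR degradation may be present or absent, and
TlR degradation may be Michaelis–Menten or first-order. V1 is the full
structure above; V2 (no TsR degradation) corresponds to the earlier
resource-limited models this family generalizes.

Parameters, with the reference bulk estimates `theta_bulk()` and
synthetic-cell estimates `theta_cell()` shipped as defaults:

```{r params}
param_units() |> mutate(bulk = as.numeric(theta_bulk()))
```

## Simulation

The right-hand side is compiled C invoked through `deSolve`: the delay
system is integrated with `deSolve::dede()`, whose stored dense
solution history supplies $R(t-\tau_d)$ (the standard adaptive
realization of the method of steps). When $\tau_d < 10^{-3}$ h the
delay is dynamically negligible and the plain ODE path is used
instead, avoiding needless history bookkeeping. Default tolerances are
`rtol = 1e-8`, `atol = 1e-10`; states are clamped at zero inside rate
expressions, and output excursions beyond $-10^{-9}$ nM trigger a
warning. These choices are validated in the test suite against an
independent fixed-step Euler integration (step $10^{-4}$ h, agreement
within $10^{-3}$ relative) and against the closed-form
frozen-resource limit $(k_r/\delta_r)(1 - e^{-\delta_r t})$ (within
$10^{-5}$).

```{r simulate}
traj <- cfe_simulate(theta_bulk(), dna0 = 3.75,
                     times = seq(0, 8, by = 1 / 6))
max_rates(traj)
```

Transcription is fastest at $t = 0$ (its flux is a product of
non-increasing factors) while translation peaks between one and two
hours, once transcript has accumulated but resources are still
plentiful — the qualitative signature of resource-limited expression.

## Likelihood, fitting, and model selection

Measurement errors are modelled as independent Gaussians per channel.
The data never identify the error model on their own, so three
conventions are offered (`noise_spec()`): fixed channel SDs, SDs
pooled from replicate scatter (the default; it matches data reported
as triplicate mean ± SD), or SDs profiled out analytically. The
negative log-likelihood of a parameter set is the usual
$\sum_c [n_c/2 \log(2\pi\sigma_c^2) + \mathrm{RSS}_c/2\sigma_c^2]$
summed over the mRNA and protein channels of every experiment in a
titration dataset; solver failures at extreme parameters return a
large finite penalty ($10^{10}$) rather than an error, so optimizers
can continue.

`cfe_fit()` maximizes the likelihood in log10-parameter space —
estimates span more than twelve decades, so a linear-scale search is
hopeless — inside box bounds (default $[10^{-8}, 10^8]$), from
Latin-hypercube multistarts: a Levenberg–Marquardt least-squares stage
followed by a Nelder–Mead polish of the exact objective. Two optional
globalization stages handle the rugged landscapes of the
full-structure variants, where local stages from random
high-dimensional starts stall in distant local minima: *screening*
(rank all starts by their initial objective, optimize only the most
promising) and *basin hopping* (seeded log-space perturbations of the
incumbent, ~0.3 decades SD, re-optimized locally and kept on
improvement). Both are applied uniformly across variants in the
model-selection studies. The
maturation rate `k_mat` is pinned by default at 2.15 h$^{-1}$, its
independently measured value, and `tau_l` is pinned at 0 for bulk data
(bulk runs reach the plate reader within minutes); both conventions
are overridable, and `tau_l` should be freed for encapsulated
populations where sample preparation takes ~0.5 h. Fits are
reproducible bit-for-bit from `(data, config, seed)`.

Variants are compared by AIC, $2k + 2\,\widehat{\mathrm{NLL}}$ with
$k$ the free-parameter count; `rank_models()` sorts ascending with
ties broken by parsimony and refuses to rank fits made on different
datasets.

```{r fit, eval = FALSE}
data <- generate_bulk_titration(generator_config(seed = 1))
fit <- cfe_fit(data, free = c("k_r", "K_r", "delta_r", "k_p", "K_p"),
               fixed = c(k_mat = 2.15, tau_l = 0, delta_TsR = 0.231,
                         delta_TlR = 0.0884, K_l = 1.21e-6,
                         a = 4.45e-4, b = 1.78e-4, tau_d = 0.433),
               bounds = default_bounds(theta_bulk()),
               n_starts = 5, seed = 1)
tidy(fit)
```

## Identifiability: profile likelihoods and CIs

`cfe_profile()` fixes one parameter on a log-spaced grid spanning one
decade either side of its MLE and re-optimizes all others at each
point, warm-starting from the neighbouring grid point and walking
outward from the center. `likelihood_ci()` intersects the profile with
the threshold $\widehat{\mathrm{NLL}} + \chi^2(\alpha, \mathrm{df})/2$
(crossings by linear interpolation between grid points). A side that
never crosses inside the window is reported as $-\infty$/$+\infty$:
the parameter is non- or weakly identifiable within one order of
magnitude of its estimate. That one-decade window is deliberately part
of the reported semantics — widening it changes what "non-identifiable"
means — and is configurable via `span`.

Two df conventions exist for the threshold. The default follows the
simultaneous reading, df = $k$ (all free parameters), which is wider
than the pointwise df = 1 convention; pass `df = 1` to
`likelihood_ci()` for pointwise intervals. The machinery is exact on
closed-form toys (a quadratic NLL gives $1 \pm 0.1\sqrt{\chi^2}$ for
both df choices; a perfect likelihood ridge profiles flat and returns
an infinite interval), and on a linear-Gaussian toy the df = $k$
intervals cover the truth in at least 95% of replicates, as the
over-covering convention should.

## Calibration and derived physical quantities

Fluorescence is converted to concentration through a forced-linear
least-squares calibration (`fit_calibration()`, warning when
$R^2 < 0.98$); readings below the intercept map to negative
concentrations and are flagged but *not* clipped, so near-zero signal
statistics stay unbiased. Derived quantities follow by exact
arithmetic: per-polymerase transcription rate
$k_r L_{rna} / (3600\, C_{RNAP})$ NTP/s (with the 1087 nt transcript,
100 nM T7 RNAP), per-ribosome translation rate
$k_p L_{prot} / (3600\, C_{ribo})$ aa/s (777 aa, 2400 nM ribosomes),
maturation half-time $60 \ln 2 / k_{mat}$ minutes, and sphere-volume
copy numbers (linear in concentration, cubic in radius). Note that
$60\ln 2 / 2.15 = 19.34$ min while the reference half-time is printed
as 19.31 min — the 0.03 min gap comes from rounding of the printed
rate and is documented rather than silently matched.

```{r units}
c(ntp_per_s = polymerase_rate_ntp_per_s(2894),
  aa_per_s = ribosome_rate_aa_per_s(2568),
  t_half_min = maturation_half_time(2.15),
  dna_copies = copy_number(30.4, 3.5))
```

## The synthetic-data generator

Because the experimental measurements behind the reference estimates
are not machine-readable, every pipeline stage is exercised against a
seeded generator whose defaults *are* the reference study conditions:

* **Bulk titrations**: DNA levels `c(0.94, 1.875, 3.75, 7.5)` nM
  around the 3.75 nM saturation level (mRNA template levels
  configurable, saturation 600 nM), triplicate, sampled every 10 min
  for 8 h, with independent proportional Gaussian noise of CV 0.02 per
  channel per time point. Negative noisy values are truncated at zero
  and counted.
* **Populations**: 85 cells per population, radius
  $\sim \mathcal{N}(30.4, \mathrm{CV}\,0.064)$ truncated positive,
  per-cell expression factor of CV 0.022 shared between channels,
  measurement lag $\tau_l = 0.5$ h, 12 h sampled every 5 min; optional
  batches with a batch factor of CV 0.10.

Two generator choices deserve explanation. First, the per-cell
expression factor defaults to a *yield* interpretation: it scales the
observed mRNA and protein channels jointly. This preserves the CV from
mRNA to protein — the defining feature of the monodisperse populations
being emulated — and makes the realized endpoint CV equal the
configured one by construction. The alternative `"kinetic"` mode
applies the factor to $k_r$ and $k_p$ instead; under resource-limited
kinetics the endpoint response to a rate perturbation is strongly
nonlinear and channel-dependent (measured endpoint log-sensitivities
at the cell parameters, 3.5 nM DNA, are ≈ 0.30 for mRNA vs ≈ 1.44 for
protein), so that mode produces unequal channel CVs and is kept only
for sensitivity studies. Second, with both the expression factor
(CV 0.022) and measurement noise (CV 0.02) on, the endpoint
observation CV is their quadrature sum ≈ 0.030; round-trip checks
compare recovered endpoint CVs against this combined value, and the
radius CV against its configured value directly. Radius variation does
not feed back into the kinetics, since concentrations are intensive.

What passing these round trips shows — and what it does not: the
generator reproduces the *statistical structure* the analysis assumes
(deterministic kinetics per cell, multiplicative well-mixed
variability, Gaussian measurement noise). Real micrographs add
segmentation error, laser drift, membrane transport and other
structure the generator deliberately omits, so green tests validate
the machinery, not the biology of any particular dataset.

## Numerical and design choices

* Optimization: log10 space, LM stage capped at 50 iterations, NM
  polish capped at 150 evaluations (tightened in the heavier
  Monte-Carlo suites), multistart count per use case. A start can
  never end worse than where it began.
* Profiles: 21-point grids by default, warm-started outward walk;
  failed re-optimizations flag the point rather than aborting.
* CIs: linear interpolation of the crossing; an inconsistent profile
  (minimum above threshold) is an error, not silently clamped.
* Ties in model ranking: smaller $k$, then variant code.
* Degenerate inputs: MM terms with zero $K$ and zero substrate raise a
  singularity error; `cv()` refuses zero means and single values;
  populations need at least two cells at the endpoint.
* Problem sizes in the shipped studies (test suite and acceptance
  script) are chosen to make Monte-Carlo conclusions stable at
  desk scale: 20 seeds for recovery/selection round trips in the
  tests, 8–10 in the acceptance script; 3 DNA levels × triplicate, 30
  min sampling for fitting studies; recovery fits free the five core
  kinetic parameters $(k_r, K_r, \delta_r, k_p, K_p)$ with resource
  and delay parameters pinned at their generating values, and
  selection fits free all structure-bearing parameters with only
  $k_{mat}$, $\tau_l$, $\tau_d$ pinned, under a uniform
  screened-multistart + basin-hopping protocol (18 starts screened to
  4, 6 hops).

## Known limitations

* The likelihood treats time points as independent; correlated
  residuals (e.g. drift) would narrow the reported CIs artificially.
* Stochastic (copy-number) effects are deliberately out of scope:
  at $\sim 10^5$ DNA copies per 30 µm cell, intrinsic noise is
  negligible compared to the measured population CVs.
* Membrane transport between a synthetic cell and its outer feeding
  solution is not modelled; parameters fitted to encapsulated data
  absorb those effects phenomenologically.
* The batch CV of maximum translation rates depends mildly on the
  rate estimator (3-point smoothed central differences by default);
  the smoothing width is configurable.
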