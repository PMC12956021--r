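---
title: "Clonal fluctuation analysis of reversible anoikis resistance"
author: "cloneFluct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal fluctuation analysis of reversible anoikis resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneFluct)
```

# The question and the design

Anoikis is the programmed death of cells that lose attachment to the
extracellular matrix. When an anoikis-sensitive (AnS) tumour-cell
population acquires resistance (AnR) after suspension stress, the origin
of that resistance can be probed with a fluctuation test in the
Luria–Delbrück tradition: expand single-cell clones for many generations
under permissive (attached) conditions, then challenge each clone with
suspension stress and compare the *clone-to-clone variability* in
survival with what candidate models predict.

- If resistance is a stably heritable clonal property, switching decisions
  made early in each clone's expansion are amplified to very different
  resistant fractions, and the interclonal coefficient of variation (CV)
  of survival is large.
- If cells switch between an AnS and an AnR state rapidly relative to the
  expansion depth, every clone converges to the same equilibrium mixture
  and the CV collapses toward the demographic-sampling floor.

`cloneFluct` packages the quantitative side of this design: the two-state
switching model and its closed-form survival relations, a
branching-process simulator of the full protocol, fluctuation statistics
with bootstrap confidence intervals, a memory-decay model for reversion
of the acquired state, and synthetic-data generators.

# The two-state model

A cell is sensitive (S) or resistant (R). At each division, a daughter of
an S cell becomes R with probability $k_\mathrm{on}$ and a daughter of an
R cell becomes S with probability $k_\mathrm{off}$, independently of its
sister. The per-lineage state probability $m_g$ follows
$m_{g+1} = m_g(1-k_\mathrm{off}) + (1-m_g)k_\mathrm{on}$, relaxing to the
equilibrium resistant fraction
$f_\mathrm{eq} = k_\mathrm{on}/(k_\mathrm{on}+k_\mathrm{off})$ with
per-generation factor $\lambda = 1-k_\mathrm{on}-k_\mathrm{off}$. The
resistant state's memory is its mean residence time
$M = 1/k_\mathrm{off}$ generations (geometric residence); the package
parameterises models either by $(k_\mathrm{on}, k_\mathrm{off})$ or by
$(M, f_\mathrm{eq})$, which is the natural frame when what is known
experimentally is a transient heritability of about 10–11 generations.
The default memory is $M = 10.5$, the midpoint of that range.

In a suspension assay of duration $T$ (24 h by default), resistant cells
proliferate with rate $\gamma = \ln 2 / T_d$, where $T_d$ is their
suspension doubling time, and sensitive cells die. With the default
"all dead at assay end" mode for sensitive cells, the expected measured
survival fraction (live cells at $T$ over cells plated) obeys the
survival balance
$$ f\,e^{\gamma T} = \bar S, $$
so the resistant fraction at plating is recoverable as
$f = \bar S\,2^{-T/T_d}$. With $\bar S = 0.9$, $T = 24$ h and
$T_d = 100$ h this gives $f \approx 0.76$: the package's canonical worked
example (`resistantFractionFromSurvival(0.9, 24, 100)`). Survival
fractions above 1 mean net growth in suspension and are never clipped;
an implied $f > 1$ is reported as infeasible rather than silently
clamped. An exponential sensitive-death mode (rate per hour) is available
for sensitivity analysis.

The model treats $\bar S = 0.9$ as the cohort mean of clonal survivals;
the source data report ~0.9 both as that mean and as the population
value, and we do not attempt to distinguish the two.

# Simulating the protocol

`fluctuationExperiment()` simulates, per clone: a single founder (state
drawn from the equilibrium distribution by default — clones are picked
from a population assumed to be at steady state; the founder rule is a
parameter), $G = 20$ generations of attached expansion, hypergeometric
subsampling of $N_0 = 250{,}000$ cells from the $2^{20}$-cell clone, and
the stochastic suspension assay (resistant cells as a Yule pure-birth
process, giving the $e^{\gamma T}$ expectation).

Two modelling choices matter:

- **Deterministic doubling, stochastic switching.** Every cell divides
  once per generation; randomness enters through daughter-state switching
  only. The object of the analysis is state-switching noise, not
  demographic birth–death noise, and attached growth of these lines is
  close to deterministic on the 20-generation horizon. Switching happens
  at division only, and the 24-h assay (shorter than one attached
  generation) applies no further switching by default.
- **Aggregate-count propagation.** Per-generation binomial draws on the
  $(n_S, n_R)$ counts are distributionally identical to per-cell
  simulation (daughters switch independently), so $2^{20}$-cell clones
  and 250,000-cell assays cost microseconds. A literal per-cell engine
  (`mode = "percell"`) exists for small instances; the test suite checks
  the two agree by KS test, and checks the Monte Carlo CV against an
  exhaustive enumeration oracle on small instances.

`predictedCV()` repeats the experiment (default 200+ replicates) and
returns the mean interclonal CV with its Monte Carlo standard error;
`predictedCVGrid()` sweeps the suspension doubling time, rebuilding
$f_\mathrm{eq}$ from the survival balance at each $T_d$ — the
biologically relevant grid runs from 38 h (the attached doubling time,
a lower bound for growth in suspension) to 200 h.

Under the default parameterisation the predicted CV is 0.0015 at
$T_d = 100$ h, rising to 0.0088 at the $T_d = 38$ h grid edge — below
0.01 everywhere, which is 28–40-fold below observed interclonal CVs of
0.25–0.3. A variance decomposition explains the grid edge: at
$T_d = 38$ h, $f_\mathrm{eq} = 0.58$ and $\lambda = 0.77$, so
$2\lambda^2 > 1$ and early-generation switching noise plus the random
founder state dominate; the founder term alone contributes about a third
of the variance. With the strict observed lower bound 0.25, the minimum
fold ratio over the grid is ≈ 28 rather than ≥ 30 — the package reports
the simulated value as is; against the upper observed bound 0.3, or for
$T_d \ge 50$ h, the ratio exceeds 30. Either way the two-state model
under-predicts the observed fluctuations by well over an order of
magnitude, which is the analysis' central inference.

# Fluctuation statistics

`cv()` is the sample SD ($n-1$ denominator) over the mean; the
convention is stated because source reports rarely do.
`bootstrapCvCI()` resamples clones with replacement (default 2,000
resamples) and returns percentile 95% limits plus the half-width
$(q_{97.5}-q_{2.5})/2$, matching the "CV ± half-width" reporting style.
Percentile intervals are the default because nothing more specific than
"bootstrapping" is stated for the original analysis; a bias-corrected and
accelerated (BCa) interval is available by flag. At $n = 60$ clones the
percentile interval's empirical coverage for a CV near 0.3 is about 0.89
(slightly anticonservative, a known property of percentile intervals for
skewed statistics at moderate $n$), while BCa attains about 0.91; the
suite's coverage check therefore uses BCa, and users wanting calibrated
intervals at this $n$ should too.

`passageCorrelation()` regresses one passage's per-clone survival on
another's (OLS, Pearson $r$, two-sided $p$; no multiple-testing
correction across the two passage pairs). `growthRateSummary()` computes
per-clone effective growth rates $\ln(N_t/N_0)/T$ — zero-survivor clones
are held out as an explicit $-\infty$ class rather than polluting the
moments — and summarises mean, SD, CV ($|SD/\text{mean}|$), sign
fractions and the count of fast clones at or above the 45-h-doubling
rate. `analyzeTable()` bundles all of this, plus the observed/predicted
fold ratio when a model prediction is supplied, into a
`FluctuationSummary`.

# Memory decay and reversion

Acquired resistance decays during stress-free attached growth. The
minimal model consistent with a state memory of $M$ generations is
geometric loss per generation,
$f(g) = f_0 (1-k_\mathrm{off})^g$, relaxing instead to
$f_\mathrm{eq}$ when re-induction ($k_\mathrm{on} > 0$) is allowed.
`generationsToThreshold()` inverts the predicted survival
$f(g)e^{\gamma T}$ against a user-supplied parental survival level (the
parental values are figure-read quantities, so the threshold is an
argument, not a constant), and `fitMemory()` recovers
$(f_0, k_\mathrm{off})$ by linear least squares on $\log f$ — exact on
noiseless curves, median error below 0.02 under 10% multiplicative noise
(verified by simulation in the suite).

The generation axis of reversion curves is treated as generic discrete
steps; source usage mixes "generations" and "passages", and nothing in
the model depends on which is meant beyond the unit's label.

There is a deliberate, documented tension here: resistant populations
regain sensitivity over 8–14 stress-free generations, but with the
default rates the two-state model relaxes to equilibrium within ~3
generations ($|\lambda| \approx 0.6$) and its equilibrium survival
(~0.9) never approaches a genuinely sensitive parental level. The suite
asserts this mismatch as a property: the simple two-state model cannot
simultaneously carry the equilibrium resistant fraction implied by the
survival balance and the slow reversion kinetics — one of the reasons to
prefer a continuum description.

# The continuum generator

`generateContinuumTable()` implements the alternative the fluctuation
data support: a heritable *continuum* of survival propensities. Each
clone draws a latent suspension growth rate
$g_i \sim \mathcal N(\mu_g, \sigma_g)$; across passages the latent value
takes a stationary AR(1) step with coefficient $\rho$; measured survival
is $e^{g T}$ times lognormal measurement noise with CV
$c_m$ (all noise terms mean-1). Counts are emitted as rounded live-cell
numbers over $N_0$ plated so tables carry the full schema.

The shipped `ov90-clones` preset uses the observed growth-rate cohort
moments directly: $\mu_g = -0.004$ h⁻¹ and $\sigma_g = 0.012$ h⁻¹ (mean
effective growth rate −0.004 h⁻¹ with CV ≈ 300%), $\rho = 0$ between
assayed passages (matching the absence of inter-passage correlation),
and $c_m = 0.03$ — a small technical counting-noise term, calibrated
once and documented here. Closed-form consequences at $T = 24$ h:

- survival CV $\sqrt{e^{(24\sigma_g)^2 + \ln(1+c_m^2)} - 1} \approx 0.296$,
  inside the observed 0.25–0.31 band;
- fraction of clones with negative growth
  $\Phi(0.004/0.012) \approx 0.63$, i.e. about two thirds;
- about 3–4 clones per 60 at or above the 45-h-doubling rate;
- mean survival $e^{24\mu_g + ((24\sigma_g)^2+\ln(1+c_m^2))/2} \approx 0.95$.

The last line is a known limitation: with a Normal latent growth rate
(a modelling assumption — only summary moments of the real clone
distribution are available, not its shape), matching the growth-rate
moments forces the lognormal mean survival to ≈ 0.95 rather than the
observed ≈ 0.90; matching the mean instead would distort the growth-rate
moments. The preset prioritises the growth-rate scale because the
fluctuation statistics under test are CVs, which the preset matches.
Presets are versioned YAML files, not code constants, so alternative
calibrations can ship side by side.

`generateParentalReplicates()` produces population-level replicate
measurements with noise CV 0.11 and no clonal-heterogeneity term — the
fluctuation floor (n = 11 replicates by default).

The discriminating property the suite asserts across seeds: two-state
tables analyse to CV < 0.01 while continuum tables analyse to a
seed-averaged CV in 0.25–0.31 — the separation on which the whole
inference rests. (At $n = 60$ a single table's sample CV has standard
error ≈ 0.03, so the band is asserted on the seed average; no generator
with the observed CV could keep every 60-clone realisation inside a
±0.03 band.)

What the generators do *not* emulate: assay-plate batch effects,
correlated measurement error across passages, clone loss/dropout, or any
mechanistic covariate (MYC, OXPHOS, immune interactions). Passing tests
therefore validate the statistical machinery and the model comparison,
not those aspects of real data.

# Numerical and interface choices

- All internal computation is in fractions; CSV I/O can flag
  percent-scale columns, and the CLI prints both.
- Simulation sizes: 200–300 replicate experiments per predicted-CV
  estimate (Monte Carlo SE on the CV ≈ 1–5×10⁻⁵), 100,000 clones for
  large-$n$ generator calibration checks, 1,000 tables for bootstrap
  coverage — all chosen so each check resolves its target quantity an
  order of magnitude below its tolerance.
- Seeds: every stochastic entry point takes one integer seed, derives any
  sub-seeds from it, and restores the caller's RNG state on exit.
- Degenerate inputs are flagged, not silently absorbed: zero-mean CVs,
  zero-variance regressions, constant bootstrap data, unreachable
  reversion thresholds and infeasible survival balances all warn or
  error with the specific constraint named.
- `expandClone()` caps $G \le 30$ (count overflow) and the per-cell
  engine at $2^{16}$ cells; the hypergeometric subsampler refuses clones
  smaller than the plating number unless the binomial fallback or
  whole-clone plating is requested explicitly.
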