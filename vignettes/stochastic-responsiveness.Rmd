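---
title: "Modelling stochastic fluctuations in anesthetic responsiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stochastic fluctuations in anesthetic responsiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochanest)
```

## The model

Repeated binary testing of responsiveness under a fixed anesthetic
concentration — the righting reflex (RR) every 3 minutes in mice, the
startle reflex (SR) every 30 seconds in larval zebrafish — produces,
for each animal, an ordered series of 0s and 1s. The package's core
model is the simplest stochastic process with memory: a two-state
Markov chain over responsive (R) and unresponsive (U),

$$M = \begin{pmatrix} a & 1-a \\ 1-b & b \end{pmatrix},
\qquad a = P(R\mid R),\; b = P(U\mid U).$$

`markov_fit()` estimates the diagonals from consecutive-trial pair
counts: $a = n_{RR}/(n_{RR}+n_{RU})$ and $b = n_{UU}/(n_{UU}+n_{UR})$.
Everything else follows from $(a, b)$:

* stationary response probability $(1-b)/(2-a-b)$ — the long-run
  fraction of trials with a response;
* eigenvalues $1$ and $\lambda_2 = a+b-1$; the spectral gap $2-a-b$
  sets how fast the chain mixes to its equilibrium;
* the lag-1 autocorrelation of the binary series, which for this chain
  is exactly $\lambda_2$;
* geometric dwell times with leave rates $1-a$ (responsive) and $1-b$
  (unresponsive).

The model's assumptions, and the diagnostics provided for them, are:
two states only (dwell-time distributions should be single-geometric;
`extract_dwell_times()` / `fit_dwell_rate()`), first-order dependence
(no autocorrelation structure beyond $\lambda_2^k$;
`response_autocorrelation()` with a $\pm 1.96/\sqrt{N}$ band), and
stationarity over the analysis window (`steady_state_check()`
correlates trial index with the across-animal response probability).

The memoryless special case $b = 1-a$ is the Bernoulli process, fully
specified by the overall response probability `ec`. It is the null
model for every comparison: `simulate_bernoulli()` mirrors the mouse
design (80 experiments of 40 trials grouped 4 per animal) and
`compare_cohorts()` runs the three tests — overall potency (expected
to match), transition fractions (expected lower in data), and
$P(U\mid U)$ versus $P(U\mid R)$ (expected higher: inertia) — plus a
Brown-Forsythe comparison of inter-animal variance against the
finite-sample spread of the null.

## Conventions and edge cases

* **Missing trials** are first-class (`NA` in the CSV dialect); a
  missing value breaks the pair chain, so no pair, dwell or
  autocorrelation product spans it. This is the conservative choice:
  an unscored trial never manufactures evidence of persistence.
* **Session boundaries.** Mouse exposures are days apart, so by
  default pairs do not span sessions (`cross_session = FALSE`);
  a zebrafish series is one session, where the flag is irrelevant.
  Pooling across all sessions of an animal (the default for
  per-animal estimates) reflects that exposures are exchangeable
  post-equilibration; epoch analyses split them explicitly.
* **Undefined diagonals.** An animal that never visited one state has
  an undefined conditional; it is carried as `NA`, excluded from
  plane/correlation analyses, and counted (`n_excluded`).
* **Dwell censoring.** Runs touching a session edge or a missing trial
  have unknown true length; they are counted but excluded from the
  geometric MLE `n / sum(dwells)`. With 40-trial mouse sessions this
  discards a non-trivial fraction of long dwells, so per-animal decay
  rates are biased toward fast leaving; the bias is shared across
  animals and does not affect the sign of cross-animal correlations,
  which is what the analysis uses.
* **Displacement thresholding** (zebrafish SR) is strict: a trial is
  responsive iff distance > 0.4 mm (about a tenth of a 5-dpf body
  length, the dip of the bimodal displacement histogram). Ties at the
  threshold are unresponsive, making the rule deterministic.
* **Mann-Whitney U** is computed from midranks and reported as
  $\min(U_1, U_2)$ — the convention that matches the magnitudes small
  behavioral studies print; p-values are exact for small untied
  samples, normal-approximate with tie correction otherwise.

## Inter-individual structure

Each fitted animal is a point $(P(U\mid U), P(R\mid R))$ on the unit
square. Three design choices were genuinely open:

* **No scaling before PCA** — both axes are probabilities in the same
  units, so `pca_plane()` centers but does not rescale.
* **PC1 orientation**: the projection increases with
  $P(U\mid U) - P(R\mid R)$, so negative scores are animals that tend
  to stay responsive (resistant), positive scores animals that tend to
  stay unresponsive (sensitive).
* **One common axis for stability.** When comparing epochs (exposures
  1–2 vs 3–4), the PC1 axis is fit to the pooled points of both epochs
  and both are projected onto it, so the two coordinates are
  comparable. The permutation test shuffles the animal pairing between
  epochs, is one-sided (the claim is directional: real pairings
  correlate *more* than shuffled ones), and uses the add-one
  correction $p = (1 + \#\{r_{perm} \ge r_{obs}\})/(1 + n_{perm})$,
  whose null distribution is uniform on the achievable lattice.

## Concentration decoding

Per animal, all trials at a concentration are pooled (160 in the
two-concentration mouse design) and resampled: 1000 bootstraps of 20
trials, recording each bootstrap's mean. A density is fit to the
bootstrap means on a fixed 1001-point grid over [0, 1]. The density
family is a configuration point (`kde`, `normal`, `beta`); the default
is a Gaussian KDE with Silverman bandwidth, renormalized after
truncation to [0, 1] — the least committal smooth choice. A
zero-spread sample (an always-responsive animal) collapses to half a
grid step rather than relying on `bw.nrd0`, whose degenerate fallback
is not a scale. Overlap is the trapezoidal integral of the pointwise
minimum; Bayes posteriors use flat priors by default (the
two-condition design implies none), and grid points where both
likelihoods fall below $10^{-12}$ are reported as undefined rather
than 0/0. Printed overlap values depend on the density family and
bandwidth at the second decimal; comparisons should hold the family
fixed.

## Dose-response

The Hill form $1 - R = 1/(1 + (EC_{50}/\mathrm{Iso})^H)$ tends to
$R = 1$ at zero concentration automatically but reaches $R = 0$ only
asymptotically, so a hard "zero at 0.9%" equality is impossible. The
constraint is implemented as an anchor pseudo-observation at
$(\mathrm{Iso}, R) = (0.9, 0)$ weighted 100× a data point
(`hill_anchor()`), which reproduces the intended behavior without an
unsatisfiable equality. Because the anchor deliberately biases the fit
near the top of the tested range, `constraints = NULL` gives the pure
least-squares fit; parameter-recovery properties are stated for the
unconstrained fit, while the anchored fit is the default analysis.
Optimization is multi-start (a grid of quantile-based $EC_{50}$ and
log-spaced $H$ starting values) with Nelder-Mead on
$(\log EC_{50}, \log H)$; ties break toward the smaller slope.
`jackknife_hill()` drops the j-th animal at every concentration
simultaneously (index-matched when ids differ across concentrations)
and reports mean ± 1.96 × jackknife SE, with the standard
$(n-1)/n$ inflation — subsample spread alone would be far too narrow.

A deliberately constructive property carried in the tests: fitting
per-animal *observed* response probabilities (which fluctuate
trial-to-trial) yields a shallower apparent Hill slope than fitting
the same animals' binarized all-or-none consensus — quantifying how
stochastic fluctuations flatten population dose-response curves.

## The bistable landscape simulator

Network activity is reduced to $x = \text{Activity}_\alpha -
\text{Activity}_\beta$ with energy

$$E(x, i) = x^2\!\left(\tfrac{x^2}{2} - 2\right) + i(x-1)^2 +
(1-i)(x+1)^2,$$

where the drug effect $i \in [0, 1]$ deepens the anesthetized well
near $x = -1$ exactly as it shallows the awake well near $x = +1$ —
the mechanism behind the conserved trace. (The bare quartic alone has
minima at $\pm\sqrt{2}$; with the quadratic drug terms the full
potential at $i = 0.5$ has equal wells at $\pm 1$.) Dynamics are
$x \leftarrow x - D\,\partial_x E\,dt + \varepsilon$.

Numerical choices:

* **Noise scaling.** The reference procedure specifies per-step
  Gaussian noise of SD $\sigma$, and that is the default
  (`noise_scaling = "per_step"`); the physically conventional
  $\sigma\sqrt{dt}$ mode is a flag. With per-step noise the effective
  temperature is $\sigma^2/(2 D\, dt)$, so $dt$ and $\sigma$ jointly
  set the switching rate.
* **Step size** $dt = 0.1$: small enough that the explicit update is
  stable throughout the wells ($|1 - dt\,E''| < 1$ for
  $|x| \lesssim 2$), large enough that $10^6$ steps cover many dwell
  cycles at $\sigma = 0.4$.
* **Tamed drift.** The cubic drift grows superlinearly, so once large
  noise ($\sigma \gtrsim 1$ at this $dt$) kicks the state beyond
  $|x| \approx 2.5$ a raw explicit update explodes. The deterministic
  displacement per step is therefore capped at 2 (about the inter-well
  distance); the cap never binds inside $|x| < 2.5$ at the default
  $dt$, leaving well dynamics untouched, and makes noise-dominated
  sweeps finite. `drift_cap = Inf` restores the raw update, which
  errors with advice when $|x| > 10^3$.
* **Binarization and decimation.** $x \le 0$ is awake/responsive
  (boundary inclusive, as specified), $x > 0$ anesthetized; the first
  $10^4$ raw steps are discarded as burn-in (initial condition
  $x_0 = +1$), then every 100th sample is kept, mimicking intermittent
  behavioral testing.
* **Saturation under decimation.** At decimation 100 the sample
  spacing is 10 time units; once $\sigma \gtrsim 0.8$ the chain mixes
  faster than it is sampled and the decimated series is
  indistinguishable from a Bernoulli process — the transition fraction
  saturates at 0.5 and $(a, b)$ collapses to the center $(0.5, 0.5)$.
  Monotonicity-in-$\sigma$ properties are therefore probed at
  decimation 10, below saturation; the geometry of the
  drug-effect × noise sweep (periphery at low noise, center at high
  noise, anti-diagonal under an $i$-sweep at $\sigma = 0.4$) is
  checked at the full decimation.

The species-specific difference in absolute dwell durations (3-min vs
30-s trial spacing) is representable only through the free diffusion
constant $D$; no species calibration is attempted.

## The synthetic-cohort generator

`cohort_spec()` defaults encode the study designs: mice — 20 animals,
4 exposures × 40 trials (160 trials/animal); zebrafish
(`zebrafish_cohort_spec()`) — 72 animals × 360 trials. Structured
sampling draws each animal's trace $s \sim N(1.4, 0.05)$ and
sensitivity $d \sim N(0, 0.15)$, setting $b = s/2 + d$,
$a = s/2 - d$ (clipped to [0.01, 0.99], with a warning past 10%
clipping). The trace and spread defaults were chosen once to give the
strongly negative diagonal correlation, dominant PC1 (>80% of
variance) and stable individual traits seen in real cohorts; they are
knobs, not fits. Note that the band of diagonal correlations quoted
for the structured generator describes matrices *estimated from
generated trials*: the raw generating matrices have population
correlation $\approx -0.95$, and the finite-sample estimation noise of
160-trial series is what spreads estimates into the observed range —
exactly as in the animal data. Under independent-marginal (null)
sampling at $n = 20$, the sample correlation has SD
$\approx 1/\sqrt{19} = 0.23$, so even true independence produces
$|r| > 0.3$ about one time in five; calibration checks account for
this.

What the generator does *not* emulate: habituation or circadian drift
(series are stationary by construction), pharmacokinetic equilibration
(sessions start from the stationary distribution), animal-specific
session effects, and any parametric family for real inter-animal
sensitivity (the Gaussian trace/sensitivity model is a choice).
Pipeline tests passing on synthetic cohorts therefore demonstrate
correctness of the estimators and tests under the model's own
assumptions, not goodness-of-fit of those assumptions to any animal
dataset. Exact replication of published per-animal statistics requires
the corresponding deposited source tables, which can be loaded with
`read_source_table()` and fed to the same functions.

## Problem sizes used by the test suite

Simulation-based checks run at sizes chosen to keep Monte-Carlo error
well below the asserted tolerances while completing quickly on one
CPU: chain parameter recovery at $10^4$ trials (±0.05), analytic
autocorrelation and memorylessness checks at $10^5$ trials,
permutation-null calibration with 500 replicates of 199 permutations,
landscape sweeps at $10^5$ steps per grid point, and 50–100 replicate
cohorts for calibration/power properties. The full suite runs in
about a minute.

## Known limitations

* Dwell-time fitting ignores censored runs instead of modelling them;
  a likelihood with censoring would use more of the data.
* The decimated landscape chain loses all super-Nyquist structure;
  inferences about raw switching rates from decimated series are
  lower bounds.
* `per_animal_overlap_summary()` compares bootstrap KDEs, whose
  overlap for *identical* behavior is slightly below 1 due to
  resampling noise in the density estimates themselves.
* The Hill anchor encodes the experimental fact that righting is lost
  by 0.9% isoflurane; fits extrapolated beyond the tested range
  inherit that assumption.
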