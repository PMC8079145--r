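---
title: "Quantifying membrane-protein turnover, lateral mobility and nanoscale organisation with memFRAP"
author: "memFRAP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-protein turnover, lateral mobility and nanoscale organisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memFRAP)
```

## The biological problem

Transmembrane proteins such as the astroglial glutamate transporter GLT1
(EAAT2) are not static residents of the plasma membrane: they diffuse
laterally within it and are continuously exchanged with an intracellular
pool by exo- and endocytosis. Tagging such a protein with a pH-sensitive
fluorophore (Super-Ecliptic pHluorin, SEP — fluorescent at extracellular pH,
dark inside acidic compartments) makes both processes measurable by live
imaging:

* **Surface fraction.** A brief extracellular acid puff quenches the surface
  pool; a brief NH~4~Cl puff alkalinises intracellular compartments and
  reveals the total pool. Epoch-averaged intensities give the surface
  fraction *R* directly.
* **Membrane turnover.** Photobleaching quenches only molecules that are
  fluorescent — i.e. the surface pool. After a *whole-cell* bleach, any
  fluorescence recovery must come from insertion of intracellular
  (unbleached) molecules, reporting the exo/endocytic rate constants.
* **Lateral diffusion.** A *spot* bleach inside an unbleached membrane
  recovers mainly by lateral diffusion, reporting the mobile fraction and
  the diffusion coefficient.
* **Nanoscale organisation.** Single-molecule localization microscopy (SMLM)
  yields coordinate lists from which cluster structure and the spatial
  relation to synaptic markers (e.g. PSD95) can be quantified.

memFRAP implements the full analysis chain for these four measurements,
plus synthetic-data generators with known ground truth for every stage, so
that each estimator can be validated without access to raw microscopy data.

## Trace normalization

Raw ROI traces carry three channels: the bleach ROI $F_{BL}$, a background
ROI $F_{BKG}$ and a reference ROI $F_{REF}$ (the whole transfected cell, or
the cell outside the bleached region). Each frame is normalized as

$$F_{NOR} = \frac{F_{BL} - F_{BKG}}{F_{REF} - F_{BKG}},$$

the value of the first post-bleach frame is subtracted from all frames, and
the result is divided by the mean of the 40 pre-bleach frames (configurable
via `nBaseline`). The normalized trace is therefore exactly 0 at bleach end
and averages 1 over the baseline, and is invariant under affine rescaling of
the raw intensities — a property the test suite asserts directly. Because
the reference enters as a ratio, slow acquisition photobleaching and
expression drift cancel to first order; what remains is absorbed by the
fitted residual-bleaching rate $k_b$ (whole-cell model) or by the paired-trial
correction below.

**Paired trials.** Spot-FRAP protocols often record two trials per location
(control cycle, then treatment cycle). The published protocols do not state
the correction arithmetic, so `pairCorrect()` offers both options and
defaults to the multiplicative one — dividing the second treatment trial by
the control drift ratio (second control / first control) — because
photobleaching and expression drift act multiplicatively on fluorescence.
Frames where the ratio denominator is below 0.05 are flagged and left
uncorrected rather than amplified.

## The two-compartment turnover model

Exchange between the membrane pool $C_{mem}$ and the intracellular pool
$C_{in}$,

$$C_{in} \underset{k_{-1}}{\overset{k_1}{\rightleftharpoons}} C_{mem},$$

implies at steady state $k_{-1} = (1/R - 1)\,k_1$ with $R$ the surface
fraction (`steadyStateRemovalRate()`). After a whole-cell bleach the
fluorescent membrane signal follows the closed form

$$f(t) = (1 - C_{in})\,C_{in}\,\bigl(e^{-k_b t} - e^{-k_1 t}\bigr)$$

on the normalized scale (`turnoverCurve()`), with two orthogonal free
parameters ($C_{in}$, $k_1$) plus the residual photobleaching rate $k_b$,
which is *fitted with a lower bound of zero* rather than fixed — it is
typically negligible, and leaving it free lets the data say so.
`fitTurnover()` performs bounded Levenberg–Marquardt least squares over the
post-bleach frames and derives $R = 1 - C_{in}$, $k_{-1}$ and the
characteristic membrane lifetime $1/k_1$. We follow the field's convention
of calling $1/k_1$ the membrane lifetime and also report $1/k_{-1}$ through
the derived estimates.

Two numerical choices deserve note:

* **Identifiability.** The amplitude $(1-C_{in})C_{in}$ is symmetric under
  $C_{in} \leftrightarrow 1-C_{in}$, so a whole-cell trace alone cannot
  distinguish the two branches. The default bound `CinUpper = 0.5` selects
  the intracellular-minority branch, which the independent pH-puff
  measurement ($R \approx 0.7$ for a predominantly surface-resident
  transporter) justifies; set `CinUpper = 1` to allow the other branch.
* **Initialization** is deterministic and derivative-free: $C_{in}$ from the
  plateau root of $(1-C)C = \text{plateau}$, $k_1$ from
  $\ln 2 / t_{1/2}$.

**Model discrepancy.** The closed form treats the intracellular fluorescent
pool as draining at rate $k_1$ without return. The full two-state system
(solved by `turnoverODE()` with an adaptive integrator, relative tolerance
$10^{-8}$) recovers at rate $k_1 + k_{-1}$ and plateaus at
$C_{in} k_1/(k_1 + k_{-1})$. The package deliberately fits the closed form —
it is what the headline rate constants refer to — and quantifies the
difference via `turnoverDiscrepancy()` instead of silently substituting the
exact solution. At the default parameter scale the maximum divergence over
0–300 s is about 0.027 normalized units.

```{r turnover-example}
nt <- simulateTurnoverTrace(Cin = 0.30, k1 = 0.045, noiseSd = 0.01, seed = 1)
fit <- fitTurnover(nt, nBoot = 0)
round(coef(fit), 4)
turnoverDiscrepancy(0.30, 0.045, 0.020)$maxAbs
```

**Surface fraction from puff traces.** `estimateSurfaceFraction()` computes
$R = (f_{base} - f_{acid})/(f_{NH_4} - f_{acid})$ from epoch-averaged,
background-subtracted intensities; values pushed outside $[0,1]$ by noise
are clamped and flagged. Epochs are user-marked frame windows — no automatic
changepoint detection is attempted, matching how such recordings are
annotated in practice. Somatic ROIs are supported but labelled separately;
process ROIs are the default analysis unit because somatic boundaries are
typically ill-defined.

## Lateral diffusion: the Soumpasis circular-spot model

Recovery by pure lateral diffusion into a uniformly bleached circular spot
of radius $w$ follows

$$F(t) = C_{mob}\, e^{-2\tau_D/t}\left[I_0\!\left(\tfrac{2\tau_D}{t}\right)
 + I_1\!\left(\tfrac{2\tau_D}{t}\right)\right],
 \qquad \tau_D = \frac{w^2}{4D},$$

with mobile fraction $C_{mob}$ and diffusion time $\tau_D$ as the only free
parameters. The Bessel product is evaluated with exponentially scaled
functions (`besselI(..., expon.scaled = TRUE)`) so that small $t$ (large
argument) neither overflows nor loses the cancellation; the test suite
verifies agreement with an independent quadrature oracle to $10^{-10}$ over
$2\tau_D/t \in [10^{-3}, 700]$. The $t = 0$ frame, whose model value is
defined only as a limit, is excluded from fitting. $\tau_D$ is initialized
at the time the trace reaches 0.524 of its plateau (the model's value at
$t = \tau_D$); a fitted $\tau_D$ below two frame intervals is flagged as
undersampled.

`tauToD()` converts to $D = w^2/(4\tau_D)$ and `effectiveDiffusivity()`
gives the population average $D^* = C_{mob} D$. **The spot size $w$ is a
radius** and is always an explicit input: published spot-size statements are
easily ambiguous between radius, diameter and area, and only the
diameter-reading of a "2.06 µm wide" spot ($w = 1.03$ µm) reproduces
$D = 0.152\ \mu m^2/s$ from $\tau_D = 1.75$ s, so the package never
hard-codes a spot geometry. `compareConditions()` reports effect sizes
between two fits (e.g. control vs. glutamate) with a bootstrap interval of
the $D^*$ difference obtained by pairing the fits' bootstrap replicates.

Bootstrap uncertainty throughout the package uses seeded residual
resampling (1000 draws by default; set `nBoot = 0` to skip), so all
reported intervals are reproducible.

## SMLM cluster and nearest-neighbour analysis

`dbscanClusters()` implements standard density-based clustering (defaults:
100 nm neighbourhood, minimum 50 points including the point itself —
parameters that correspond to PSD-sized clusters). Two deterministic
tie-breaks make the labelling reproducible: border points reachable from
several clusters go to the lowest-index core neighbour, and clusters are
numbered by their lowest member index. The implementation (grid-binned
neighbour search + union–find) is checked against a brute-force
distance-matrix reference on randomized instances. Cluster density
$\lambda$ (clusters/µm²) comes from `lambdaDensity()`.

`nnDistances()` returns per-source nearest-neighbour distances (to cluster
centroids, or within a channel), discarding distances beyond a 500 nm
cutoff; `nnDistribution()` bins them (5 or 10 nm bins) into a cumulative
distribution normalized to the retained events, and `poissonNullCdf()`
provides the analytic null of evenly random scatter,
$D(r) = 1 - \exp(-\lambda \pi r^2)$. Analysis is strictly 2D: published
cluster densities are areal (µm⁻²), and any z coordinate is ignored.

`compareToNull()` classifies the deviation as *association* (empirical CDF
above the null: distances shorter than random), *dispersion*, or
*indistinguishable*. Because no analytic test accompanies the visual
comparison in common practice, significance uses a seeded Monte-Carlo
threshold: 999 replicate distance sets of the observed size are drawn from
the null by inverse transform with the same cutoff conditioning and
binning, and the 95th percentile of their KS statistics is the decision
threshold. Conditioning the replicates exactly as the data keeps the test
calibrated even when the null CDF has not saturated at the cutoff.

Edge handling: by default no edge correction is applied (the cutoff is
assumed small relative to the field). For strict comparisons against the
Poisson null, `nnDistances(margin = cutoff)` applies minus-sampling —
sources within one cutoff of the field border are dropped so every retained
source sees its complete neighbourhood. Nearest-neighbour targets for the
molecule-to-cluster analysis are cluster *centroids*, chosen for
determinism; distances to cluster edges depend on the realized cluster
outline and are not provided.

## Synthetic data: what the generators emulate

Every stage has a generator with recorded ground truth; all are
seed-deterministic (identical configuration + seed gives bit-identical
output, asserted by tests).

* `simulateTurnoverTrace()` samples the closed-form whole-cell curve at the
  experimental frame interval (1.644 s) with 40 baseline frames, i.i.d.
  Gaussian noise (default study condition: sd 0.01 normalized units,
  matching the low-noise averaged traces of whole-cell recordings) on the
  post-bleach frames, and optionally emits raw
  bleach/background/reference channels (with a 5% residual bleach floor)
  that normalize back to the model exactly — a round trip the tests use to
  validate the normalization chain.
* `simulatePuffTrace()` produces three-epoch acid/NH~4~Cl traces with a
  configurable residual intracellular brightness (default 0: acidic
  vesicular pool dark).
* `simulateBrownianFrap()` is a particle-based 2D Brownian-dynamics
  simulation: Gaussian steps of per-axis sd $\sqrt{2 D\, dt}$
  (default $dt = 10$ ms, guarded so the step length stays below a fifth of
  the bleach radius), a planted immobile fraction, periodic boundaries on a
  domain at least ten bleach radii wide, and an instantaneous hard-edged
  disk bleach — appropriate because the experimental bleach (tens of ms) is
  much shorter than $\tau_D \approx 1.75$ s. The readout is the count of
  unbleached particles in the readout disk, pushed through the same
  normalization as real data; the emitted reference channel tracks the
  total unbleached pool, which cancels finite-domain depletion exactly as
  the experimental reference ROI cancels global bleaching. Without an
  immobile fraction the trace converges to the Soumpasis curve (mean
  absolute deviation $\le 0.03$ at 50,000 particles, asserted in tests).
* **Exchange mode** models membrane turnover: each particle independently
  leaves the membrane with probability $1 - e^{-k_{-1} dt}$ per step and is
  immediately replaced at a uniform position, conserving mass exactly.
  Before the bleach every molecule is fluorescent, so replacements are
  unbleached; after the bleach a replacement is unbleached with probability
  `unbleachedFraction`, defaulting to $R\,C_{in}$ with
  $C_{in} = k_{-1}/(k_1 + k_{-1})$ — the effective fluorescent availability
  of the intracellular pool under the closed-form model. With the symmetric
  default $k_{-1} = k_1$ a whole-field bleach recovers as
  $0.25\,(1 - e^{-k_1 t})$, i.e. the turnover model's shape at the
  configured rate, which is how the package cross-checks at mechanism level
  that exchange (not lateral diffusion) reproduces whole-cell FRAP
  kinetics. This replacement-purity construction is a deliberate
  phenomenological simplification: a literal finite two-pool simulation
  recovers at $k_1 + k_{-1}$ (see the ODE oracle) and would not correspond
  to the closed form being fitted.
* `simulatePointPattern()` generates Poisson fields, Thomas cluster
  processes (Gaussian offspring around Poisson or fixed-count parents), and
  two-channel patterns with planted association (a fraction of channel-2
  points Gaussian-displaced from channel-1 anchors) or repulsion (hard-core
  thinning).

What the generators do **not** emulate: image formation (PSF, pixel shot
noise), detector artefacts, localization imprecision and blinking
overcounts, drift, the quasi-1D geometry of fine glial processes, and
biological heterogeneity between cells. Passing tests therefore demonstrate
that the estimators are correct and well-calibrated under the stated
models, not that those models capture every property of real recordings.

## Problem sizes and reproducibility

The validation studies run at desk scale by design: 50 replicate whole-cell
traces (≈180 frames each) for turnover parameter recovery, three seeds of
20,000-particle Brownian simulations (60 s at 10 ms steps) for the mobile
fraction study, and 50,000 particles for the Soumpasis convergence check.
These sizes hold the Monte-Carlo error well below the decision tolerances
(10% for rate constants, ±0.05 for the mobile fraction) while keeping a
full run in minutes on one core. `scripts/acceptance.R` re-runs the whole
battery from scratch under a single `--seed`.

## Known limitations

* The turnover fit inherits the closed form's no-return approximation; for
  $k_{-1}$ comparable to $k_1$ the recovered $k_1$ should be interpreted as
  the model's effective insertion rate (the ODE oracle quantifies the gap).
* The whole-cell amplitude only identifies $C_{in}$ up to its complement;
  an independent surface-fraction measurement is needed to pick the branch.
* Nearest-neighbour analysis applies no edge correction by default and the
  Monte-Carlo null conditions on the estimated $\lambda$; both choices are
  adequate when the cutoff is small relative to the field and the target
  count is large.
* The pipelines treat drug/condition labels as opaque metadata; group-level
  inference beyond paired comparisons with bootstrap intervals is out of
  scope.
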