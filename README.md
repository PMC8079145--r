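# memFRAP

Quantitative analysis of membrane-protein dynamics from live-cell
fluorescence microscopy, built around pH-sensitive (pHluorin-tagged)
membrane proteins such as the astroglial glutamate transporter GLT1. The
package is aimed at cell biologists and biophysicists who record FRAP
(fluorescence recovery after photobleaching) traces and single-molecule
localization (SMLM/dSTORM) maps and want reproducible, tested estimators
for:

* **Surface fraction** *R* from acid/NH4Cl puff traces:
  `R = (f_base − f_acid) / (f_NH4 − f_acid)`.
* **Membrane turnover** from whole-cell FRAP, via the two-compartment
  exchange model `Cin ⇌ Cmem` with closed-form recovery
  `f(t) = (1 − Cin)·Cin·(e^(−kb·t) − e^(−k1·t))`, steady-state relation
  `k−1 = (1/R − 1)·k1`, and membrane lifetime `1/k1`.
* **Lateral diffusion** from spot FRAP, via the Soumpasis circular-spot
  model `F(t) = Cmob·e^(−2τD/t)·[I0(2τD/t) + I1(2τD/t)]` with
  `τD = w²/(4D)` and effective diffusivity `D* = Cmob·D`.
* **Nanoscale organisation** from localization tables: density-based
  (DBSCAN) clusters, cluster density λ, and nearest-neighbour distance
  distributions against the 2D Poisson null `D(r) = 1 − exp(−λπr²)`.

Every stage has a seed-deterministic synthetic-data generator with known
ground truth (closed-form turnover traces, particle-based Brownian-dynamics
photobleaching simulations, pH-puff traces, spatial point patterns), so the
whole pipeline is verifiable without raw microscopy data. See the vignette
`vignettes/membrane-turnover-and-mobility.Rmd` for the models, assumptions
and numerical choices.

## Worked example

Fit the turnover model to a synthetic whole-cell FRAP trace generated at
realistic parameters (frame interval 1.644 s, 300 s, noise sd 0.01):

```r
library(memFRAP)
nt  <- simulateTurnoverTrace(Cin = 0.30, k1 = 0.045, noiseSd = 0.01, seed = 1)
fitTurnover(nt, nBoot = 200)
#> Two-compartment membrane turnover fit
#>   Cin = 0.3134, k1 = 0.04761 /s, kb = 0 /s
#>   derived: R = 0.6866, k-1 = 0.02173 /s, membrane lifetime = 21 s
#>   rss = 0.01738 over 183 frames
```

The fit recovers the planted intracellular fraction (0.30) and insertion
rate constant (0.045 s⁻¹) within noise; the derived membrane lifetime
(`1/k1`, here 21 s) says a surface-resident molecule is replaced from the
intracellular pool roughly every ~20 s, and `k-1` is the removal constant
implied by the steady state. A particle-based spot-FRAP simulation with a
planted 24% immobile fraction, refit with the Soumpasis model:

```r
sim <- simulateBrownianFrap(D = 0.152, immobileFraction = 0.24,
                            nParticles = 20000, duration = 60, seed = 101)
fitSoumpasis(sim$trace, w = 1.03, nBoot = 0)
#> Soumpasis circular-spot diffusion fit
#>   Cmob = 0.7791, tauD = 2.39 s (w = 1.03 um)
#>   D = 0.111 um^2/s, D* = Cmob*D = 0.08644 um^2/s
#>   rss = 1.468 over 400 frames
```

`Cmob` recovers the planted mobile fraction (0.76) to within sampling
error; `tauD` carries most of the single-trace variance, which is why
diffusion-time conclusions should come from several seeds or traces.
Surface fractions from puff epochs:

```r
estimateSurfaceFraction(fBase = 1, fAcid = 0, fNh4 = 1.389)
#>           R      Rraw clamped f_base f_acid f_nh4 roi_kind
#> 1 0.7199424 0.7199424   FALSE      1      0 1.389  process
```

End-to-end runs over CSV inputs (`runFrapPipeline()`, `runSmlmPipeline()`)
take a JSON config, write per-trace fits and a provenance-stamped
`bundle.json`, and are byte-reproducible under a fixed seed; a thin shell
wrapper lives in `inst/scripts/memfrap-pipeline.R`.

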