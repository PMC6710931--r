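# RGCglia

Kinetic network model of neuron–glia interactions in glaucoma: simulation,
local and global sensitivity analysis, and a reaction–diffusion model of
cellular stress.

## The problem

Glaucoma is the progressive death of retinal ganglion cells (RGCs).  The
surrounding glia — astroglia, microglia and Müller cells — are not
bystanders: their activated phenotypes drive, and their quiescent
phenotypes protect against, RGC loss, together with a lumped pool of
cellular stress (inflammation, oxidative stress, proapoptotic factors).
`RGCglia` packages a 22-pathway kinetic hypothesis of this system for
people who want to simulate it, probe which rate constants matter, and run
*in silico* intervention experiments (e.g. microglial-activation
inhibitors).

## The model in brief

Nine states — surviving/dead RGCs (Rσ, Rδ), quiescent/activated astroglia
(Aα, Aβ), microglia (Mα, Mβ) and Müller cells (Gα, Gβ), plus a stress pool
(Cσ) — are linked by 22 directed pathways with per-year rate constants
k₁…k₂₂ (15 homeostatic, 7 pathogenic).  Each edge maps to a typed kinetic
term (hazard contribution, stress production, first-order or catalyzed
conversion), lineage pair sums are conserved, and RGCs die by one-hit
kinetics with a state-dependent hazard:

    dRσ/dt = −h·Rσ,   h = max(0, Σ_harmful k·x̂ − Σ_protective k·x̂),

where x̂ is each catalyst population normalized by its lineage's initial
total.  The dead pool is bookkept by conservation, giving 7 cell-population
equations plus one stress equation, dCσ/dt = Σ production − λ·Cσ.  The
stress field version ∂C/∂t = D·∂²C/∂x² + π − λC is solved on a 1-D domain
with zero-flux boundaries.  Sensitivity tooling covers signed ±3 % central
finite differences (Ψ = ∂x(T)/∂k at horizons up to 20 years) and Latin
hypercube sampling with time-resolved partial rank correlation
coefficients (PRCC, significance p < 0.01) for live-RGC density and
inflammation buildup.

## Worked example

Load the packaged model, push it into a pathogenic regime (weakened
protective signalling `k1`, `k17`; stronger death channel `k3`), simulate
20 years, and test a microglial-inhibition intervention:

```r
library(RGCglia)

model <- defaultModel()
model
#> NetworkModel: 9 states, 22 pathways (15 homeostatic, 7 pathogenic)
#>   name: glaucoma22
#>   states: Rs, Rd, Aa, Ab, Mb, Ma, Cs, Ga, Gb

sys <- buildRateSystem(model)
sys
#> RateSystem: 7 cell-population equation(s) + 1 stress equation(s), 22 term(s)
#>   lambda (stress degradation): 0.5 /yr
#>   bookkept dead pool(s): Rd

scenario <- setRateValues(model, c(k1 = 0.02, k17 = 0.02, k3 = 0.5))
traj <- simulateTrajectory(buildRateSystem(scenario))
traj
#> Trajectory: 21 time points over [0, 20] years, 8 state(s)
#>   progression ratio: 0.01 -> 1311

round(progressionRatio(traj, 20), 3)
#> [1] 1311.372

treated <- simulateTrajectory(buildRateSystem(scenario),
  intervention = intervention(5, c(k12 = 0.1, k14 = 0.1)))
round(progressionRatio(treated, 20), 3)
#> [1] 148.108
```

The progression ratio Rδ/Rσ is the model's surrogate for disease severity:
in this scenario nearly all RGCs are lost by year 20 (ratio ≈ 1311), while
inhibiting the microglial activation pathways `k12` and `k14` ten-fold
from year 5 retains about nine times more surviving cells (ratio ≈ 148).
Which rates matter most for survival in this regime:

```r
psi <- sensitivityMatrix(scenario, horizon = 20)
round(sort(psi@matrix[, "Rs"])[1:4], 1)
#>    k3    k5   k20    k2
#> -97.1 -64.1 -64.1 -54.5
```

At the homeostatic default rates the protective terms dominate and the
clipped hazard is exactly zero — the baseline retina loses no RGCs; see
the methods vignette (`vignettes/rgcglia-methods.Rmd`) for why, and for
every modelling decision.

Global sensitivity (this is the expensive step, ~30 s):

```r
design <- lhsSample(defaultRanges(model), n = 200, seed = 1)
pr <- timeResolvedPRCC(model, design, output_times = 0:20)
pr@coefficients["k3", "Rs", "20"]   # harmful edge: negative PRCC
pr@coefficients["k1", "Rs", "20"]   # protective edge: positive PRCC
```

A thin command-line front end over the same functions is installed at
`system.file("scripts", "rgcglia-cli.R", package = "RGCglia")` with
subcommands `validate`, `simulate`, `sens-local`, `lhs-prcc`,
`stress-pde`, `export-graph` and `fixtures`.

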