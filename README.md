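# chondrosim

Reaction–diffusion–delay simulation of articular cartilage lesion
expansion and abatement.

## The problem

An acute injury to articular cartilage kills chondrocytes inside a small
disc by necrosis. The debris releases alarmins (DAMPs) that switch
surrounding healthy chondrocytes into a catabolic state; catabolic cells
produce TNF-α and reactive oxygen species, and TNF-α amplifies the
inflammation — converting more cells, degrading matrix (which releases
further DAMPs), and driving sick cells into apoptosis. Left alone, this
pro-inflammatory loop spreads the lesion far beyond the original wound.
The counterweight is erythropoietin (EPO): healthy cells sensing ROS
begin, after a synthesis delay, to produce EPO, which rescues
receptor-expressing sick cells and — once it exceeds a critical level
`P_c` — shuts off the healthy-to-catabolic switch. Whether a lesion
expands without bound or stalls at a fixed radius ("abates") is decided
by the balance between these two arms.

`chondrosim` implements this model for quantitative exploration: four
diffusing chemical species (ROS `R`, DAMPs `M`, TNF-α `F`, EPO `P`), four
immobile chondrocyte states (healthy `C`, catabolic `S_T`, EPOR-active
`S_A`, necrotic `D_N`), extracellular matrix `U`, and an apoptosis ledger
`D_A`, on a circularly symmetric domain. The chemical balance laws are of
the form

    ∂t F = ∇·(D_F ∇F) − δ_F F + σ_F S_T

with Michaelis–Menten saturation `sat(x, λ) = x/(λ+x)` in every signaling
term; cell states exchange density through saturating switching terms,
two discrete delays (τ₁ ≈ 12 h for EPO-receptor expression, τ₂ ≈ 24 h for
EPO synthesis onset), and the threshold gate `H(P − P_c)` that permits
conversion of healthy cells only while local EPO is below critical. The
semi-discrete system (conservative finite-volume radial diffusion) is a
delay-differential system, integrated by an embedded Runge–Kutta 2(3)
method of steps with cubic dense output. The full model and every
numerical choice are documented in `vignettes/lesion-model.Rmd`.

Intended users: modelers of inflammation and wound-penumbra dynamics, and
anyone needing a tested, deterministic reference implementation of a
threshold-gated cytokine-balance model with delays.

## Worked example

```r
library(chondrosim)

# ten-day injury response with the EPO pathway active
traj <- run_scenario("with_epo")
smry <- lesion_summary(traj)
classify_regime(smry)
#> [1] "abated"
abatement_day(smry)
#> [1] 3.583333
round(subset(as.data.frame(smry), day %in% c(1, 3, 10),
             c(day, lesion_radius, penumbra_outer, total_C)), 2)
#>     day lesion_radius penumbra_outer total_C
#> 25    1          0.59           0.86 7731.73
#> 73    3          1.66           2.07 7037.18
#> 241  10          1.71           2.91 6848.57
```

The lesion (radius where the healthy density is below half its
background) expands for about three and a half days and stalls just
above 1.7 mm; the penumbra of sick cells around it stays essentially
stationary from day 7 on while the healthy population slowly recovers. The same scenario with EPO production switched off
(`run_scenario("no_epo")`) classifies `"expanding"`: the front crosses
the whole 5 mm domain and fewer than 5% of the healthy cells survive to
day 10.

```r
autoplot(traj)                       # radial profiles at selected days
tidy(traj)                           # long tibble: time, radius, field, value
glance(traj)                         # one-row run summary
sensitivity_table(n_points = 5)      # the one-at-a-time response table
```

A thin command-line front end ships in `inst/cli/chondrosim`
(`simulate`, `metrics`, `sensitivity` subcommands); reference scenario
configurations are under `inst/extdata/`.

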