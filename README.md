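# micellemix

Thermodynamic and structural analysis of binary mixed micelles, built
around the sodium cholate (NaCA) + sodium dodecylsulphate (SDS) 1:1
system. The package is for surfactant and colloid scientists who have
(a) temperature-dependent critical micelle concentrations (cmc) of two
surfactants and their mixture, (b) raw fluorimetric titration,
conductivity or surface-tension curves, or (c) coarse-grained
self-assembly trajectories, and want the standard quantitative analyses
for each, with ground-truthed synthetic data to validate every step.

## What it computes

**Regular-solution thermodynamics.** For bulk mole fraction α₁ and
pure-component cmc values c₁, c₂, the ideal mixed cmc follows Clint's
relation

    1/cmc_id = α₁/c₁ + (1 − α₁)/c₂

The micellar mole fraction x₁ of component 1 is the root of Rubingh's
implicit regular-solution equation

    x₁² ln[α₁ c_mix/(x₁ c₁)] = (1 − x₁)² ln[(1 − α₁) c_mix/((1 − x₁) c₂)]

and the interaction parameter is

    β₁,₂ = ln[α₁ c_mix/(x₁ c₁)] / (1 − x₁)²

β₁,₂ < 0 means synergism: the mixed cmc sits below the ideal prediction
because unlike building units attract.

**cmc extraction.** Boltzmann-sigmoid fits of pyrene I₁/I₃ titration
curves (cmc = inflection), segmented-line breakpoint fits of κ(c)
conductivity curves with an F-test + slope-ratio acceptance rule
(cmc = breakpoint; counterion binding fraction = 1 − S₂/S₁), and the
same breakpoint analysis on γ–log c tension data.

**Trajectory statistics.** For coarse-grained frames (4-bead SDS, 8-bead
cholate, Na⁺ beads, cubic periodic box): closest-bead cluster detection
(< 7 Å criterion), number-of-clusters time series with 100 ns block
averaging, cluster-size distributions, per-size SDS content, gyration
tensor shape anisotropy K², condensed/free Na⁺ partitioning (< 7 Å from
SO3/OCO), radial bead distributions about the micelle centre of mass,
and SDS head-to-tail orientation angles. GRO and extended-XYZ readers
and writers are included.

**Synthetic data.** Seeded generators for all of the above: noisy model
curves, constructed micelle configurations with exactly known cluster
labels, compositions and ion partitions, and a toy overdamped-Langevin
aggregation simulator that reproduces the qualitative mechanism
(spontaneous aggregation, SDS-rich cores, loosely bound cholate).

## Worked example

```r
library(micellemix)

tbl <- nacasds_cmc_table()        # packaged 0–50 °C NaCA + SDS cmc table
res <- rubingh_analysis(tbl)
dplyr::select(res, temperature_C, cmc_mix_mM, cmc_ideal_mM, x1, beta12)
#> # A tibble: 11 × 5
#>   temperature_C cmc_mix_mM cmc_ideal_mM    x1 beta12
#> 1             0       4.09         9.47 0.510  -3.36
#> 2             5       4.01         9.85 0.507  -3.60
#> 3            10       4.01        10.2  0.504  -3.75
#> # …

glance(res)
#>       n mean_beta12 sd_beta12 mean_x1 all_synergistic
#> 1    11       -3.89     0.433   0.504 TRUE
```

The experimental mixed cmc (~4 mM) sits less than half the ideal
prediction at every temperature and β₁,₂ is negative throughout: the
mixed micelle is synergistic, with an essentially equimolar composition
(x₁ ≈ 0.50–0.51) that barely moves with temperature.

Fitting a synthetic noisy titration curve recovers its cmc:

```r
cur <- generate_curve(curve_spec("titration",
  true_params = list(a1 = 1.82, a2 = 1.22, x0 = 4.07, dx = 0.35),
  noise_sd = 0.01, n_points = 30, x_range = c(1, 10), seed = 42))
fit_boltzmann(cur)
#> Boltzmann sigmoid fit
#>   cmc (inflection x0): 4.097 mM
#>   plateaus: 1.824 -> 1.216, width dx = 0.3485 mM
#>   rss = 0.003739 over 30 points

effective_concentration(60, 8114.11)  # 60 surfactants in 8114.11 nm^3
#> [1] 12.28  # mM
```

Fitted objects support `tidy()`, `glance()` and `autoplot()`; a full
simulate-then-analyse run is one call:

```r
run_micelle_pipeline(list(simulate = list(seed = 1),
                          analyze = list(cutoff = 7, block_ns = 100)),
                     out_dir = "out")
```

which writes `trajectory.gro`, per-analysis CSVs and a `summary.json`.

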