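# marshpva

Stochastic, spatially structured metapopulation viability analysis for
species living in networks of small habitat patches — built around the kind
of system the endangered Amargosa vole occupies: a few dozen desert marshes,
most tiny, strung along a valley floor, where persistence depends on the
balance between local extinction and recolonization, and where drought,
fire, water diversion and habitat restoration all act through patch
carrying capacity.

## The model

Each patch *i* has carrying capacity

&nbsp;&nbsp;&nbsp;&nbsp;K<sub>i</sub> = depth<sub>i</sub> (cm) × area<sub>i</sub> (ha) × K<sub>volume</sub>,

with K<sub>volume</sub> the species' density at carrying capacity in
voles/(cm × ha), estimated by regression of observed subpopulation sizes on
habitat volume through the origin. Within a patch, yearly dynamics follow a
Ricker recursion with environmental stochasticity,

&nbsp;&nbsp;&nbsp;&nbsp;N<sub>t+1</sub> = N<sub>t</sub> exp( r<sub>d</sub> (1 − N<sub>t</sub>/K) + ε ),&nbsp;&nbsp; ε ~ Normal(0, v<sub>r</sub>),

bounded above by a ceiling at K (a boom year cannot push a subpopulation
above carrying capacity) and subject to the local-extinction rule N < 1 → 0.
Patches are coupled by a distance-decaying *migration pressure* in the
incidence-function tradition: the expected number of immigrants into patch
*i* per year is

&nbsp;&nbsp;&nbsp;&nbsp;λ<sub>i</sub> = β Σ<sub>j≠i</sub> N<sub>j</sub> e<sup>−α d<sub>ij</sub></sup>,

realized as a Poisson draw, with α the inverse mean dispersal distance (the
exponential-kernel MLE from movement data) and β a dimensionless migration
calibrator. Monte-Carlo trials (default 500 trials of 101 years) yield the
mean time to metapopulation extinction T<sub>e</sub> (censored at the run
length), occupancy, abundance and migrant counts; per-patch isolation runs
classify patches as Context-independent Sources, Rescued Sinks, Converted
Sinks or Context-independent Sinks; scenario and one-factor-at-a-time
sensitivity engines compare management options.

## Worked example

```r
library(marshpva)

land <- synthetic_landscape(seed = 1)   # 36 patches, 3 regional clusters
range(carrying_capacity(land))          # 1.2 ... 120.2 voles

sim <- run_simulation(land, demography_params(), migration_params(),
                      sim_config(trials = 200, seed = 42))
glance(sim)
#>   trials tmax    te prop_extinct   mvp    mN  mcol  t
#> 1    200  101 75.29        0.805 0.250 118.0 0.965 25

compare_scenarios(land,
  list(scenario("baseline"), drought_scenario(0.35), fire_scenario("south")),
  config = sim_config(trials = 200, seed = 42))
#>     scenario mvte   mvp    mN  mcol pct_change_mvte
#> 1   baseline 75.3 0.250 118.0 0.965            0.00
#> 2 drought_35 63.6 0.156  61.1 0.540          -15.54
#> 3 fire_south 68.4 0.173  85.2 0.555           -9.18
```

Read: on this landscape the metapopulation persists on average 75 years
(80% of trials go extinct within the 101-year horizon); at year 25 a
quarter of patches are occupied, ~118 voles remain, and about one migrant
moves between marshes per year. A moderate (35%) drought cuts mean time to
extinction by ~16%, a fire that burns the southern cluster by ~9%.

`autoplot(land)` maps the landscape; `autoplot(sim)` plots the mean
trajectory; `tidy(sim)` returns the per-patch yearly table;
`classify_patches()`, `ofat_sweep()` and `alpha_mle()` / `rd_from_lambda()`
/ `fit_k_volume()` cover classification, sensitivity analysis and
calibration. A thin command-line front end lives in `inst/cli/marshpva`
(subcommands `simulate`, `classify`, `scenarios`, `sensitivity`,
`calibrate-alpha`).

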