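---
title: "Methods: a stochastic patch-network viability model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a stochastic patch-network viability model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marshpva)
```

## The model

marshpva simulates a metapopulation on a landscape of discrete habitat
patches. Each patch $i$ carries

$$K_i = \text{depth}_i \,(\mathrm{cm}) \times \text{area}_i\,(\mathrm{ha})
        \times K_{volume},$$

where $K_{volume}$ (voles per cm·ha, default 17) is the species' density at
carrying capacity, estimated from field counts by regression through the
origin of subpopulation size on habitat volume (`fit_k_volume()`): a patch
with no water or no area holds no animals, so the no-intercept model is the
biologically correct one.

Within-patch dynamics are a Ricker recursion with environmental noise on
the exponent,

$$N_{t+1} = N_t \exp\!\big(r_d (1 - N_t/K) + \varepsilon\big), \qquad
  \varepsilon \sim \mathcal N(0, v_r),$$

with a **population ceiling at $K$** applied after each step
(`demography_params(ceiling = 1)`), and the local-extinction rule
$N < 1 \Rightarrow N = 0$. $N$ is continuous; only the extinction rule
discretizes it.

The ceiling deserves its own paragraph because it is the one place where
the package's annual step adds a term to the bare recursion. At the
parameter regime this model family is used in — $r_d$ near 0, $v_r$ near
1 — the bare recursion is a nearly undamped random walk in $\log N$ on the
low side and only weakly damped above $K$: its stationary distribution
puts surviving patches orders of magnitude above carrying capacity
(overshoots of 50–100 × $K$ are typical), which in turn makes migration
pressure enormous and any clustered landscape effectively immortal. No
field system of this kind behaves that way: subpopulations sit at or below
carrying capacity, isolated small marshes die within a decade, and whole
networks fail within a century. The ceiling — the standard device of
ceiling-type PVA models, the same tradition the $r_d$/$v_r$
parameterization comes from — restores exactly that behavior: a boom year
holds a patch at $K$, busts accumulate, and persistence times scale with
$(\ln K)^2 / v_r$. Setting `ceiling = Inf` recovers the unbounded
recursion for users who want it.

Patches are coupled by *migration pressure*: the expected number of
immigrants into patch $i$ per year is

$$\lambda_i = \beta \sum_{j \ne i} N_j \, e^{-\alpha d_{ij}},$$

realized as an independent Poisson draw per patch. $\alpha$ (1/m) is the
rate of an exponential dispersal kernel — the reciprocal of the mean
dispersal distance, which is also its maximum-likelihood estimate from
movement records (`alpha_mle()`). $\beta$ is a dimensionless calibrator:
near 1 for vagile, locally common species, far lower (default 0.01) for a
rare, dispersal-limited one. Immigrants are *added* to the receiving patch;
sources are not decremented — emigration mortality and within-patch
feedback of emigration are deliberately not modeled. An extinct patch with
habitat can be recolonized by immigrants; a zero-habitat patch absorbs
immigrants that die at the next growth step (a dispersal dead-end).

### The annual event order

The yearly loop is: (1) draw one shared noise vector; (2) advance all
patches one Ricker step simultaneously and apply the ceiling; (3) apply the
extinction rule; (4) compute migration pressures *from the post-growth
populations*; (5) draw and add migrants; (6) record. Populations start at
$K_i$ by default (`sim_config(n0_rule = "at_K")`); an `"area_K"` rule
(area × $K_{volume}$, depth-free) and an explicit `n0` vector are provided
because initialization conventions differ between implementations of this
model family and colonization experiments need empty starting patches.
Migrants arriving in a year count toward that year's recorded abundance
and face density dependence the following year.

### Correlated environmental noise

`spacecor` interpolates between independent per-patch noise (0, the
default) and strong local correlation (1). The correlation between patches
$i$ and $j$ is $\rho_{ij} = \text{spacecor} \cdot e^{-d_{ij}/L}$ with $L$
the mean off-diagonal inter-patch distance, so the decay scale adapts to
the landscape rather than to an arbitrary constant. When the implied
matrix is merely positive *semi*definite (coincident patches at full
correlation) sampling falls back to an eigenvalue square root; an
indefinite matrix is repaired to the nearest PSD correlation
(`Matrix::nearPD`) with a warning.

## Outputs and response variables

A run of `run_simulation()` aggregates `trials` independent trials (trial
$i$ is seeded `seed + i - 1`, so results are identical however the trial
set is partitioned; an identical base seed reproduces every output bit for
bit). Time to extinction $T_e$ is the mean over trials of the first year
the metapopulation total hits zero; trials surviving the whole run
contribute `tmax` — a censored mean, never an extrapolation, so $T_e \le$
`tmax` always and responses saturate at the censor (visible as the plateau
in the $K_{volume}$ sensitivity curve). The standard responses at
evaluation year $t = 25$ are the mean proportion of occupied patches
(`mvp`, occupancy means $N \ge 1$, the complement of the extinction rule),
mean metapopulation size (`mN`), and mean migrants per year (`mcol`,
counting every individual drawn, including those landing in zero-habitat
patches).

## Source/sink classification

`classify_patches()` runs each patch in isolation (every other patch's
depth set to zero — geometry untouched) and the landscape intact. A patch
is a source-in-isolation if its isolated $T_e$ exceeds 25 years, and
persistent-in-context if its mean occupancy at year 25 in the intact run
is at least `occupancy_cut`. The four combinations give Context-independent
Source, Rescued Sink, Converted Sink and Context-independent Sink. Two
genuinely open choices are exposed as knobs rather than hidden:
in-context persistence could equally have been defined through a
patch-specific $T_e$; occupancy was chosen because it is defined for every
patch in a shared run, and the cut (default 0.5) is a parameter.
Isolated-$T_e$ sink classes use thresholds >25 (I), 10–25 (II), <10 (III),
with both boundary values placed in class II. Isolation runs reuse the
same `trials` and `tmax` as the in-context run for comparability.

## Scenarios

`apply_scenario()` is a pure transformation of the landscape. Fire and
anthropogenic water loss zero the depth of a patch set or region; drought
scales *depth* by $1-p$ — since habitat is area × depth, this scales every
$K_i$ by $1-p$, and an `scale_area` action exists for users who prefer the
other margin. Moderate drought is $p = 0.35$; the minor and severe levels
(0.15 and 0.55) are this package's defaults, chosen to bracket moderate
symmetrically, and are plain arguments. A megamarsh merges a region into
one patch with the summed area (conserved exactly), the maximum depth, and
the area-weighted centroid — one defensible concretization of "expand a
cluster into a single large marsh". `compare_scenarios()` shares one base
seed across scenarios, reports percent change in $T_e$ against the
mandatory baseline entry, and attaches the per-trial extinction-year table
so downstream ANOVA/Tukey comparisons can use standard tools (`aov`,
`TukeyHSD`) rather than anything bespoke.

## Sensitivity analysis

`ofat_sweep()` varies one parameter over a grid with everything else at
defaults: $r_d \in [-0.5, 0.5]$ by 0.1, $K_{volume} \in [1, 100]$ by 5,
$v_r \in [0, 10]$ by 1, $\beta$ and $\alpha \in [0, 0.1]$ by 0.01. "1 to
100 by 5" ends at 96; whether the endpoint belongs in the grid is
ambiguous, so `include_endpoint` (default off) appends 100. Each grid
row's seed is a hash of the parameter name and value folded into the base
seed, making rows independent of grid order and subsetting. The reported
spread is the across-trial standard deviation of the extinction year.
`sweep_shape()` compares a linear and an asymptotic-exponential fit by AIC,
the diagnostic used to distinguish the linearly rising responses ($r_d$,
$\beta$) from the exponentially decaying ones ($v_r$, $\alpha$).

## The synthetic landscape

The authors of real marsh-network datasets rarely publish patch tables, so
`synthetic_landscape()` generates one that emulates a desert wetland
complex: 36 patches in three regional clusters (north/central/south) whose
centers sit ~1.4 km apart along a valley axis — far enough that
between-cluster dispersal is rare under $\alpha = 0.01$/m — with
within-cluster spread of 250 m (typical neighbor separations of tens to a
few hundred meters). Areas are log-uniform on 0.02–1.1 ha and depths
uniform on 2–7 cm, so carrying capacities at $K_{volume} = 17$ are
right-skewed across roughly 1–130: many small patches and a handful of
large ones, matching the skew of observed subpopulation sizes in such
systems. Under default parameters the preset produces a *mortal* baseline
(mean $T_e \approx 75$ yr, most trials extinct within the horizon, about
one migrant per year at year 25) and isolated-patch lifetimes spanning all
three sink classes — the dynamic regime in which the sensitivity and
scenario machinery is informative.

What the generator does **not** emulate: real marsh geometry and
hydrological grouping, correlated area–depth structure, temporal trends in
water availability, or observation error in the patch table. Tests passing
on this fixture therefore validate the simulator's mechanics and
qualitative response shapes, not any quantitative prediction for a real
landscape.

## Numerical choices and degenerate inputs

* $K = 0$ maps the Ricker step to 0 directly (no division by zero).
* `v_r = 0` returns an exact zero noise vector and consumes no random
  numbers, keeping deterministic runs replayable.
* Once the metapopulation total is zero the trial is closed out early;
  extinction is absorbing by construction (no outside immigration).
* Sample variances of abundance guard against tiny negative values from
  the one-pass accumulation.
* Validation rejects negative areas/depths/parameters and duplicate patch
  ids with field-named errors.

## Problem sizes

The test suite runs the full preset at 100–500 trials × 101 years
(sweeps at 100 trials; the distributional oracle comparison and the
classification fixture at 500), sizes at which a complete run takes a few
minutes on one core while Monte-Carlo error stays well inside the margins
the qualitative assertions need. Moment checks use $10^5$ draws.

## Known limitations

No demographic (individual-level) stochasticity, age/stage structure, or
density-dependent dispersal; no within-year time steps or pulsed
synchronized forcers; migration does not deplete source patches; $\lambda$
is linear in neighbor abundance with no saturation. The ceiling is a hard
bound rather than a soft density response above $K$. These match the
scope of the model family this package implements; relaxing them is
future work, not configuration.
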