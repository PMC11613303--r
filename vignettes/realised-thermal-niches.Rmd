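---
title: "Realised thermal niches in a bioenergetic fish community: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Realised thermal niches in a bioenergetic fish community: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

A fish's *fundamental* thermal performance curve (TPC) describes the net
energy it can devote to growth and reproduction as a function of
temperature when nothing else is limiting: food at satiety, water fully
oxygenated. Field populations never live under those conditions. Prey
abundance and dissolved oxygen covary with temperature over space and
season, so the *realised* TPC — the net energy fish actually achieve at
each temperature they encounter — sits below the fundamental curve and can
differ from it in height, width and the location of its optimum.

`realTPC` builds a small, fully synthetic world in which this divergence
can be generated, measured and decomposed: an individual-based,
size-structured community of three interacting fish species on a gridded
seasonal environment. Because every flux in the model is known, the
deviation of realised from fundamental performance can be split exactly
into an oxygen-attributable and a food-attributable component, per species
and life stage, and related to trophic level.

## Bioenergetics

All energy fluxes are carried per individual of somatic mass $w$ (g), in
grams of prey-mass equivalents per year.

**Ingestion** follows a Holling type I functional response with a satiety
plateau:
$$I = w^\beta \min(\kappa_0 P,\; s\, I_{max}),$$
where $P$ is the accessible prey biomass co-occurring with the individual,
$s$ is the life-stage multiplier ($\eta_{early} \in [1.4, 1.9]$ below age
1, 1 afterwards, reflecting the faster mass-specific growth of early
stages), and $\kappa_0 = I_{max} / P_{sat}$ is the mass-specific clearance
coefficient. Clearance scales with $w^\beta$ like the plateau, so the
satiety threshold sits at a fixed accessible biomass $P_{sat}$ (tonnes per
cell) regardless of body size; this is what lets the stage multiplier
translate into stronger early-life food limitation, the model's core
ontogenetic mechanism.

**Assimilation** is a fixed fraction $A = \xi I$; the rest is lost to
egestion and excretion.

**Mobilisation** converts assimilated energy into usable form at rate
$$E_M = A \cdot f_{O_2}(O_2)\cdot \varphi_T(T),$$
with a Hill dose–response in oxygen saturation,
$f_{O_2}(x) = x^h/(x^h + K_{O_2}^h)$ (one half at $K_{O_2}$ for any $h$),
and a peaked temperature response: Arrhenius
$\exp(-E_A^M/k_B T_K)$ normalised to 1 at a peak temperature $T_{peak}$,
multiplied by $\exp(-\lambda (T - T_{peak}))$ above the peak. For the
factor to actually decline past the peak, $\lambda$ must exceed
$E_A^M/(k_B T_K^2)$; calibration enforces this.

**Maintenance** is a plain Arrhenius cost
$E_m = c_m w^{\beta_m} \exp(-E_A^m / k_B T_K)$, and the **net energy**
available for tissue production is $E_P = E_M - E_m$, which may be
negative. Temperatures are degrees Celsius at every interface and Kelvin
only inside the exponentials; activation energies are in eV with $k_B$ in
eV/K.

The *fundamental* TPC is $E_P(T)$ under satiety ingestion and 100 %
saturation. Note that 100 % saturation is taken literally: the Hill factor
$f_{O_2}(100) < 1$ is part of the fundamental curve, so the oxygen
component of the deviation is exactly zero in a fully saturated
environment.

## Calibration to characteristic points

Users prescribe, per species, the three characteristic points of the
fundamental curve at a reference mass $w_{ref}$: the zeros $T_{min}$ and
$T_{max}$ and the optimum $T_{opt}$. `calibrateSpecies()` solves:

1. given a candidate $T_{peak}$, the two zero conditions
   $E_P(T_{min}) = E_P(T_{max}) = 0$ form a linear 2×2 system in
   $(\log c_m, E_A^m)$, solved in closed form;
2. a one-dimensional root search over $T_{peak}$ drives the curve's argmax
   onto $T_{opt}$. In the regular regime the argmax coincides with
   $T_{peak}$ (below the peak the mobilisation term outgrows maintenance
   whenever the curve is positive; above it the net decline is immediate),
   so the search converges at once — but the result is always verified on
   a dense 0.01 °C grid: zeros to $10^{-6}$ of the curve maximum, argmax
   within 0.1 °C, and exactly one sign change of the successive
   differences between the zeros (dome shape).

Infeasible requests (an optimum too close to a bound for the chosen
$\lambda$, or a non-ordered triple) are reported as errors, never silently
adjusted.

## The simulated community

The biological unit is a school: a cohort of identical individuals with
one age, somatic mass, gonadic mass, abundance and grid cell. Each 1/24-y
step runs, in fixed order: movement → predation → bioenergetics →
maturation/reproduction → ageing. The order is a reproducibility
convention; nothing in the analysis depends on it at this time resolution.

* **Movement** is a lazy rook random walk (stay or one of four
  neighbours, uniformly), with moves out of the grid or the species
  habitat rejected; the stationary distribution over the habitat is
  uniform.
* **Predation** is opportunistic and size-based. A predator of mass $w$
  can eat co-located schools and low-trophic-level (LTL) pools whose
  individual mass falls within $[w/R_{max}, w/R_{min}]$ (closed bounds).
  Benthic pools are reachable only by demersal and benthic species;
  benthic-species schools are out of reach of pelagic predators. On top of
  the size window, an OSMOSE-style accessibility matrix (per species ×
  life stage × LTL group, coefficients in $[0,1]$) scales the pool biomass
  a stage perceives — this is how ontogenetic diet shifts beyond pure size
  structure (e.g. a strictly piscivorous adult) are encoded. Demands are
  spread over accessible items proportionally to biomass; when an item is
  over-subscribed all takes from it are scaled down by one factor
  (single-pass proportional competition, order-independent). Biomass is
  conserved to machine precision and the simulator tracks the largest
  overdraw and intake/removal imbalance over a run.
* **Bioenergetics** uses the realised per-capita ingestion rate, fixed at
  ingestion time, with the temperature and oxygen of the school's cell:
  vertically integrated fields for pelagic and demersal species, bottom
  fields for benthic species. Positive net energy grows soma (immature) or
  is split soma/gonads with a fixed allocation fraction (mature, the
  biphasic rule). Negative net energy triggers starvation mortality
  proportional to the unmet maintenance fraction:
  $N \leftarrow N e^{-m_{starv}\, u\, \Delta t}$ with
  $u = \min(1, -E_P/E_m)$.
* **Maturation** occurs deterministically when length crosses a linear
  age–length reaction-norm midpoint. During spawning steps, pooled gonad
  mass becomes eggs (gonad / egg mass), passed through a Beverton–Holt
  cap (`egg_capacity`) and an egg-to-recruit survival factor that folds
  pre-recruitment larval mortality; recruits enter as a small number of
  age-0 schools in random habitat cells. The Beverton–Holt cap is the
  standard density-dependent closure; it only binds when food does not
  (e.g. under deliberately non-limiting forcing) and is far above any egg
  flow the food-limited community produces.
* **Ageing** applies background mortality ($m_{bg}$, plus $m_{early}$
  below age 1), removes schools beyond the species longevity `max_age`,
  and drops near-empty schools.

## Synthetic forcing

`generateForcing()` builds a periodic climatology on the grid:
temperature = latitudinal gradient + seasonal sinusoid + seeded noise
(bottom fields are integrated fields plus configurable cooler/less
oxygenated offsets); oxygen = baseline minus a seasonal depression, with
an optional seasonal bottom hypoxic patch over southern rows; LTL biomass
per group = seasonal bloom modulated by $\exp(\rho\, z(T))$, where $z$ is
the standardised noise-free temperature anomaly and the signed coefficient
$\rho$ controls how strongly prey tracks temperature ($\rho = 0$ decouples
them); fields are renormalised so the group mean equals its prescribed
biomass, and clamped at zero. Identical (grid, scenario, seed) inputs give
bit-identical output.

Three presets isolate mechanisms:

* **optimal** — pools so large that no reachable community demand can dent
  them (food non-limiting *by construction*) and oxygen pinned at 100 %.
  Under this forcing every realised sample must coincide with the
  fundamental curve; the pipeline reproduces this to machine precision,
  which is the strongest internal consistency check of the whole package.
* **uniform_limitation** — prey a fixed fraction of a satiety reference,
  constant over space and season, oxygen at 100 %. Used for the analytic
  properties of uniformly scaled ingestion (lower, narrower curve with a
  non-warm-shifted optimum).
* **covarying** — the study conditions: a 6 °C latitudinal gradient with a
  ±3.5 °C season on a 10 × 10 grid of 30 km cells, mild oxygen
  unsaturation (92–97 % integrated) with a late-summer southern bottom
  hypoxic patch, and four LTL groups whose item masses deliberately
  segregate consumer stages: scarce, strongly seasonal, temperature-
  covarying small zooplankton (larval food), moderate large zooplankton
  (juvenile food), and generous, nearly stable macrozooplankton and
  benthos (adult food). Early stages therefore face the most
  temperature-variable prey and adults the most stable — the mechanism
  behind the ontogenetic gradient in food limitation.

## The demonstration community

Three species span roughly one trophic level: a cold-preferring pelagic
planktivore ("forage"), a warm-preferring benthic flatfish feeding on
benthos as an adult, and a demersal piscivore whose adults eat fish
(flatfish juveniles, forage fish, own young) with only a marginal
macrozooplankton by-catch. Diet shifts emerge from the size windows and
accessibility coefficients rather than being prescribed as diet fractions.

Choices that shaped the community, made once during model construction:

* **Thermal windows are wide relative to the climate** ($T_{min}$ and
  $T_{max}$ are physiological tolerance limits well outside the 4–18 °C
  the domain produces, while every $T_{opt}$ lies inside it). Fish
  therefore sample the interior of their fundamental curve, not its zeros,
  where the relative deviation statistic diverges.
* **Maintenance shares the ingestion exponent** ($\beta_m = \beta = 0.75$
  for the demonstration species; both remain configurable). Mass-specific
  net energy $E_P / w^\beta$ is then independent of mass, so one
  fundamental curve per species × stage describes all sizes, the cell
  averages of the analysis are insensitive to the mix of school masses,
  and the ontogenetic pattern in the oxygen component is carried purely by
  the early-life ingestion multiplier. With distinct exponents, cell
  averages acquire a mass-aggregation bias that can dominate the adult
  statistics — the main reason this choice matters.
* **Scope margin.** The demonstration species use a mobilisation
  activation energy of 0.75 eV with $\lambda = 0.18$ per °C, which leaves
  maintenance at about 40 % of mobilised energy at the optimum; juveniles
  at ~70 % of satiety still grow, which keeps the community viable while
  leaving room for measurable limitation.
* **Regulation lands on the early/juvenile bottleneck.** High egg survival
  floods the scarce larval pool, so recruitment is self-limited by
  scramble competition while adults stay near satiety on generous pools —
  the same asymmetry the real system shows, and the reason the food
  component of the deviation falls across ontogeny. Two capture-efficiency
  coefficients keep a few percent of genuine adult limitation in the
  planktivore (its effective adult pool straddles its satiety threshold
  seasonally), which gives the adult stage its (small, negative) trophic
  level gradient.
* **Habitat bands** keep each species in thermally suitable latitudes,
  with a northern refuge for the forage fish outside the piscivore's
  range.

## Realised TPCs and the deviation decomposition

After a spin-up (default half of a 20-year run), the simulator records,
per school and step, the mass-specific net energy rate together with the
temperature and oxygen that forced it. `collectSamples()` averages these
over schools within each (species, life stage, cell, step): one realised
sample per occupied cell and step, as in the protocol the package
emulates. Stages are: early life (age < 1), juvenile (older, immature),
adult (mature).

For a species × stage sample set with temperatures $T_j$,

$$D_{O_2,B} = \frac{1}{n} \sum_j
  \frac{E_{\cdot,\cdot}(T_j) - E_j}{E_{\cdot,\cdot}(T_j)}$$

is the mean relative deviation of realised from fundamental net energy.
The oxygen component $D_{O_2,\cdot}$ replaces $E_j$ with a counterfactual
computed at satiety ingestion but the sample's actual temperature and
oxygen; because the fluxes are additive, the food component is exactly
$D_{\cdot,B} = D_{O_2,B} - D_{O_2,\cdot}$. All three statistics use one
retained sample set, which makes the decomposition additive to machine
precision.

**Near-zero guard.** The ratio diverges at the TPC zeros, where the
denominators vanish. Samples whose fundamental value is at or below 1 % of
the fundamental maximum at their own stage and mass are excluded and
counted (`n_excluded`); additionally, samples whose whole dome is
degenerate — maximum below 1 % of the mass-specific flux scale
$\xi s I_{max} f_{O_2}(100)$, as happens for fish near an asymptotic
mass — are excluded, since no relative comparison is meaningful there. The
guard fraction is configurable (`analysis$eps_frac`).

The realised optimum is reported from 0.5 °C temperature bins (mean net
energy per bin, maximal bin centre, ties towards the colder bin); the
deviation statistics themselves never use binning.

## Trophic levels and the ANCOVA

Diets are aggregated over the whole analysis window into a predator
(species × stage) by prey (species × stage and LTL group) biomass matrix.
Trophic levels solve the flow-weighted fixed point
$TL = 1 + \sum_p f_p\, TL_p$ with configured base levels for the LTL
groups (phytoplankton-anchored: zooplankton 2.0–2.5, benthos 2.5); the
fixed point matches a direct linear solve on constructed webs to the
iteration tolerance ($10^{-6}$). The food component of the deviation
(converted to percentage points) is regressed on trophic level with life
stage as a categorical factor and stage-specific slopes:
`100 * d_food ~ 0 + stage + stage:tl`.

## Reproducibility and numerical conventions

* One root seed drives everything; stage seeds (forcing, simulation) are
  derived deterministically from it, and identical configuration + seed
  give bit-identical outputs, including across file round-trips.
* Configurations are YAML with documented defaults; forcing and all
  outputs are plain CSV; `runAll()` writes a JSON manifest (configuration
  hash, seed, versions) for every run directory.
* Process order, closed predation bounds, the deterministic maturation
  midpoint, school-weighted (not abundance-weighted) cell averages, and
  the low-temperature tie-break of the binned optimum are fixed
  conventions, each chosen as the simplest reproducible variant.
* Desk-scale problem sizes: the analyses in the tests and the acceptance
  script use the 10 × 10 demonstration grid at 24 steps per year, 20-year
  runs with 10-year spin-ups, and three seeded replicates of the covarying
  scenario.
* The package is operated from R: configuration builders, the step
  functions, `runSimulation()`, the analysis functions and `runAll()` are
  the interface, with `scripts/acceptance.R` as a worked command-line
  entry point.

## What the synthetic world does and does not show

The generator emulates the gross structure of a shelf-sea forcing — a
latitudinal temperature gradient, seasonality, plankton blooms that track
temperature, near-saturated oxygen with localised seasonal bottom
hypoxia — but none of its hydrodynamic or biogeochemical detail, no
depth-resolved water column, no interannual variability, and its
temperature–prey coupling ($\rho$) is a knob rather than an emergent
property. The community is three species with stylised life histories, not
a calibrated regional food web; passing the package's checks demonstrates
that the *mechanisms* (stage-segregated prey variability, the ingestion
multiplier, dose–response oxygen limitation) produce the expected
qualitative patterns — deviations falling with ontogeny, food limitation
falling with trophic level, oxygen effects rising with stage — not that
any particular ecosystem shows these numbers. Quantities like the
per-stage deviation percentages depend on the chosen pool scarcities and
should be read as properties of the demonstration scenario.

Known limitations: larvae become feeding schools immediately at spawning;
maturation has no probabilistic envelope; movement ignores habitat
quality; LTL pools regenerate fully each step (donor control); and the
single-pass competition slightly under-allocates contested prey relative
to an iterative solution.
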