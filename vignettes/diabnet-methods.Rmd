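---
title: "Modeling the diabetes epidemic on a small-world social network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the diabetes epidemic on a small-world social network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The model

`diabnet` is an agent-based microsimulation of population diabetes dynamics
in an adult population. Each agent carries two demographic attributes (age,
sex), three binary lifestyle behaviors (smoking, diet, physical activity),
and six health dimensions modeled as small state charts: body weight
{normal, overweight}, hypertension {no, yes}, hypercholesterolemia
{no, yes}, glycemic status {none, prediabetes, diabetes}, nephropathy
{no, yes}, retinopathy {normal, diabetic retinopathy, blindness} and
cardiovascular history {none, MI history, stroke history, death}. HbA1c is
drawn at initialization for reporting but has no dynamics; glycemic status
is the categorical chart.

Time advances in annual cycles. Each year runs seven fixed stages:

1. behavior signals are counted from start-of-year states;
2. the three behaviors toggle (influence-adjusted Bernoulli draws);
3. body weight responds to the updated behaviors;
4. hypertension and hypercholesterolemia onset/remission;
5. glycemic progression (normal → prediabetes → diabetes);
6. complications: nephropathy, retinopathy (diabetics only), CVD events
   and death;
7. survivors age by one year.

Each stage is synchronous — it reads only the state left by the previous
stage — so within-stage update order cannot matter. The ordering itself is
a modeling choice (the annual cycle gives no canonical order); we let
behaviors changed in a year affect that same year's weight transition
because behavior change is the faster process. Death (only via the CVD
chart), diabetes and blindness are absorbing; dead agents undergo no
further transitions and are excluded from all rate denominators.

### Social influence

Agents are linked by one undirected Watts–Strogatz network shared by all
three behaviors: a ring lattice of $n$ nodes, each tied to its $k$ nearest
neighbors, with every lattice edge rewired to a random target with
probability $\beta$. Defaults $k = 6$, $\beta = 0.1$ give the classic
small-world regime — clustering far above, and mean path length close to,
an equal-density random graph. $k$ and $\beta$ are free parameters: the
source material for this model requires only the small-world signature,
not specific values, and $\beta = 0$ recovers the pure lattice.

At the start of each year every living agent sends a positive signal to
its neighbors if it is in the healthy state of a behavior (not smoking,
healthy diet, active) and a negative signal otherwise. An agent receiving
$m$ positive and $n$ negative signals adjusts its behavior-transition
probability by the influence factor $F$:

$$p^{*} = \min(1,\; p \cdot F), \qquad
  F = \operatorname{clamp}\!\left(\frac{m+1}{n+1},\; 1/F_{\max},\; F_{\max}\right)$$

applied to the unhealthy→healthy transition; the reverse transition is
multiplied by the reciprocal influence $F(n, m)$ (positive signals that
make adopting a healthy habit more likely equally make abandoning it less
likely). The raw ratio $m/n$ is available (`smoothing = "raw"`) but the
Laplace-smoothed form is the default: it is defined for isolated agents
(where it yields $F = 1$, preserving the configured base rates), it is
antisymmetric ($F(m,n)\,F(n,m) = 1$), and it is monotone increasing in $m$
and decreasing in $n$. A product reading of the signal combination ($m
\cdot n$) is not offered: it would make influence increase with *negative*
signals, contradicting the qualitative rule it encodes.

The cap $F_{\max}$ (default 5) bounds how strongly a neighborhood can
rescale a rate: an uncapped $F$ in a uniformly healthy neighborhood would
push $p^{*}$ to 1. One structural property is worth understanding:
multiplicative influence makes each symmetric behavior chart *bistable* —
for any $F_{\max} > 1$ the population-level behavior dynamics have stable
healthy-minority and healthy-majority equilibria separated by an unstable
threshold (at 50% for symmetric base rates). This is a property of
$p^* = pF$ with reciprocal reverse transitions, not of the cap, and it
has a visible consequence for interventions (below).

Influence applies only to the three behavior charts, never to clinical
transitions.

### Transition rates

All rates are annual probabilities in a single configurable
`transition_table()`. Three charts use published literature values: diet
0.03 in both directions, activity 0.049 in both directions, nephropathy
onset 0.01 and remission 0.0003. Every other default is a **non-calibrated
placeholder**: the upstream calibration (age-specific smoking rates,
age-/sex-specific CVD risk, and the age/weight-dependent hypertension,
cholesterol and diabetes functions) was never published, so this package
replaces each with a transparent base-rate × multiplier structure
(age-band tables, overweight multipliers, behavior multipliers on weight)
with defaults chosen once to place the model in the qualitative regime the
original study reports:

* diabetes prevalence rises steadily from its 5.59% baseline
  (`dm_none_to_pre_base = 0.01`, `dm_pre_to_dm_base = 0.012`, age
  multipliers 1/1.5/2 across bands 20–39/40–59/60+, overweight ×3);
* behaviors affect diabetes only through body weight (weight gain base
  0.08, loss base 0.06), with physical inactivity the stronger per-agent
  risk factor (gain ×2.75 when inactive vs ×1.1 when diet is unhealthy,
  mirrored on the loss side). This asymmetry is what makes the *activity*
  intervention the most effective per flipped agent — strongly enough to
  outweigh the diet intervention's three-times-larger recruitment pool —
  reproducing the published effectiveness ordering
  activity > diet > smoking;
* smoking feeds no downstream chart (the published parameter table gives
  the smoking chart no dependent), so "control smoking" is expected to be
  approximately null for diabetes — consistent with the near-null smoking
  effect in the published comparison.

These placeholders are structure-testing defaults, not estimates; any
serious application should replace them with locally calibrated tables via
the configuration file.

## Population and interventions

`generate_population()` draws agent attributes independently: age and
HbA1c from truncated normals (rejection sampling; the four printed moments
— mean, sd, min, max — are matched by the simplest family consistent with
all of them), every categorical state from its Bernoulli proportion.
Glycemic status is initialized directly from a configured prevalence
(default 5.59%) rather than thresholded from HbA1c: thresholding N(5.5,
0.7) at 6.5% would give ≈7.6% diabetes, contradicting the baseline the
model is anchored to. Prediabetes defaults to the probability mass of
HbA1c in [5.7, 6.5) among non-diabetics (≈31%). Two baseline presets
exist because the published baseline tables conflict (smoking 24.7% vs
29.8%, overweight 42.7% vs 8.84%, active 76.2% vs 68.8%): the default
preset uses the parameter table, the `"validation"` preset the 2006 survey
column. Attributes are independent at baseline — no age–smoking or
diet–activity correlation — a documented simplification.

An `intervention()` is a one-shot baseline shock: a fraction `intensity`
of the agents in the unhealthy state of the target behavior, sampled
uniformly, is flipped to the healthy state before year 1 (flip counts
round half away from zero). Flipped agents immediately rejoin the ordinary
relapse dynamics. A sustained annual program is deliberately not modeled:
the quantity being halved is a stock, and the re-convergence of treated
and control arms is part of what the model studies.

One consequence of the influence bistability deserves emphasis. A shock
that leaves the population on the same side of the contagion threshold
(smoking and activity interventions, in the default baseline) decays: the
treated and control arms re-converge and the behavior-prevalence gap is
maximal immediately after the shock — the "impact is largest early and
attenuates" pattern. A shock that *crosses* the threshold (the diet
intervention at intensity 0.5 lifts healthy diet from 24% to 62%, past
the symmetric-rate threshold at 50%) is locked in by social facilitation
and its gap persists indefinitely. Relatedly, because diabetes is
absorbing and the CVD chart depends only on age and sex (no excess
mortality among diabetics in the placeholder structure), the
control-minus-intervention *diabetes prevalence* gap is a cumulative
integral of the incidence gap: it plateaus but cannot shrink. Attenuation
of intervention impact is therefore assessed on the behavior-prevalence
gap, where the mechanism lives.

## Scenario engine

`run_scenario()` runs `replications` independent runs (seed = base seed +
replication index; 30 replications by default, with mean ± SD reported —
the original study reports single trajectories with no uncertainty, which
we deliberately do not imitate), each generating a population and network
(a `resample_population = FALSE` mode reuses one baseline across
replications, since it is unknown which convention the original study
used), applying the optional intervention, stepping the annual cycle, and
summarizing every year. Rates use living agents as the denominator; with
no survivors rates become `NA`, never zero. `compare_interventions()` and
`sweep_intensities()` wrap the control-vs-intervention table and the
intensity × horizon grid; `cost_savings()` converts a prevalence
reduction in percentage points to averted cases and annual medical-cost
savings (reporting both exact and 2-significant-figure case counts,
because published summaries mix the two roundings).

## Numerical and testing choices

* Every probability handed to a Bernoulli draw is asserted into [0, 1];
  multiplier products are clamped.
* Determinism: a scenario is a pure function of (configuration, base
  seed); outputs are reproducible bit for bit.
* Rate-recovery tests isolate one chart by zeroing all other rates and
  compare one-year cohort frequencies against exact 99% binomial
  intervals (n = 10,000; n = 100,000 for the 0.0003 remission rate).
* Network metrics in tests (clustering coefficient, BFS mean path length,
  random-graph baselines) come from igraph as an independent oracle; the
  package's own network code never computes them.
* Simulation-property tests run at the full study scale — 10,000 agents,
  20 years, 30 replications — for the epidemic-shape, ordering and
  attenuation properties; structural network/unit tests use n ≤ 2,000.
* The long-run behavior equilibrium test (symmetric 0.03 diet rates,
  influence off, 200 years) checks the two-state Markov chain stationary
  fraction 0.5 to binomial precision.

What passing these tests shows is that the machinery is correct and the
model sits in the intended qualitative regime. It does **not** show that
the placeholder rates describe any real population: absolute trajectories
(e.g. the diabetes rate after 20 years) are calibration-dependent and are
not validation targets here.

## Known limitations

* Baseline attribute independence; no household or geographic structure.
* All clinical factors except HbA1c are categorical; no continuous BMI or
  blood-pressure values, no treatment effects.
* One static network for all behaviors; no tie weights, homophily or
  network dynamics.
* Agents past the oldest age band keep that band's rates (no aging out).
* The placeholder CVD chart ignores diabetes status, which removes one
  mechanism (differential mortality) by which intervention gaps could
  attenuate in prevalence terms.

## A worked example

```{r, eval = FALSE}
library(diabnet)
cfg <- run_config(population = population_spec(n = 2000),
                  engine = list(years = 10, replications = 5,
                                base_seed = 1))
cmp <- compare_interventions(cfg, intensity = 0.5, horizons = c(5, 10))
cmp$table
cost_savings(0.69, 1.39e9, 465)
```
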