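---
title: "Growth-starvation cycles and socially-neutral life histories in sporulating amoebae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-starvation cycles and socially-neutral life histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporecycle)
```

## The model

`sporecycle` simulates the eco-evolutionary life cycle of sporulating
social amoebae (the *Dictyostelium discoideum* life style) in a
well-mixed, socially neutral setting: genotypes interact only through
shared resource consumption, never through within-aggregate interactions.
Time alternates between **growth phases**, which end when a resource
pulse is exhausted, and **starvation phases**, whose lengths are either a
fixed `T` (deterministic environments) or exponential with mean
`lambda_T` (stochastic environments).

A genotype couples a division rate $c$ (per hour; the doubling time is
$\ln 2 / c$) with one aggregation trait:

* **discrete mechanism** — a stochastic switch commits a fixed fraction
  $\alpha$ of the population to aggregation the instant starvation sets
  in; the remaining $1-\alpha$ stays solitary;
* **continuous mechanism** — starving solitary cells join the aggregate
  at a constant per-capita rate $\gamma$, so the aggregated fraction
  depends on how long starvation lasts.

### Growth

During growth every genotype grows as
$\dot X_i = c_i\,R/(R_{1/2}+R)\,X_i$ while the resource declines at the
summed rate, so cells + resource are conserved. The package exploits this
conservation law: substituting $X_i(t) = X_i(0)e^{c_i\varphi(t)}$
collapses the whole system to the scalar equation
$\dot\varphi = R/(R_{1/2}+R)$ with
$R = \mathrm{total} - \sum_i X_i$. Genotype ratios at starvation onset
are then resolved exactly (the onset coordinate $\varphi^*$ is a root of
a monotone scalar equation), and the elapsed time is an exact integral
evaluated by adaptive quadrature; only a time-budgeted partial phase
(used for the germination lag) requires an actual Runge-Kutta
integration. All three kernels are compiled. Under saturating kinetics
$R$ reaches zero only asymptotically, so starvation is triggered when
$R$ falls to `exhaustion_tol` (default $10^{-9}$) of the pulse and the
residual is clamped; the bias on any total is at most that tolerance.

### Starvation

At onset, aggregated cells differentiate: a fraction $s = 0.8$ becomes
spores and $1-s$ dies building the stalk (the constant 20%:80%
stalk:spore split; stalk evolution is deliberately outside scope, since
stalk height matters for dispersal, which has no meaning in a well-mixed
patch). Spores are dormant and decay at a small constant rate $\delta$.
Solitary cells die according to a smoothed, truncated Weibull-type
survivorship

$$S_c(t) = \frac{e^{-(\mu t)^{\beta(c)}} - e^{-(\mu T_{sur})^{\beta(c)}}}
                {1 - e^{-(\mu T_{sur})^{\beta(c)}}},
  \qquad \beta(c) = b_0 - b_1 c,$$

normalised to 1 at onset and reaching exactly 0 at the maximum lifetime
$T_{sur}$. $\beta > 1$ is enforced at validation: it gives the slow
initial decay expected while cells consume their own reserves by
autophagy, and $\beta$ decreasing in $c$ encodes the
reproduction-survival tradeoff (fast dividers make smaller cells with
fewer reserves). Both starvation pools have closed forms, so the
starvation phase is evaluated analytically — no stepping — which is what
makes $10^5$-cycle competitions affordable.

When food returns, solitary survivors eat immediately; spores germinate
over a lag $\tau$ and only a viability fraction $\nu(c) = a_0 - a_1 c$
of them recruits (the spore-size/viability tradeoff: faster dividers
make smaller, less viable spores). With the default coefficients the
viability spans exactly $[0.2, 1]$ over the admissible division-rate
range $[0.05, 0.45]$.

### Continuous mechanism details

For the continuous mechanism the solitary pool obeys
$N(t) = N_0 e^{-\gamma t} S_c(t)$ — aggregation and intrinsic mortality
act as independent risks — and the aggregate accumulates as
$\dot A = \gamma N - \delta A$, evaluated by quadrature of its
variation-of-constants solution (substituting $v = \gamma u$ keeps the
integrand well-scaled for any $\gamma$, including the near-instantaneous
limit, which reproduces the discrete $\alpha = 1$ strain to within 0.1%).
The published description leaves open whether aggregate death $\delta$
acts before or only after spore differentiation and whether $s$ applies
per cohort or at measurement; we apply $\delta$ to the aggregate
throughout and $s$ at measurement, which matches the discrete mechanism
in the fast-aggregation limit. The *aggregation time* is the first time
the remaining solitary fraction drops below a threshold `epsilon`
(default $10^{-6}$); it is bounded by $T_{sur}$ and decreasing in
$\gamma$.

## Parameters

| symbol | argument | default | units | provenance |
|---|---|---|---|---|
| $s$ | `s` | 0.8 | — | published value |
| $\delta$ | `delta` | $10^{-4}$ | /h | assumed ("very low") |
| $\tau$ | `tau` | 4 | h | assumed |
| $\mu$ | `mu` | 0.005 | /h | assumed ($1/T_{sur}$) |
| $T_{sur}$ | `T_sur` | 200 | h | published value |
| $\beta(c)$ | `beta_b0`, `beta_b1` | $3.1 - 4c$ | — | published value |
| $\nu(c)$ | `nu_a0`, `nu_a1` | $1.1 - 2c$ | — | published value |
| $R_{1/2}$ | `R_half` | $10^7$ | resource | assumed |
| $c$ range | `c_min`, `c_max` | 0.05–0.45 | /h | published value |

Values not printed in the source's main text ($\mu$, $\delta$, $\tau$,
$R_{1/2}$) are order-of-magnitude defaults, all configurable, and every
configuration echo tags each parameter `paper` or `assumed`
(`param_sources()`). Choosing $\mu = 1/T_{sur}$ keeps $\mu t \le 1$ over
the whole survivorship support, which makes survival monotone in the
division rate at all times — matching the published ordering of the
survivorship family. Sensitivity variants of the survivorship cost
($\beta = 5.1-8c$, $5.5-10c$, $19-40c$) are reachable through the same
two coefficients; no separate code path exists.

## Evolutionary competitions

`run_evolution()` competes a whole genotype grid through repeated
cycles. Initial abundances are i.i.d. standard log-normal, normalised to
$10^8$ cells; each pulse has magnitude $R_0 = 10^8$. The winner is read
off at the first starvation onset at or after the horizon — a
well-defined event at which every cell is classified — counting spores
plus solitary cells per genotype. (The alternative, counting spores
only, would misrank loner-heavy strategies; the source text does not fix
the within-cycle phase of the measurement.) Stochastic environments run
`n_runs` independent replicates under labelled RNG streams; the winner
is the argmax of the mean relative abundance, and per-run winners are
retained.

Two further conventions the source leaves open: starvation clocks reset
at every food pulse (fed survivors re-partition at the next onset
together with their descendants), and spores whose germination lag is
cut short by resource exhaustion stay dormant until the next pulse
(germination is nutrient-triggered). Counts are continuous densities —
no demographic noise — and genotypes are never pruned, since pruning
could in principle alter long-run winners.

### Problem sizes

The published full-scale experiments use 4141 genotypes (deterministic)
or 44k (stochastic) and horizons of $10^8$ h. The package constructs
those grids (and the tests verify the 4141 count and the two-segment
stochastic $\alpha$ sampling, which yields 1091 values of $\alpha$,
i.e. 44731 genotypes — the source prints 1092/44772 for the same
description; we follow the description), but the package's default
working scale is a reduced grid of 9 $\alpha$-values $\times$ 5 division
rates with horizons of $10^5$–$10^6$ h, which reproduces every
qualitative regime: deterministic environments select pure strategies
($\alpha = 0$ below the lifespan switch near $T_{sur}$, $\alpha = 1$
above it), stochastic environments select pure strategies at the
extremes and bet-hedging mixtures ($0 < \alpha < 1$) at intermediate
mean starvation times. The `paper`-scale preset is recorded in
configuration but must be launched explicitly (it is not a desk-scale
computation).

## Assay emulations

* `clonal_growth_assay()` — one clonal growth phase to onset. By
  conservation the onset population is $X_0 + R_0$ for every genotype,
  so clonal spore counts reflect $\alpha$ alone. Because the question of
  whether "aggregators" includes the stalk-bound cells is
  protocol-dependent, both `aggregators` ($\alpha P$) and `spores`
  ($s\alpha P$) are reported.
* `exponential_starve_assay()` — unbounded exponential growth for a
  fixed time then abrupt starvation (the wash-and-starve protocol);
  here spore number rises with division rate.
* `chimeric_success_starvation()` / `_growth_starvation()` — the
  classical starvation-only 50:50 mix versus the proposed measure that
  includes the shared growth phase. Spores are counted at spore
  formation: instantaneous for the discrete mechanism, at the
  standardised time $T_{sur} = 200$ h for the continuous one. The
  growth-starvation measure reduces to the starvation-only one at high
  cell-to-resource density.
* `dominance_matrix()` / `rank_and_check_linearity()` — pairwise
  tournaments, win counts, and transitivity checks of the dominance
  hierarchy. Ties use a relative spore difference below `tie_tol`
  (default $10^{-9}$; "the same number of spores" is not defined
  numerically in the source). Mixes in which neither genotype makes
  spores (two loner strains) are scored 0.5/0.5 — a convention needed
  because fast-environment winners have $\alpha = 0$.

Only pairwise mixes are implemented; chimeras of three or more genotypes
are out of scope, as is any viability or germination effect on chimeric
success (it is measured before germination).

## Numerical choices

* Growth: exhaustion tolerance $10^{-9}$ of the pulse; the onset root is
  solved to machine precision and the elapsed-time quadrature to
  $10^{-10}$ relative. Genotype updates use log-space exponentials so
  near-extinct lineages (down to the smallest normal double) remain
  finite; lineages below it underflow harmlessly to zero.
* Starvation: closed forms only. The survivorship hazard diverges at
  $T_{sur}$; `survival_hazard()` refuses $t \ge T_{sur}$ rather than
  return infinities.
* Reproducibility: every replicate, sweep entry and assay derives its
  RNG stream from `(master seed, label)` via `seeded_rng()`, so a fixed
  master seed reproduces byte-identical CSV output; CSVs are written
  with 12 significant digits.
* Ranking tie-breaks: win count, then average chimeric success, then
  input order — all recorded in the result object.

## What the synthetic conditions do and do not show

All inputs are generated by the package itself under the study
conditions above; there is no external data. Passing tests therefore
demonstrate internal consistency with the modelled life history — the
conservation law, the closed-form starvation kinetics against
independent fine-step integrations, the winner regimes, and the
hierarchy phenomenology — but not agreement with any particular
laboratory strain set: real amoebae live in spatially structured
habitats, disperse, mutate and recombine, and may carry genuine social
interactions (e.g. stalkless cheater mutants), all of which are
deliberately excluded from this neutral, well-mixed baseline.

## A worked example

```{r example, eval = FALSE}
params <- life_history_params()
grid <- build_genotype_grid(
  genotype_grid_spec("discrete", c(0, 1, 0.125), c(0.05, 0.45, 0.1)))

envs <- lapply(10^seq(1, 4, length.out = 5), function(lt)
  environment_spec("stochastic", lambda_T = lt,
                   horizon = min(1e6, max(1e5, 200 * lt)), n_runs = 5))
sw <- winner_sweep(envs, grid, params, seed = 1)
sw[, c("lambda_T", "winner_alpha", "winner_c")]

winners <- unique(data.frame(alpha = sw$winner_alpha, c = sw$winner_c))
attr(winners, "mechanism") <- "discrete"
dm <- dominance_matrix(winners, mode = "GS", X0 = 1e10, R0 = 1e8,
                       params = params)
dm$is_transitive
winners$alpha[dm$ranking]
```
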