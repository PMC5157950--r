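# sporecycle

Growth–starvation cycle simulation of social amoeba life histories.

## The problem

Social amoebae such as *Dictyostelium discoideum* respond to starvation
by aggregating into a multicellular fruiting body: part of the aggregate
dies building a stalk, the rest becomes hardy, slow-to-germinate spores,
while cells that stay out of the aggregate ("loners" or non-aggregators)
keep the option of instant regrowth but die if starvation lasts too
long. Laboratory chimera experiments read the unequal spore shares of
mixed genotypes as social dominance — yet strongly "dominant" strains
coexist with "subordinate" ones in nature. `sporecycle` implements a
socially-neutral, ecologically grounded null model for this life cycle:
genotypes differ only in non-social life-history traits, interact only
by competing for food, and the package asks how much of the apparent
social phenomenology (reproductive skew, linear dominance hierarchies,
trait correlations) such a neutral model already produces. It is aimed
at microbial eco-evolution researchers who want a tested, scriptable
baseline against which genuinely social explanations must be judged.

## The model

A genotype is a pair (α, c) — or (γ, c) for the continuous variant —
where c is the division rate and α the fraction of the population that
aggregates at starvation onset (γ: the per-capita aggregation rate
during starvation). One cycle consists of:

* **Growth** — Michaelis–Menten competition for a shared pulse R₀:

  ẋᵢ = cᵢ R/(R₁/₂+R) xᵢ,  Ṙ = −R/(R₁/₂+R) Σᵢ cᵢ xᵢ,

  so cells + resource are conserved; exhaustion of R triggers
  starvation.
* **Partitioning** — a fraction α of each genotype aggregates; s = 0.8
  of the aggregate becomes spores, 1−s is lost to the stalk.
* **Starvation** (duration T, fixed or exponential with mean λ_T) —
  spores decay at rate δ; solitary cells survive with probability

  S_c(t) = (e^−(μt)^β(c) − e^−(μT_sur)^β(c)) / (1 − e^−(μT_sur)^β(c)),

  a truncated Weibull-type survivorship with β(c) = 3.1 − 4c > 1, zero
  at the maximum lifetime T_sur = 200 h.
* **Germination** — when food returns, survivors eat immediately while
  spores germinate after a lag τ with viability ν(c) = 1.1 − 2c (from
  1 at c = 0.05 down to 0.2 at c = 0.45).

Long-run competitions (`run_evolution`, `winner_sweep`) determine the
winning genotype per environment; single-cycle assays emulate laboratory
protocols: clonal growth (`clonal_growth_assay`), wash-and-starve
exponential growth (`exponential_starve_assay`), and pairwise chimeric
success in starvation-only or growth+starvation setups
(`chimeric_success_*`, `dominance_matrix`, `rank_and_check_linearity`).

## Worked example

Sweep five stochastic environments (mean starvation times from 10 h to
10⁴ h) on the reduced 9 × 5 genotype grid, then build the dominance
hierarchy of the winners at high cell density:

```r
library(sporecycle)
params <- life_history_params()
grid <- build_genotype_grid(
  genotype_grid_spec("discrete", c(0, 1, 0.125), c(0.05, 0.45, 0.1)))

envs <- lapply(10^seq(1, 4, length.out = 5), function(lt)
  environment_spec("stochastic", lambda_T = lt,
                   horizon = min(1e6, max(1e5, 200 * lt)), n_runs = 5))
sw <- winner_sweep(envs, grid, params, seed = 1)
sw[, c("lambda_T", "winner_alpha", "winner_c")]
#>    lambda_T winner_alpha winner_c
#> 1     10.00        0.000     0.15
#> 2     56.23        0.125     0.35
#> 3    316.23        0.625     0.35
#> 4   1778.28        1.000     0.25
#> 5  10000.00        1.000     0.35

winners <- unique(data.frame(alpha = sw$winner_alpha, c = sw$winner_c))
attr(winners, "mechanism") <- "discrete"
dm <- dominance_matrix(winners, mode = "GS", X0 = 1e10, R0 = 1e8,
                       params = params)
dm$is_transitive
#> [1] TRUE
winners$alpha[dm$ranking]
#> [1] 1.000 1.000 0.625 0.125 0.000
```

Fast-recovery environments select pure loner strategies (α = 0),
slow-recovery ones select all-spore strategies (α = 1), and intermediate
ones select bet-hedging mixtures — and when the winners are mixed
pairwise at high cell density (starvation-dominated conditions), they
fall into a *transitive* dominance hierarchy ordered exactly by their
spore investment α, with no social interaction anywhere in the model.

A command-line wrapper with the same functionality is installed at
`inst/cli/sporecycle` (subcommands `evolve`, `sweep`, `clonal-assay`,
`chimera`, `hierarchy`, `validate-config`).

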