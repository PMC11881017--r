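# evorescue

Spatially explicit individual-based simulations of **evolutionary rescue
under structured habitat loss and a warming environment**, with the
landscape metrics and hierarchical Bayesian analysis needed to ask: *which
properties of a habitat-loss pattern decide whether a locally adapted
population survives climate change?*

The package is aimed at evolutionary ecologists and conservation
geneticists studying the interaction of fragmentation and environmental
change. It simulates diploid, hermaphroditic populations on a periodic
(torus) landscape carrying a spatially autocorrelated environmental
gradient. Populations first adapt locally over a burn-in; then, in a
single generation, two thirds of the landscape is destroyed according to a
structured loss map while a 100-generation linear warming ramp begins.
Because de novo mutation is frozen after the burn-in, any persistence must
come from movement and selection on standing genetic variation.

## The model in brief

Individual survival each generation is the product of local competition
and phenotype–environment matching,

    w_i = min{ 1, (2 π σ_p² K / C_i) · exp( −((P_i − e(x_i, y_i)) σ_b)² / (2 σ_f²) ) }

where `C_i = Σ_j exp(−d_ij² / 2σ_p²)` sums a Gaussian competition kernel
over neighbours within `3σ_p` (torus distances), `P_i = Σ_l q_l` is a
polygenic phenotype summing QTL effects `q_l ~ N(0, σ_QTL)` over both
haplotypes, and `σ_b` ramps from 0.1 to 1 over the burn-in. Mating is
nearest-neighbour within `3σ_p`, offspring counts are Poisson(λ₀), and
each individual may make one small habitat-choice move per generation,
accepted only if fitness strictly improves.

Each loss scenario is summarized by three landscape properties computed on
the post-loss landscape: the change in trimmed environmental breadth
`ΔB_e = B₂ − B₁` (2.5th–97.5th percentile range), the mean environmental
shift `Δμ_e`, and the loss autocorrelation length `l_hl` (larger ⇒ larger
remnant patches). Scenario sets spanning wide property ranges are drawn by
weighted density sampling, and persistence is analysed with a Bayesian
random-slope logistic regression per property,

    logit(p_persist) = (β₀ + β₀ˡ) + (β₁ + β₁ˡ) · V ,   β₀ˡ ~ N(0, σ₀), β₁ˡ ~ N(0, σ₁)

with landscape-level random intercepts and slopes (JAGS), plus
fixed-effect two-way interaction models `β₀ + β₁V₁ + β₂V₂ + β₃V₁V₂`.

## Worked example

```r
library(evorescue)

L  <- generate_landscape(landscape_params(mu_e = 0, sigma_e = 1, l_e = 0.1,
                                          resolution = 128, seed = 7))
L
#> <env_landscape> 128x128 torus grid | mu_e=0 sigma_e=1 l_e=0.1 seed=7 | Geary's C=0.004

sc <- generate_loss_map(l_hl = 0.08, p_l = 2/3, resolution = 128, seed = 42)
scenario_properties(L, sc)[, c("delta_Be", "delta_mu_e", "l_hl", "fraction_lost")]
#>   delta_Be delta_mu_e l_hl fraction_lost
#> 1   0.3318    -0.1819 0.08        0.6666

cfg <- sim_config(K = 500, burn_in = 1000)   # desk-scale defaults
bi  <- run_burn_in(L, cfg, seed = 1)
bi$state
#> <sim_state> generation 1000 | 378 individuals | 420 segregating alleles
cor(bi$state$phen, env_at(L, bi$state$x, bi$state$y))
#> [1] 0.977    # strong local adaptation after the burn-in

tr  <- run_scenario(bi$state, L, sc, cfg, delta_e = 3, seed = 2)
score_trajectory(tr)[, c("persisted", "t_extinct", "delta_n_i", "delta_n_a", "mu_d")]
#>   persisted t_extinct delta_n_i delta_n_a  mu_d
#> 1     FALSE       103         0         0 0.006
```

Geary's C near 0 confirms strong spatial autocorrelation of the landscape;
the burned-in population of 378 individuals carries 420 segregating QTL
alleles and its phenotypes track the local environment (r = 0.98). Under
this loss map the warmed population goes extinct 103 generations after
habitat loss — but it is the warming, not the loss, that kills it: over 10
replicates, persistence is 0.2 with `delta_e = 3` versus 1.0 with
`delta_e = 0`. Full study designs (scenario selection across landscapes,
both warming arms, and the hierarchical fits) run through
`study_design()` + `run_main_design()`, with `run_interaction_design()`
and `run_sensitivity()` for the interaction and sensitivity analyses; a
thin command-line front end is installed at `inst/cli/evorescue.R`.

See the methods vignette (`vignettes/evorescue-methods.Rmd`) for the full
model description, parameter calibration, and numerical conventions.

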