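# ricomp

Bayesian phylogenetic mixed models for comparative crossing data on
reproductive isolation (RI).

## The problem

Speciation studies assemble tables of interspecific crosses — one row per
cross, with an RI index (0 = free interbreeding, 1 = complete isolation)
and predictors such as genetic distance, sympatry/allopatry, or floral
divergence. Because each species is used in many crosses, rows are not
independent: crosses sharing a parent, or whose parents are close
relatives, resemble each other. Mantel tests and phylogenetically
independent contrasts, the traditional tools, cannot model categorical
predictors with interactions or several correlated predictors at once.

`ricomp` fits the mixed model

    y_RI = mu + x1*b_gen.dist + x2*g_sym + (x1*x2)*b_int + Z_f f + Z_m m + e

with separate random effects for the maternal (`Z_f f`) and paternal
(`Z_m m`) species of each cross, distributed `u ~ N(0, sigma^2 * A)` where
the relatedness matrix `A` comes from an ultrametric phylogeny
(shared-MRCA depth, scaled to [0,1]) or from a pairwise genetic-distance
matrix (`1 - D`). Fitting is by a blocked Gibbs sampler (compiled sweep,
seed-reproducible) with scaled inverse-gamma variance priors whose scale is
one-third of the response variance. Hypotheses are tested by whether the
95% highest-posterior-density (HPD) interval of a coefficient — or of a
derived sum such as the sympatric slope `b_gen.dist + b_int` — excludes
zero. Convergence is checked with Gelman–Rubin potential scale reduction
factors across >= 2 over-dispersed chains.

Also included: composite and sequential (multiplicative) RI indices from
barrier-component data, tree grafting by proportional branch-length
rescaling to merge two phylogenies, and a synthetic-data generator that
simulates crossing datasets from the model with known truth.

## Worked example

```r
library(ricomp)

tree <- simulate_yule(30, seed = 1)                 # unit-depth Yule tree
sim  <- simulate_crossing_data(tree, simulation_truth(),
                               n_crosses = 150, seed = 2)
fit  <- ri_fit(sim$dataset, RI ~ gen_dist * sympatry, sim$relate, seed = 7)
summary(fit, contrasts = list(
  sympatric_slope = c(gen_dist = 1, "gen_dist:sympatrysympatric" = 1)))
```

```
Posterior summary (2 chains, 20000 iterations)
                  parameter     mean     mode hpd_lower hpd_upper   psrf excludes_zero signif
                (Intercept) 0.220638 0.234373  0.060680   0.37590 0.9997          TRUE      *
                   gen_dist 0.519279 0.518250  0.400402   0.64063 0.9997          TRUE      *
          sympatrysympatric 0.248203 0.244134  0.143585   0.36732 1.0015          TRUE      *
 gen_dist:sympatrysympatric 0.404696 0.394036  0.263846   0.55835 1.0017          TRUE      *
            sigma2_maternal 0.008430 0.006692  0.003156   0.01523 1.0029          TRUE      *
            sigma2_paternal 0.007769 0.006142  0.002603   0.01428 0.9997          TRUE      *
            sigma2_residual 0.010119 0.009687  0.007740   0.01294 1.0001          TRUE      *
            sympatric_slope 0.923975 0.914520  0.815458   1.04426     NA          TRUE      *
Multivariate PSRF: 1.006
```

The data were generated with `mu = 0.2`, `b_gen.dist = 0.5`,
`g_sym = 0.25`, `b_int = 0.4`: every 95% HPD covers its generating value,
each coefficient is correctly flagged (HPD excludes zero), and the derived
sympatric slope is `0.5 + 0.4 = 0.9` within its interval. All PSRF values
are at the converged `<= 1.1` threshold.

For real data, read a crossing table and a tree and join them by taxon
label:

```r
schema  <- cross_schema("maternal", "paternal", "RI",
                        continuous = "gen_dist", categorical = "sympatry")
dataset <- read_cross_table("crosses.csv", schema)
relate  <- tree_to_relatedness(ultrametricize(read_newick("tree.nwk")))
fit     <- ri_fit(dataset, RI ~ gen_dist * sympatry, relate, seed = 7)
```

A thin command-line wrapper with `simulate` / `fit` / `diagnose` / `index`
subcommands is installed at `inst/scripts/ricomp`.

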