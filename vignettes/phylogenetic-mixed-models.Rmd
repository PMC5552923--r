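---
title: "Phylogenetic mixed models for reproductive-isolation crossing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic mixed models for reproductive-isolation crossing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricomp)
```

## The problem

Comparative crossing studies measure reproductive isolation (RI, indexed 0
to 1) for many interspecific crosses and ask what predicts it: time since
divergence (genetic distance), geographic context (sympatry vs. allopatry),
trait divergence. When each species is used in several crosses, the crosses
are not independent observations — two crosses that share a parent, or whose
parents are close relatives, tend to resemble each other. Classical tools
for these data (Mantel tests, phylogenetically independent contrasts)
either cannot model categorical predictors and interactions, or cannot
handle the repeated use of species at all.

`ricomp` treats each cross as one row of a linear mixed model

$$ y_{RI} = \mu + x_1\beta_{gen.dist} + x_2\gamma_{sym}
   + (x_1 x_2)\beta_{int} + Z_f f + Z_m m + e, $$

where \(x_1\) is genetic distance, \(x_2\) a sympatry dummy (0 =
allopatric), and \(Z_f f\), \(Z_m m\) are random effects for the maternal
and paternal species of each cross. The two parental effects are kept
separate because species are rarely used symmetrically in both roles;
separate incidence matrices stay dense and keep the variance components
estimable. Each vector of species effects is distributed
\(u \sim N(0, \sigma^2 A)\), where \(A\) is a relatedness matrix: the
phylogeny (or a genetic-distance matrix) enters the model only through
\(A\). Multi-level categorical predictors (e.g., flower-color classes) and
multiple correlated continuous predictors (genetic, geographic, and floral
distance simultaneously) fit in the same framework by changing the fixed
part of the formula.

Hypotheses are tested with the highest-posterior-density (HPD) decision
rule: an effect is supported when its 95% HPD interval excludes zero.
Derived quantities follow by adding coefficients per posterior draw — for
example the genetic-distance slope *in sympatry* is
\(\beta_{gen.dist} + \beta_{int}\), computed with `contrast()`.

## The relatedness matrix

For an ultrametric tree of depth \(T\), `tree_to_relatedness()` sets
\(A_{ij} = \mathrm{depth}(\mathrm{MRCA}(i,j)) / T\): the proportion of
evolutionary history two taxa share, 1 on the diagonal, 0 for taxa that
split at the root. Scaling by \(T\) puts every tree on the correlation
scale, so variance components are comparable across trees; the alternative
(leaving \(A\) in branch-length units) would fold the tree's absolute depth
into \(\sigma^2\). Tree-derived \(A\) is positive semi-definite by
construction.

Trees that are not ultrametric are handled by `ultrametricize()`, which
extends pendant edges to the maximum depth. We deliberately do not rescale
internal branches: they encode the shared history that \(A\) measures, and
pendant-edge extension leaves them untouched.

For closely related taxa without a reliable tree, a pairwise
genetic-distance matrix \(D\) substitutes via \(A = 1 - D\)
(`distance_to_relatedness()`). Such matrices are not guaranteed positive
semi-definite, and distances above 1 produce negative relatedness entries
(kept, with a warning; a flooring flag clamps them). The sampler therefore
inverts every \(A\) through `stable_inverse()`, which returns the ordinary
inverse for numerically full-rank matrices and the Moore–Penrose
pseudoinverse otherwise, flagged on the result. An indefinite \(1-D\)
matrix makes the implied Gaussian prior improper; if that matters for a
given dataset, a small diagonal addition ("bending") before inversion is a
standard remedy the user can apply to \(D\) directly.

Two trees with complementary coverage are combined with `graft_clade()`:
the backbone subtree spanned by a monophyletic tip set is replaced by a
more detailed donor tree whose branch lengths are multiplied by
(backbone clade depth)/(donor depth), so the grafted clade occupies exactly
the time-depth of the clade it replaces and the result stays ultrametric.
Subspecies or races without resolved relationships can be left as
polytomies; zero-length internal edges are accepted and simply merge MRCA
depths.

## RI indices

`composite_index()` is the unweighted mean of per-barrier strengths
(`barrier_strength()` is `1 - het/hom`). With \(k\) coarse score
components the composite lives on a \(1/k\) grid; `sequential_index()`
instead compounds ordered barriers multiplicatively — total
\(1 - \prod_k (1 - RI_k)\) with per-barrier absolute contributions
\(RI_n \prod_{i<n}(1 - RI_i)\) — producing a more continuous response. The
contributions always sum to the total. Negative strengths (heterospecific
advantage) are allowed in the composite but rejected in the sequential
form, whose multiplicative bookkeeping requires \([0,1]\).

## Priors

Variance components get scaled inverse-gamma priors. The scale \(V\) for
each of the three components (maternal, paternal, residual) is one-third
of the sample variance of the response — the total variance split evenly
across the three covariance matrices. The belief parameter defaults to
\(\nu = 1\) and is exposed because posterior sensitivity to \(\nu\) is real
when the number of species per role is small.

Fixed effects get \(N(0, B_0)\). By default \(B_0 = 10^8 I\), effectively
flat. With several mutually correlated continuous predictors,
`build_prior(mode = "correlated")` sets the off-diagonal prior covariance
between continuous design columns to `beta_scale` times their empirical
correlation. The off-diagonal values of such a prior are not uniquely
pinned down by theory; the empirical-correlation construction is one
defensible choice, and it is confined to `build_prior()` so that other
choices can be substituted. If clipping is needed to restore positive
semi-definiteness, the (pseudo)inverse of \(B_0\) is used downstream.

## The sampler

`ri_fit()` runs a systematic-scan blocked Gibbs sampler: per sweep, one
joint draw of the full \(\beta\) block (much better mixing than
coordinate-wise updates when predictors are correlated), then each
parental effect vector, then the three variances from their inverse-gamma
full conditionals. The sweep loop is compiled code driven by R's RNG, so
chains are bit-identical given a seed.

Defaults: 2 chains, 20,000 iterations, 5,000 burn-in, thinning 10, chain
\(c\) seeded `seed + c - 1`, started from the OLS estimate \(\pm 2\)
standard errors (over-dispersed starts are what give the Gelman–Rubin
diagnostic its power), variances started at \(\mathrm{var}(y)/3\).
Variances are floored at \(10^{-12}\) to avoid the absorbing-zero
degeneracy when a role has very few species. Responses are modeled as
Gaussian even though RI is approximately bounded in \([0,1]\) — the
coefficients stay on the interpretable RI scale, and no link function is
used; this is the framework's deliberate modeling choice, and simulated
responses are correspondingly left untruncated.

Convergence is assessed with `psrf()`: the classic Gelman–Rubin estimator
\(\hat R = \sqrt{((n-1)/n\,W + (1+1/m)\,B/n)/W}\) without the
Brooks–Gelman degrees-of-freedom correction (the correction factor is
negligible near convergence, where the diagnostic is actually used), plus
the multivariate version based on the largest eigenvalue of
\(W^{-1}B/n\). The working rule: accept a fit when all univariate
\(\hat R \le 1.1\); in practice converged desk-scale fits here sit near
1.00 with multivariate values below 1.02. Parameters with zero
within-chain variance are flagged degenerate rather than producing
infinities, unless the chains disagree, which is reported as `Inf`.
`summary()` warns if pooling happens above the 1.1 threshold.

`hpd()` computes the shortest interval containing the requested mass by
scanning all windows of \(\lceil pn \rceil\) consecutive order statistics
(leftmost window on ties); posterior modes come from a Gaussian kernel
density with Silverman's bandwidth.

## The synthetic-data generator

`simulate_yule()` + `simulate_crossing_data()` generate data from exactly
the model the sampler fits, with known truth, so parameter recovery is a
meaningful end-to-end check. Species pairs are drawn with replacement
(each species typically appears in several crosses and both roles), the
genetic-distance predictor is patristic distance scaled to \([0,1]\),
sympatry is Bernoulli(0.5) independent of distance (an option links the
two to emulate differential fusion, for exploration only), and optional
geographic/floral predictors are drawn from a Gaussian copula with a
configurable correlation to genetic distance, to exercise the correlated
prior.

Default truth: \(\mu = 0.2\), \(\beta_{gen.dist} = 0.5\),
\(\gamma_{sym} = 0.25\), \(\beta_{int} = 0.4\), parental standard
deviations 0.05 each (variances \(2.5\times10^{-3}\)) and residual
standard deviation 0.1 (variance \(10^{-2}\)) — moderate effects on the RI
scale relative to noise. Geographic distance is uniform on 0–1000 km and
corolla difference on 0–10 mm, plausible ranges for the kinds of plant
datasets this framework targets.

What the generator does *not* emulate: bounded responses (unless the
realism-only `clip` flag is set), measurement error structure specific to
choice vs. no-choice assays, missing data patterns, or any systematic
dependence of sympatry on divergence. Passing recovery tests on this
generator demonstrates the estimator is correct for its own model, not
that the model is right for any particular empirical dataset.

Validation uses problem sizes chosen to be informative yet quick: 30 taxa
and 150–200 crosses for convergence and recovery studies (10 replicate
recovery fits, 20 replicate null-calibration fits), 50 crosses and 15 taxa
for the fixed-variance GLS equivalence check, and \(10^5\) draws for
conditional-moment checks.

## Numerical choices and limitations

* Eigenvalue rank tolerance for `stable_inverse()`:
  `max(dim) * eps * largest singular value`, the conventional choice.
* The formula parser accepts R's `~`, `+`, `*`, `:` operators and a
  `C(term, ref = "LEVEL")` annotation for reference levels; the default
  reference is the first level in sorted order, which makes "allopatric"
  the baseline without annotation. A categorical term with a single
  observed level is an error rather than a silently zero column, and a
  rank-deficient fixed design is rejected naming the collinear columns.
* Taxon labels are matched to tree tips case-sensitively after trimming
  and space-to-underscore normalization; there is no fuzzy matching, so
  subspecies naming must agree between table and tree.
* Crosses with missing responses or predictors are dropped with a logged
  count.
* Non-Gaussian responses, multi-response variance matrices, random slopes,
  and an interaction between the two phylogenetic effects are out of
  scope; the last would require a cross-classified covariance far sparser
  than these datasets can estimate.

## A worked example

```{r example, eval = FALSE}
tree <- simulate_yule(30, seed = 1)
sim <- simulate_crossing_data(tree, simulation_truth(), n_crosses = 150,
                              seed = 2)
fit <- ri_fit(sim$dataset, RI ~ gen_dist * sympatry, sim$relate, seed = 7)
summary(fit, contrasts = list(
  sympatric_slope = c(gen_dist = 1, "gen_dist:sympatrysympatric" = 1)))
```
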