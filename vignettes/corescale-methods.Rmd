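---
title: "Methods: finding the optimal sampling percentage of a core collection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: finding the optimal sampling percentage of a core collection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corescale)
```

## The problem

A core collection is a subset of a germplasm bank chosen to retain the
genetic diversity of the whole collection with minimal redundancy. For
quantitative-trait data the open question is *how large* the subset
should be: fixed sampling percentages risk either losing diversity or
keeping redundant accessions. `corescale` implements a simulation-based
strategy for choosing that percentage: build candidate subsets at many
sizes, score how much diversity each retains, model the score as a
smooth function of subset size and trait count, and invert that model at
a diversity threshold.

The pipeline has six stages, each usable on its own:

1. **Genotypic values** (`adjust_genotypic()`): strip environment and
   field-position effects from multi-environment plot observations.
2. **Subset construction** (`ldss_sample()`): least distance stepwise
   sampling (LDSS) under one of six genetic distances.
3. **Evaluation** (`evaluate_core()`): seven statistics comparing a
   subset with its initial collection.
4. **Statistic validity** (`tukey_groups()`, `assess_validity()`):
   homogeneous-population counting to pick the most discriminating
   statistic.
5. **Monte Carlo surface** (`simulate_surface()`): mean statistic over a
   (sampling percentage x trait count) grid.
6. **Formula fit and inversion** (`fit_families()`, `select_formula()`,
   `invert_at_threshold()`): a parametric model of the surface, solved
   for the percentage that attains a target score.

## The observation model and the synthetic generator

Observed plot values follow the additive model

$$Y_{hk(ij)} = \mu + E_h + R_{i(h)} + C_{j(h)} + G_k + GE_{hk} + \varepsilon,$$

with population mean $\mu$, fixed environment effect $E_h$, fixed row
and column effects nested within environment, a random genotypic effect
$G_k \sim (0, \sigma^2_G)$ per accession, a genotype-by-environment
effect $GE_{hk} \sim (0, \sigma^2_{GE})$, and a plot residual
$\varepsilon \sim (0, \sigma^2_\varepsilon)$. `generate_germplasm()`
draws all random terms as (multivariate) normals — the standard
quantitative-genetics assumption, and what the downstream ANOVA-based
tests expect.

Default study conditions are a collection of 168 accessions scored for
20 traits in 2 environments (years) with 2 replications each, on a
6-row x 80-column field per replication. Variance components default to
$\sigma^2_G = 100$, $\sigma^2_{GE} = 10$,
$\sigma^2_\varepsilon = 20$ around trait means of 50 — a plot-level
heritability of roughly 0.77, typical of agronomic traits — with fixed
effect standard deviations of 5 (environment) and 2 (rows, columns) and
a compound-symmetric accession-level trait correlation of 0.2.
Because LDSS exists to remove redundancy, the generator plants
redundancy deliberately: by default 30% of accessions are a donor's
genotype plus jitter with standard deviation 0.5 trait units
(`redundancy_fraction`, `redundancy_jitter`). Fixed-effect draws are
centred (environments over years, rows/columns within each
environment), so they are genuine deviations from $\mu$ and the
noise-free model is exactly identified.

What the generator does **not** emulate: real trial designs (lattices,
blocks), missing plots, trait distributions that are skewed or bounded,
and spatial autocorrelation beyond additive row/column effects. Tests
passing on this generator demonstrate algorithmic correctness and the
qualitative behaviour of the statistics, not performance on any real
crop dataset.

Whether the two replications within a year are separately randomized is
exposed as `independent_replication_layouts` (default `TRUE`, the usual
field practice); row and column *effects* are shared across
replications within a year either way, as the model nests them in the
environment only.

## Genotypic-value adjustment

`adjust_genotypic()` fits, per trait, the fixed-effects model
`value ~ mean + environment + row(environment) + column(environment) +
genotype` by QR least squares with sum-to-zero constraints, and reports
genotypic value = grand mean + genotype effect. One QR decomposition is
shared by all traits. This is deliberately *not* a mixed-model
prediction: no variance components are estimated and no shrinkage is
applied (`method_label = "lsmeans-standin"` records this). Users with
mixed-model genotypic values from dedicated software can feed them in
directly via `run_config(trait_matrix_path = ...)` and skip this stage.

Two identifiability notes. First, adding a constant to every
observation of one environment shifts all genotypic values uniformly by
`c / n_environments` (the grand mean absorbs it); differences between
accessions — all that sampling and evaluation use — are invariant.
Second, exact recovery of the generator truth on noise-free data holds
when every row and column of the field is occupied in each environment;
with partially empty columns the unobserved levels leave a small common
offset, again invisible to every downstream stage.

## Distances and stepwise sampling

Subsets are constructed on the *standardized* collection (z-scores
against the initial collection; sample, i.e. $n-1$, standard
deviations) and evaluated on the *unstandardized* one. Six distances
are available: `euclid`, `seuclid` (Euclidean on z-scores), `mahal`
(reference covariance; pseudo-inverse with a flag when singular),
`cityblock`, `cosine`, and `correlation`. UPGMA (`upgma()`, average
linkage via `stats::hclust`) summarizes the clustering; its first merge
is by construction the globally closest pair, which is exactly the
"least-distance subgroup" LDSS operates on.

`ldss_sample()` repeats: find the closest pair, keep one member
uniformly at random, remove the other, until
`round_half_up(N * p / 100)` accessions remain (half-away-from-zero
rounding, so 6.07% of 168 gives 10; percentages below 2 accessions are
rejected). Ties in the closest pair resolve to the lexicographically
smallest index pair, making runs fully reproducible under a seed.

Scaling parameters (trait standard deviations, covariance) are
estimated once on the initial collection and held fixed during
stepwise deletion, so recomputing distances after a removal is exactly
taking a submatrix — the property that makes the stepwise algorithm
cheap. The alternative reading, re-estimating after every removal, is
available as `reference_policy = "refit"`; on redundant collections the
two differ negligibly because early removals are near-duplicates that
barely move the scale estimates.

Because the removal stream does not depend on the stopping size, one
stepwise run per seed yields the subset at *every* percentage
(`snapshot_percentages`); the test suite verifies snapshot equality
with independent runs. The Monte Carlo stage leans on this.

## Evaluation statistics and their validity

For a subset C of initial collection I over $n$ traits:
MD and VD are the percentages of traits whose mean (pooled-variance
two-sample t-test) or variance (two-sided F-test) differ significantly
at $\alpha$; CR averages $100\,R_C(i)/R_I(i)$ (ranges), VR averages
the coefficient-of-variation ratios, CR\_max and CR\_mea the maximum and
mean ratios, and CR\_min the *inverted* minimum ratio
$100\,\mathrm{Min}_I(i)/\mathrm{Min}_C(i)$. The subset is always
compared against the full initial collection. The test choices (pooled
t, variance-ratio F) are the conventional ones; the source framework
names only "significant difference at 0.05", so the report records
`alpha` and the per-trait p-values for scrutiny.

Ratios with a zero denominator, or whose numerator and denominator
differ in sign (possible for CR\_max/CR\_min/CR\_mea and CV ratios on
synthetic traits spanning zero), are excluded from that statistic's
average and listed in the report's `excluded` field rather than
producing meaningless negative percentages.

Validity is assessed by building many subcores over a percentage grid
(default 10–30% in 1% steps, 4 replicates: 84 constructions per
distance, `sampling_design()`), then counting, per statistic, how many
Tukey letter groups the percentages fall into (`tukey_groups()`). The
compact letter display uses the insert-and-absorb algorithm with groups
sorted by descending mean; its letter sets are exactly the maximal
cliques of the non-significance graph, which the test suite checks
against a brute-force clique enumeration for up to six groups. The
count of distinct letters is the homogeneous-population count: a
statistic that spreads the percentages over more letters discriminates
subset sizes better. On redundant synthetic collections CR reliably
out-discriminates MD/VD, which is why CR is the default `parameter`.
Tukey–Kramer standard errors are used throughout, reducing to Tukey HSD
at equal replication.

## The Monte Carlo surface

`simulate_surface()` replicates the following (default 20 times): draw
one random trait order; for each trait count $k$ use the first $k$
traits of that order (nested prefixes — randomizing the order
homogenizes trait effects while keeping adjacent $k$ cells correlated,
which halves the roughness of the surface in $k$); for each percentage
run LDSS and record the chosen statistic. Replication $r$ uses seed
`base_seed + r`, so cells can be recomputed in any order with identical
results and the whole surface is reproducible. The default grid is
21 percentages x 20 trait counts = 420 cells, each a mean of 20
replicates.

## Formula families, selection, inversion

Twelve parametric families (`formula_families()`) form the hypothesis
space for the surface — from `a + b*x*y` (size 7) to nested
log/rational forms (size 34), with natural logarithms throughout. Sizes
are fixed per-family expression-tree complexities; the reference
constants published with each family serve as the primary starting
values for Levenberg–Marquardt fitting (`minpack.lm::nls.lm`), with
seeded perturbed restarts. Free-form symbolic regression is a
non-goal: the families *are* the model space. Points violating a
family's domain (log of a non-positive number, vanishing denominator)
incur a large penalty residual during fitting, and a family whose best
fit still violates its domain on the data is reported as failed rather
than silently clipped.

`select_formula()` encodes the working selection rule: drop fits with
$R^2$ below 0.70; among the rest keep those whose mean absolute error
is within 20% of the best; choose the smallest size (ties: higher
$R^2$). On the published (size, error, $R^2$) triples of all twelve
candidates this rule reproduces the choice of the compact
four-parameter log family
$f(x, y) = a + b\log(xy - cy - d)$ (family 6, size 15). "Error" is
reported as mean absolute error with RMSE alongside, since the original
fitting engine's objective is not public.

`invert_at_threshold()` solves $f(x, y) = CR^\*$ for the percentage
$x$ at each trait count $y$. Family 6 inverts in closed form,
$x = (e^{(CR^\*-a)/b} + cy + d)/y$; every family can also be inverted
by monotone bracketing + `uniroot` (tolerance 1e-12), and the two
routes agree to better than 1e-6. With the reference constants
(65.90, 5.12, 5.07, 4.24) and $CR^\* = 80$ the optimal percentage
falls from 25.01% at one trait to 6.07% at twenty — the package's
acceptance script recomputes exactly this. Solutions outside the
fitted percentage grid are flagged `extrapolated` (the 6.07% endpoint
lies below the simulated 10% floor; inverting there is an explicit
extrapolation of the fitted model), and thresholds the family cannot
attain yield `defined = FALSE` cells rather than fabricated roots.

## Validation

`compare_treat_ck()` contrasts LDSS subsets ("treat") with uniformly
random ones ("CK") at chosen percentages across seeds; on redundant
collections LDSS dominates on CR at every percentage, and treat CR
rises with percentage. `project_pca()` projects all accessions onto the
first two principal components of the standardized collection
(correlation-scale PCA, appropriate for traits in heterogeneous units),
with component signs fixed by the largest-loading convention so plots
are deterministic; core members are flagged so one can see whether the
subset covers the cloud and its extremes.

## Numerical choices and problem sizes

- Rounding of target sizes: half away from zero, floor of 2.
- Closest-pair ties: lexicographic smallest (i, j); UPGMA ties follow
  `hclust`'s deterministic merge order.
- Degenerate inputs: zero-variance traits stop standardization with the
  trait named; zero-norm / zero-variance accession vectors stop cosine /
  correlation distances; a singular Mahalanobis covariance falls back to
  a flagged pseudo-inverse; all-equal Tukey groups yield a single letter.
- All randomness flows through per-call seeds; package functions
  restore the caller's RNG state.

The shipped test suite and examples run at deliberately desk-scale
sizes — collections of 40–168 accessions, surface grids up to 5 x 6
cells with up to 8 replications, 10–20 seeds for stochastic
comparisons — chosen so the whole suite completes in well under a
minute while still exercising every code path at the full 168 x 20
design where the assertion depends on it.

## Known limitations

- On multivariate-normal synthetic collections the CR surface tends to
  *fall* with trait count at a fixed percentage: joint-distance removals
  trade away single-trait extremes. Real germplasm, with its skewed and
  strongly structured traits, can show the opposite, rising shape. The
  formula families carry signed free parameters precisely so either
  shape fits; which family wins the selection is a property of the data,
  not of the package.
- The least-squares adjustment is unshrunken; with very noisy data BLUP
  or equivalent mixed-model predictions (supplied externally) will give
  more precise genotypic values.
- The evaluation t/F tests compare a subset against the full collection
  that contains it, so their nominal levels are conservative.
- CR and its relatives assume traits on ratio/interval scales;
  qualitative or marker data need diversity-index statistics outside
  this package's scope.
- Inverted percentages below the simulated grid floor inherit the
  model's extrapolation risk; the `extrapolated` flag should be heeded.
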