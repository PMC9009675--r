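---
title: "Multi-trait ideotype selection for multi-environment trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait ideotype selection for multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ideosel implements the analysis chain a plant breeder runs on a
multi-trait, multi-environment yield trial: per-trait mixed models with
REML variance components and BLUPs, the genetic-parameter suite used to
judge each trait's usefulness for selection, and a multi-trait
genotype-ideotype distance index (MGIDI) that ranks genotypes by their
distance, in factor-score space, from an ideal genotype. This vignette is
the package's account of the statistical methods, the choices that were
genuinely open, and what the bundled simulator can and cannot tell you.

## The mixed model

Each trait is analysed separately under

$$ y = X\beta + Zu + e $$

where $y$ stacks the $n = geb$ plot observations ($g$ genotypes, $e$
environments, $b$ blocks per environment), $\beta$ is the $eb$-vector of
fixed environment-by-block cell effects, and
$u = (\alpha_1,\dots,\alpha_g, (\alpha\tau)_{11},\dots,(\alpha\tau)_{ge})'$
holds the random genotype main effects,
$\alpha_i \sim N(0, \sigma^2_g)$, and genotype-by-environment
interactions, $(\alpha\tau)_{ij} \sim N(0, \sigma^2_{ge})$, with
residuals $e \sim N(0, \sigma^2_e I)$. Blocks are fixed (they live inside
$\beta$), genotypes and their interaction with environments are random —
the standard layout when genotypes are a sample of breeding material and
environments are deliberately chosen conditions such as irrigated control
versus drought.

`fit_reml()` estimates the variance components by REML through `lme4`,
with two numerical refinements that matter for reproducibility:

* the optimizer (bobyqa, `rhoend = 1e-10`) is followed by a Newton
  refinement of the profiled REML deviance over the variance ratios,
  using a boundary-aware finite-difference stencil and a shrinking step
  ladder ($h = 10^{-3}, 10^{-4}, 10^{-5}$). Generic optimizers leave
  around $10^{-5}$ relative error in small components because the
  profiled deviance is extremely flat near its optimum; after refinement
  the estimates reproduce the closed-form balanced-ANOVA
  (expected-mean-squares) estimators to better than $10^{-6}$ relative on
  balanced designs, which is also the equivalence the test suite asserts.
* non-negativity is enforced at the boundary, so $\hat\sigma^2 = 0$ is a
  legitimate outcome; a trait whose observations are all identical is
  returned as a degenerate fit (all components zero, all BLUPs zero)
  rather than an optimizer failure.

BLUPs are the conditional means of $u$ given $y$ at the REML estimates.
`blup_means()` reports predicted values: at genotype level the grand mean
(the average of the $eb$ fixed cell effects) plus $\hat\alpha_i$; at
genotype-by-environment level the environment mean plus
$\hat\alpha_i + \widehat{(\alpha\tau)}_{ij}$.

Missing plots are carried as `NA` through ingestion and simply dropped at
the fitting stage — the mixed model handles unbalance natively and
nothing is imputed.

### Hypothesis tests

Random effects are tested by REML likelihood-ratio tests: twice the
log-likelihood difference between the full model and the model without
the term, referred to $\chi^2_1$. The null value of a variance component
lies on the boundary of its parameter space, so the plain $\chi^2_1$
reference (rather than the 50:50 mixture) is conservative; the test
suite's null simulation confirms the empirical size stays below the
nominal 5%.

The environment fixed effect is tested by a maximum-likelihood (not REML)
likelihood ratio — REML likelihoods are not comparable across fixed
structures. One structural subtlety: in the cell-means parametrization
$\beta$ contains one effect per environment-by-block cell, and blocks
nested in environments span the environment contrast, so "dropping the
environment term" from that parametrization changes nothing.
`test_fixed_effects()` therefore compares additive fixed structures
(`~ environment + block` against `~ block`, both with the full random
structure), which yields the natural $e - 1$ degrees of freedom and is
the standard practical choice.

## Genetic parameters

From the variance components, design sizes and grand mean $\mu$,
`genetic_parameters()` reports:

| quantity | formula |
|---|---|
| broad-sense heritability | $\sigma^2_g / (\sigma^2_g + \sigma^2_{ge} + \sigma^2_e)$ |
| mean-basis heritability | $\sigma^2_g / (\sigma^2_g + \sigma^2_{ge}/e + \sigma^2_e/(eb))$ |
| selection accuracy | $\sqrt{h^2}$ of the headline variant |
| genotype-environment correlation | $\sigma^2_g / (\sigma^2_g + \sigma^2_{ge})$ |
| genotypic CV | $100\,\sigma_g / \mu$ |
| residual CV | $100\,\sigma_e / \mu$ |

Both heritability variants are always emitted; the **mean-basis**
(genotype-mean) version is the headline by default because published
selection accuracies in this literature are the square roots of the
printed heritabilities, and that identity holds on the genotype-mean
basis. The genotype-environment correlation has a second common
definition, $\sigma^2_{ge}/(\sigma^2_{ge}+\sigma^2_e)$; it is available
via `rge = "interaction"` since reports are often silent about which was
used. $\mu$ is the grand mean across both environments.

## The genotype-ideotype distance index

`mgidi()` chains four steps on a genotype-by-trait matrix of predicted
means (BLUP-based, across environments — selection is simultaneous for
both conditions; run it per environment if you want condition-specific
rankings):

1. **Rescaling.** Each trait is linearly mapped to $[0, 100]$ so that 100
   is always the desired end: for increase-direction traits the largest
   observed mean maps to 100, for decrease-direction traits the smallest
   does. Every column is an affine image of the original, so the
   correlation structure survives up to sign flips on decrease traits — a
   property the test suite checks exactly. A trait that is constant
   across genotypes (typically because its genotypic variance was
   estimated at the zero boundary and every BLUP shrank to the grand
   mean) carries no ranking information; `mgidi()` drops it from the
   index with a warning but keeps it in the gains table.
2. **Factor analysis.** The correlation matrix $R$ of the rescaled
   matrix is eigen-decomposed; factors with eigenvalue above 1 are
   retained (Kaiser rule; if none qualify, one factor is kept so the
   index remains defined). Initial loadings are eigenvectors scaled by
   the square roots of their eigenvalues; retained loadings are
   varimax-rotated (`rotate = FALSE` gives the unrotated solution), and
   each factor's loading vector is sign-fixed so its largest-magnitude
   entry is positive — rotation and eigenvectors are otherwise only
   defined up to sign, and determinism matters for reproducible reruns.
   Factorial scores follow $F = Z (A^\top R^{-1})^\top$ with $Z$ the
   column-standardized rescaled matrix. A singular $R$ is pseudo-inverted
   with a warning.
3. **Ideotype.** The ideal genotype scores 100 on every rescaled trait.
   The vector $(100,\dots,100)$ is standardized with the genotype
   columns' means and standard deviations and scored with the same $A$
   and $R$ — this is what places it in the same factor-score space as the
   genotypes; distances computed any other way are not comparable.
4. **Index.** $\mathrm{MGIDI}_i = [\sum_{j=1}^f (y_{ij} - y_j)^2]^{0.5}$,
   read as the Euclidean norm over factors (the root of the sum, not a
   sum of roots — the only reading under which the index is a distance).
   Factor contributions are $\omega_{ij} = D_{ij}^2 / \sum_j D_{ij}^2$,
   so each genotype's contributions sum to one, and the *smallest*
   $\omega$ marks the genotype's strength: the factor whose traits are
   already closest to the ideotype.

Selection keeps the $\lfloor \pi g \rfloor$ lowest-index genotypes
(minimum one; ties broken by input order). At the conventional
$\pi = 0.25$ with 18 genotypes that is exactly 4. Selection differentials
are computed on the original trait scale: $X_s - X_o$ and
$100\,(X_s - X_o)/X_o$, with the gain flagged as goal-met when its sign
agrees with the trait's desired direction.

## The exploratory layer

`pearson_matrix()` gives product-moment correlations between trait means
with two-sided p-values from the $t$ reference on $n-2$ df — no
multiple-testing correction, matching the plain annotated-correlogram
practice; flags at 5% and 1% are supplied. `pca_traits()`
eigen-decomposes the correlation (or covariance) matrix of the
genotype-by-environment BLUP-mean matrix, reporting percent variance per
component and squared-loading contributions; `variable_contributions()`
aggregates them over the leading components, weighted by eigenvalue.

## The simulator and what it does (not) emulate

`simulate_met()` draws data from exactly the model the fitter assumes:
per-trait grand means, fixed environment and block-within-environment
effects, Normal genotype effects correlated across traits through a
genetic correlation matrix $K$, Normal genotype-by-environment effects
drawn independently per trait (the simplest structure consistent with
the univariate fits), and Normal residuals. A lower-triangular square
root of $K$ combines per-trait substreams whose seeds are derived
arithmetically from the root seed, so the same seed is bit-reproducible
and adding a 13th trait does not perturb the first 12.

`preset_wheat_drought()` encodes the study conditions the package is
tested under: 18 wheat genotypes, irrigated control versus drought,
three blocks, 12 traits (grain yield, hectolitre weight, initial/final
net photosynthesis and stomatal conductance, proline, Na, K, total
phenolics, and the ABTS and FRAP antioxidant assays; lower values
desired for Na and both conductances). Its grand means are the published
overall trait means and its variance components are back-calculated from
published mean-basis heritabilities and genotypic/residual CVs — three
targets that determine $(\sigma^2_g, \sigma^2_{ge}, \sigma^2_e)$
exactly. The published genotype-environment correlations cannot then be
matched simultaneously (the printed parameter set is overdetermined with
respect to a three-component model), so they fall where they fall.
Environment shifts are plausible drought responses (e.g. yield down
~15%, proline up severalfold), block gradients are $\pm 0.3$ residual
SD, and the genetic correlation is 0.6 within four published trait
groupings and zero between — enough structure for the factor analysis to
find meaningful groups at realistic sample sizes.

What the simulator does **not** emulate: spatial field trends, multi-year
structure, non-Normal or heavy-tailed effects, dominance or epistasis,
missing-plot mechanisms, and trait-specific interaction correlations. A
passing test suite therefore shows that the chain recovers what it
assumes, at the stated design sizes — not that those assumptions hold in
any particular field trial.

Two statistical facts about the preset are worth knowing. At $g = 18$,
REML estimates of small genotypic variances frequently hit the zero
boundary; the pipeline then drops the fully-shrunk trait from the index
(with a warning) and reports a zero differential for it. And a
mean-basis heritability observed on one simulated dataset scatters
substantially around its generating value — single-trial estimates of
$h^2$ at this size are noisy, which is exactly why the recovery tests
average over 200 replicates.

## Problem sizes and runtimes

The test suite exercises: balanced-ANOVA equivalence on $6 \times 2
\times 3$ toys; variance-component recovery over 200 simulated trials at
$g = 18$ (relative bias under 15%); the interaction LRT's null size over
500 replicates; planted-ideotype recovery in 100 random instances;
brute-force ranking equivalence at $g \le 10$; and exact
published-arithmetic reproductions. These sizes keep the whole suite
around a minute on one core while leaving Monte-Carlo noise well inside
the asserted margins.

## Known limitations

* Variance components are per-trait; no multivariate REML, so genetic
  correlations are used only generatively (simulation), not estimated.
* The LRT for random effects uses the conservative plain $\chi^2_1$;
  power-sensitive users may prefer the boundary mixture.
* The index inherits the factor model's instabilities: with $g$ barely
  above the trait count, loadings — and hence factor membership — can
  rotate between nearby datasets even when the ranking is stable.
* No economic weighting of traits and no restricted/desired-gains
  variants of the index.
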