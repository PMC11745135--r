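---
title: "Phylogenetic allometry and size prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic allometry and size prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scorpsize)
```

This vignette documents the statistical machinery behind `scorpsize`:
the models, their assumptions, the tunable parameters, and the design
choices made where more than one reasonable option existed.

## The allometric prediction model

Size prediction rests on the classical allometric relationship between a
body part `x` and a body-size measure `Y`, linear on the log scale:

\[ \ln Y = a + b \,\ln x \quad\Longrightarrow\quad Y = e^{a} x^{b}. \]

Predictions back-transform with a plain exponential, matching the
published form of the equations. No smearing (log-normal bias)
correction is applied: the bundled coefficients were estimated on the
log scale and the exponential of the posterior-mean linear predictor is
the quantity the equations define. A smearing factor would change
predictions by roughly half the residual variance on the log scale
(well under 1% here) and would no longer reproduce the printed
equations.

Coefficients are stored at the two-decimal precision at which they were
published; coefficient sets fitted in-package keep full precision and
are interchangeable everywhere a bundled set is accepted.

## The phylogenetic mixed model

Coefficients are estimated from species means (one record per species
and sex) with the linear mixed model

\[ y = X\beta + u_{\text{phylo}} + u_{\text{species}} + e, \]

where \(u_{\text{phylo}} \sim N(0, \sigma^2_p C)\) with \(C\) the
Brownian-motion tip covariance of the time-calibrated tree (shared
root-to-ancestor path lengths), \(u_{\text{species}} \sim N(0,
\sigma^2_s I)\) a species-level intercept shared by a species' two sex
records, and \(e\) i.i.d. record-level noise. Priors are diffuse normal
(variance \(10^{10}\)) on fixed effects and weak inverse-gamma
(\(V = 1\), \(\nu = 0.002\)) on each variance component; one test
verifies that strengthening \(\nu\) tenfold moves the slope posterior by
less than one posterior standard deviation.

Sampling is plain Gibbs — every full conditional is conjugate — with one
structural choice that matters: **the fixed effects and the phylogenetic
effect are drawn as a single Gaussian block**, with
\(u_{\text{phylo}}\) parameterised in the eigenbasis of \(C\). When a
predictor is itself phylogenetically structured (which is the rule for
allometric data: the predictor is a body part evolving along the same
tree), \(\beta\) and \(u_{\text{phylo}}\) are strongly correlated a
posteriori, and alternating one-at-a-time updates crawl along the
resulting ridge; effective sample sizes for slopes drop to single
digits and credible intervals computed from such a chain are
meaningless. The joint block restores near-independent slope draws at
the cost of one Cholesky factorisation of a \((p + n)\)-dimensional
precision matrix per iteration.

The reference MCMC schedule is a single chain of 50,000 iterations,
burn-in 5,000, thinning 50 — exactly 900 retained draws. Summaries
report posterior means, quantile-based 95% credible bounds, spectral
effective sample sizes (AR-fit estimator), and `pMCMC` — twice the
smaller posterior tail probability of a coefficient's sign, floored at
one over the retained draw count — for fixed effects, with 0.05 as the
significance threshold for sex-interaction tests.

Model quality is compared by the root-mean-square error of
back-transformed predictions in millimetres, over all species-sex
records, using posterior-mean fixed effects only. Random-effect BLUPs
are deliberately excluded: the published prediction equation carries
fixed effects only, and RMSE is meant to measure what that equation
achieves on its training data.

### Identifiability and its limits

With exactly two records per species, \(u_{\text{phylo}}\) and
\(u_{\text{species}}\) both act at the species level and their variance
components are only weakly separated (by the off-diagonal structure of
\(C\)). This is accepted: the variance split is not a quantity the
package reports as a result, and slopes and intercepts — which the
prediction equations use — are insensitive to it. An independent
maximum-likelihood estimator (`fit_pgls_ml`, profiling the fixed effects
by GLS inside a numeric optimisation of the three variance components)
serves as a cross-check; the test suite requires Gibbs posterior means
and ML estimates to agree within two posterior standard deviations
across simulated datasets.

Two practical caveats surfaced by the synthetic experiments are worth
recording. First, *degenerate data* — species means with no record-level
noise at all — drive \(\sigma^2_e\) to zero and pin the 392 random
quantities against 390 observations; the chain then explores a thin
slice of the ridge and interval calibration fails. Real species means
always carry measurement noise, and the recovery tests draw data from
the model's own generative process. Second, *predictor measurement
error*: species means computed from two noisy individuals carry noise in
the predictor, and because GLS weights phylogenetic contrasts by branch
length, the short-branch contrasts with the worst signal-to-noise get
the highest weight — slope attenuation is therefore stronger than the
naive cross-species noise ratio suggests (about 10% under the default
generator settings). This errors-in-variables effect is a property of
the method, not of this implementation; it is why parameter-recovery
checks must separate sampler calibration (predictor observed exactly)
from pipeline behaviour on noisy means.

## Phylogenetic PCA under Pagel's lambda

The trait covariation structure is summarised by principal components of
the *evolutionary* covariance matrix. With \(C(\lambda)\) the tree
covariance whose off-diagonals are scaled by Pagel's \(\lambda\):

- \(\lambda\) is estimated by maximising the joint multivariate Brownian
  likelihood over all traits, with the GLS mean vector and the full trait
  covariance \(R\) concentrated out at their ML values; the
  one-dimensional search runs on \([0, 1]\) to tolerance \(10^{-6}\)
  (values above 1 can break positive definiteness on ultrametric trees).
  Collinear trait columns are dropped from the \(\lambda\) search only —
  they make \(R\) singular and carry no additional information about
  \(\lambda\).
- the ancestral mean is the GLS mean
  \(\mu = (1'C^{-1}X)/(1'C^{-1}1)\);
- \(R = (X-\mu)'C^{-1}(X-\mu)/(n-1)\) is eigendecomposed; scores are
  \((X-\mu)V\) and loadings are evolutionary correlations,
  \(V_{tk}\sqrt{\ell_k}/\sqrt{R_{tt}}\).

Covariance mode (not correlation mode) is used on log-scale traits: the
log transform already places all measurements on a common relative
scale, and covariance mode preserves the interpretation of eigenvalues
as evolutionary variances. The sign of a principal axis is arbitrary;
axes are oriented so the largest-magnitude loading is positive, so
published tables whose first axis is all-negative correspond to the same
result reflected, and comparisons should use absolute loadings. On a
star phylogeny the procedure reduces exactly to ordinary PCA, which the
test suite verifies to \(10^{-8}\), and results match an independent
implementation (`phytools::phyl.pca`) to the \(\lambda\)-search
tolerance.

## Phylogenetically informed imputation

Missing trait cells are completed per sex with the missForest algorithm
on top of `randomForest` (100 trees, default feature subsampling,
maximum 10 passes): initialise missing cells with column means, then
cyclically re-fit each incomplete column on all other columns — plus the
first 10 principal-coordinate eigenvectors of the tree's cophenetic
distance matrix, which inject phylogenetic structure — and stop at the
first increase of the normalised change in imputed values, returning the
previous iteration. Observed cells are never modified (asserted
bitwise in tests). Ten eigenvectors follow the established default for
eigenvector-based phylogenetic imputation; the eigenvectors are computed
once from the tree, since they carry no trait information and need no
per-replicate refresh.

Accuracy is assessed by the masked-reimputation protocol: on a
complete-case matrix, mask 13% of each trait column uniformly at random
within each sex (13% being the largest per-trait missingness rate
observed in the kind of compiled trait matrices this emulates), impute,
and score the normalised root-mean-square error

\[ \mathrm{NRMSE} = \sqrt{\frac{\langle (x_{\text{true}} -
x_{\text{imp}})^2 \rangle}{\langle (x_{\text{true}} -
\bar x_{\text{true}})^2 \rangle}} \]

over the masked cells (population moments; 0 = perfect). Masking is
applied per trait column rather than globally, so every trait is
stressed at the same rate. The protocol masks on the mm scale,
log-transforms, imputes, back-transforms and scores on the mm scale —
the order real use follows. NRMSE is scale-equivariant, so this choice
affects only which cells dominate within a trait, not the statistic's
meaning.

## The synthetic-data generator

`allometry_scenario()` fixes the study conditions under which the
pipeline is exercised:

| parameter | default | rationale |
|---|---|---|
| `n_species` | 195 | comparative study scale for a species-rich family |
| `birth_rate` | 0.05 / My | pure-birth crown age near 100 My |
| `sigma2_size` | 0.0015 / My | tip SD of ln toL near 0.37 (CV ~ 0.4) |
| `root_size_mm` | 50 | mid-range adult buthid total length |
| trait slopes / intercepts | inverted bundled sets | realistic allometry mirroring the published coefficient magnitudes |
| `sigma2_resid` | 2e-4 / My | trait-specific residual well below the size signal |
| `sex_offset` | -0.06 x slope | modest male-smaller dimorphism lying on the allometric line |
| `individual_sd` | 0.03 | ~3% measurement/individual variation |
| `n_individuals` | 2 | typical per-sex sample in compiled trait tables |
| `missing_fraction` | 0.13 | highest per-trait missingness rate the validation protocol stresses |

The generator produces a pure-birth ultrametric tree, a latent
\(\ln(\text{toL})\) evolving by Brownian motion (latent size *is* the
log of total length, mirroring the use of toL as the size proxy), traits
that scale log-linearly with size plus independent Brownian residuals,
additive log-scale sex offsets, lognormal individual noise, and MCAR
missingness that removes all individuals of a species-sex-trait cell.
Missingness is MCAR because the validation protocol itself masks at
random; nothing is claimed about informative missingness. Responses
(`toL`, `carL`) are never masked.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: empirical tree shape and clade ages,
taxonomically structured (non-random) missingness, correlated residuals
among traits beyond the shared size axis, literature measurement error
beyond i.i.d. lognormal noise, and unequal individual counts across
species.

## Numerical choices and conventions

- Ultrametricity tolerance: relative \(10^{-6}\) of tree depth.
- Principal-coordinate axes are scaled by \(\sqrt{\text{eigenvalue}}\)
  and sign-fixed (largest-magnitude coordinate positive); negative
  eigenvalues are dropped (tree distances, being ultrametric, never
  produce them).
- Lognormal calibration priors are solved in closed form — the two
  quantile conditions are linear in `meanlog`/`sdlog` on the log scale —
  rather than numerically; round-trip accuracy is \(10^{-8}\) or better
  by construction.
- Species means are computed on raw mm and then logged (not
  mean-of-logs), matching the pipeline order of the compiled data this
  emulates; means are unweighted.
- Predictor ranking breaks RMSE ties alphabetically for reproducibility.
- A duplicated secondary predictor falls back to the single-predictor
  model with a warning; near-collinear pairs (|r| > 0.999) warn.
- Test and acceptance problem sizes (50-195 species, chains of
  1,000-4,000 retained draws for synthetic recovery, the full 50,000
  schedule for bookkeeping) were chosen as the smallest sizes at which
  the checked properties are stable; they are package choices, not
  statements about the method's limits.

## Known limitations

- Predictions assume adult, morphologically typical specimens within the
  size range the coefficients were estimated on; extrapolation to very
  large non-buthids or fossils inflates error.
- The bundled equations carry no calibrated predictive uncertainty; the
  envelope from coefficient bounds ignores residual variance and
  coefficient correlation and is labelled accordingly.
- Slope estimates from species means of few individuals are attenuated
  by predictor measurement error (see above); users fitting new data
  with very noisy predictors should expect slopes biased toward zero.
- Variance components are reported but not interpretable individually
  under the two-records-per-species design.
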