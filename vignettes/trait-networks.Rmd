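---
title: "Separating and learning genomic and residual trait networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating and learning genomic and residual trait networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In multi-trait panels of inbred (doubled-haploid, DH) lines, the covariance
between traits mixes two very different sources: genetic covariation
(pleiotropy, linkage disequilibrium) and residual covariation (shared
micro-environment, physiological dependencies, non-additive effects).
`traitnets` separates the two and asks, for each source independently,
*which traits are directly connected* — not merely correlated — by learning
a Gaussian Bayesian network (BN) for each component and then stress-testing
the learned structures inside structural equation models (SEMs).

The workflow has three stages:

1. **Decomposition.** A Bayesian multivariate kinship model ("MTM") is
   fitted by Gibbs sampling to the n x d panel: \(y = \mu \otimes 1_n + u +
   e\) with \(u \sim N(0, G \otimes K)\), \(e \sim N(0, R \otimes I)\),
   where K is a marker-based simple-matching kinship matrix and G, R are
   the d x d genomic and residual covariance matrices with inverse-Wishart
   priors.
2. **Decorrelation and structure learning.** BN learning assumes
   independent rows. Residuals are independent across genotypes by model
   assumption; the fitted genomic values are not, so they are transformed
   with the Cholesky factor \(K = LL'\): \(u^* = (I \otimes L^{-1})u\),
   which removes cross-genotype correlation while preserving G. Six
   settings are then run on each component: Grow-Shrink under four
   conditional-independence tests (correlation/exact-t,
   correlation/permutation, Gaussian mutual information/\(\chi^2\), mutual
   information/permutation) and tabu search under BIC and BGe, each
   averaged over bootstrap resamples of genotypes with an arc-strength
   significance threshold.
3. **Assessment.** Each distinct learned structure is translated into a
   strictly-lower-triangular structure matrix \(\Lambda\) and embedded in a
   recursive SEM in which \(G\) and/or \(R\) is replaced by
   \((I-\Lambda)^{-1}\Psi(I-\Lambda)^{-T}\) with diagonal innovation
   variances \(\Psi\). Models are ranked by DIC, a plug-in marginal
   log-likelihood, and replicated cross-validated predictive ability
   against the unstructured MTM and a single-trait baseline.

## Priors and their parametrization

All covariance priors are fixed in the parametrization with density
\(\propto |W|^{-(\nu+d+1)/2}\exp(-\mathrm{tr}(\Sigma W^{-1})/2)\), whose
mode is \(\Sigma/(\nu+d+1)\). This is the unique convention under which the
package defaults \(\nu = 8\), \(\Sigma = 7I\) put the prior mode of every
trait variance at 0.5 for d = 5 standardized traits, and whose d = 1
special case is the scaled-inverse-\(\chi^2\) with mode
\(\mathrm{scale}/(\nu+2)\) — so the single-trait baseline's df 4 / scale 3
priors also have mode 0.5. SEM structure coefficients get zero-mean normal
priors; the default variances 6.3 (genomic) and 0.07 (residual) are chosen
so that covariance components as large as 5.0 and 0.52 respectively lie
within two prior SDs (`coeff_prior_floor()`: \((5/2)^2 = 6.25\),
\((0.52/2)^2 = 0.0676\)).

## The samplers

The MTM Gibbs sampler cycles flat-prior intercepts, genomic values,
and the two covariance matrices. The genomic-value update exploits the
eigendecomposition \(K = QDQ'\): rotating the phenotypes by \(Q'\)
decouples genotypes, so each iteration costs n independent d x d solves
(vectorized through a simultaneous diagonalization of \(R^{-1}\) and
\(G^{-1}\)) instead of one nd x nd system. `G | u` is inverse-Wishart
\((\Sigma_G + U'K^{-1}U,\ \nu_G + n)\) and `R | e` inverse-Wishart
\((\Sigma_R + E'E,\ \nu_R + n)\). Kinship matrices that fail a Cholesky
factorization are repaired by ridge doubling from 1e-8 (logged; the ridge
used is recorded on the transform object).

The SEM sampler extends the same cycle: the current genomic draw is
decorrelated through the fixed Cholesky factor, the free coefficients of
\(\Lambda\) are drawn child-by-child from Gaussian full conditionals
(regression of the component on its parents with the fixed-variance normal
prior), \(\Psi\) from scaled-inverse-\(\chi^2\) full conditionals, and the
reconstructed \(G^*\) (and/or \(R^*\)) replaces \(G\) (\(R\)) in the other
updates. The structured layer is thus a hierarchical prior on the
covariance matrix; structural zeros are never touched and remain exactly
zero. The update order is one valid Gibbs realization among several; it is
validated by simulation-based calibration (below).

Chain defaults mirror a full production run (burn-in 30,000; 300,000
draws; thinning 2). The package's own tests and examples use short chains
(hundreds to a few thousand retained draws) at n between 50 and 800 —
problem sizes chosen so that each check isolates one property with
adequate Monte-Carlo resolution.

## What the synthetic generator emulates — and what it does not

`simulate_markers()` builds DH marker panels from family-specific allele
frequencies (Beta(2, 2)) with Bernoulli genotypes coded {0, 2}: this
creates the block-structured kinship of multi-family DH panels without
modeling meiosis, linkage maps, or testcrosses. `kinship_from_markers()`
uses raw proportion simple matching (any affine rescaling of K only
rescales genomic variance estimates). `simulate_panel()` draws genomic and
residual components from known sparse structure matrices through
\((I-\Lambda)^{-1}\) and stores the true components next to the phenotypes.
The default five-trait truth uses 4 genomic arcs (coefficients 0.7–0.9 in
magnitude) and 3 residual arcs (0.45–0.65) with all innovation variances
0.5 — the coefficient range that reproduces the moderate-to-strong trait
correlations of real DH panels on standardized traits.

Passing tests on these panels show that the pipeline recovers structures
*when the generating process is exactly the assumed Gaussian recursive
model*. Real data add model misspecification (non-Gaussian traits,
genotype-by-environment leakage into residuals, LD structure in K) that the
generator deliberately omits; structure recovery rates on real panels will
be lower, which is exactly why the SEM assessment stage exists.

A note on simple matching: with intermediate allele frequencies, the
expected matching proportion between unrelated lines is well above zero
(~0.6 under Beta(2, 2)), so K has a large shared component. This weakens
the separation between the intercept and a genotype-common genomic term
and is the main driver of slow mixing of G in the sampler — a property the
real panels share.

## Numerical and design choices

* **Correlations** are computed per retained draw and then averaged; SDs
  across draws use denominator n − 1. (The alternative — correlations of
  the averaged covariance — differs only at third order.)
* **CI tests**: partial correlations come from the inverse of the
  correlation submatrix; the permutation variants permute the raw x column
  and use the +1-corrected p-value, so permutation p-values are never 0.
  Collinear pairs (|r| = 1 within 1e-12) are flagged with an infinite
  statistic and p = 0.
* **Grow-Shrink**: Markov blankets are symmetrized with the AND rule;
  neighbor resolution searches separating subsets of the smaller blanket;
  colliders are oriented when the midpoint is outside the recorded
  separating set; propagation uses the three standard orientation rules
  (sufficient without background knowledge). Output may be an equivalence
  class (undirected edges).
* **Scores**: BIC counts |pa| + 2 parameters per node (coefficients,
  intercept, residual variance), sign chosen so larger is better. BGe uses
  imaginary sample sizes 1 (mean) and d + 2 (precision), prior mean equal
  to the sample mean, and identity-proportional prior scale
  \(t = \alpha_\mu(\alpha_w - d - 1)/(\alpha_\mu + 1)\); the node-wise
  form is validated in the tests against the closed-form joint
  normal-Wishart marginal likelihood of the complete DAG, and score
  equivalence across Markov classes is asserted to 1e-8 for both scores.
* **Tabu search** uses add/delete/reverse moves, a structure-keyed tabu
  list (default length 10, which also bounds the tolerated non-improving
  streak), and canonical move order for deterministic tie-breaks.
* **Bootstrap averaging** resamples genotypes jointly across traits. The
  inclusion threshold is the L1-minimizing step-function fit to the
  empirical CDF of arc strengths (the Lebesgue median of the CDF, then a
  type-1 quantile); arcs strictly above the threshold are kept (with the
  degenerate all-strength-1 case included explicitly). Undirected edges
  contribute half to each orientation. Direction ties break toward the
  earlier trait in canonical order; any cycle arising from majority
  orientation is broken by removing the weakest arc in the cycle (logged).
* **Equivalence-class representative** for SEM translation: the consistent
  extension whose sorted arc list is lexicographically first.
  Representatives of one class share fit and likelihood, so ranking is
  unaffected.
* **DIC** uses the conditional deviance \(-2\log N(y\,|\,\mu + u, R\otimes
  I)\) per draw: its effective-parameter count is of the order of the
  dimension of u, matching the magnitude expected for these models. The
  marginal log-likelihood is a deterministic plug-in evaluation at
  posterior means of \(N(\mu\otimes 1,\ G\otimes K + R\otimes I)\) — not
  an evidence estimate; only differences between models fitted to the same
  data are interpreted. Both choices are deliberate substitutes for
  estimators that admit many variants, and both are config-visible.
* **Cross-validation** uses uniform random fold assignment of genotypes
  (no family stratification), derived from the master seed, and the
  identical assignments for every model. Held-out genotypes are predicted
  from the conditional multivariate normal given all training phenotypes,
  which is what gives multi-trait models their advantage.
* **Seeds**: one master seed is expanded into independent substreams per
  stage (`derive_seeds()`), so stages are independently reproducible and
  two runs with one seed are byte-identical.

## Validation strategy

Beyond unit oracles (hand Cholesky factors, brute-force kinship,
closed-form GLS/BLUP for the d = 1 fixed-variance sampler, exhaustive DAG
enumeration at d ≤ 4), the samplers are checked by prior-predictive
simulation-based calibration (`prior_predictive_check()`): parameters
drawn from the prior, data from the model, and the rank of each true
covariance entry within its posterior draws tested for uniformity. The
intercept is held at zero during calibration because its prior is
improper (flat), which would make the joint prior-predictive undefined.

## A known limitation: saturated SEM vs MTM

With fully recursive structures on both components, \(G^*\) and \(G\) have
identical parameter counts (10 connections, 15 nonnull entries at d = 5)
and the two models share one likelihood parametrization. Their
*posteriors*, however, are not identical: the inverse-Wishart on G implies
its own Bartlett-type shrinkage of the recursive coefficients (prior
variance on the order of \(\psi/7\) under the defaults), which differs
from the SEM's fixed-variance normal priors, and the latent u/e
decomposition leaves directions that n = 800 genotypes do not fully
identify. Replicated long chains show chain-to-chain agreement near 0.003
per model while the two models' posterior means differ by up to ~0.2 per
covariance entry on high-baseline-relatedness kinship. The package
reports this honestly: the parameter-count equivalence is asserted
exactly; the posterior agreement check is run at its stated tolerance and
can fail on panels where the kinship leaves G weakly identified. Matching
the two priors exactly (a Bartlett-decomposed inverse-Wishart prior for
the SEM) is possible but would leave the SEM's stated prior family.

## Worked example

```{r, eval = FALSE}
library(traitnets)

truth <- default_truth()
markers <- simulate_markers(300, 1000, 10, seed = 1)
K <- kinship_from_markers(markers)
panel <- standardize_panel(
  simulate_panel(truth, K, seed = 2, family_ids = markers$family_ids))

fit <- fit_mtm(panel, K, mcmc = mcmc_settings(500, 3000, thin = 2, seed = 3))
posterior_correlations(fit)

Ustar <- decorrelate(fit$U_hat, cholesky_factor(unclass(K)))
avg <- bootstrap_average(as.data.frame(Ustar), learner_setting("tabu1"),
                         B = 100, seed = 4)
avg$averaged
autoplot(avg)

spec <- sem_spec(structure_genomic = to_structure_matrix(avg$averaged))
sem <- fit_sem(panel, K, spec, mcmc = mcmc_settings(500, 3000, thin = 2, seed = 5))
rank_models(dplyr::bind_rows(
  fit_metrics(fit, panel, K, "MTM"),
  fit_metrics(sem, panel, K, "SEM G*")))
```

Or, end to end with artifacts on disk:

```{r, eval = FALSE}
cfg <- run_config(out_dir = "run1", seed = 1, n_lines = 300,
                  settings = c("gs3", "tabu1"), bootstrap_B = 100,
                  mcmc_mtm = mcmc_settings(500, 3000, 2),
                  mcmc_sem = mcmc_settings(500, 3000, 2))
res <- run_pipeline(cfg)
res$comparison
```
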