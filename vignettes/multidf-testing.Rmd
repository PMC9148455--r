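---
title: "Multiple degree of freedom testing in repeated-measures RNA-seq: models, simulation design, and evaluation"
author: "mdseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple degree of freedom testing in repeated-measures RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdseq)
```

## The problem

Longitudinal bulk RNA-seq studies collect repeated samples from the same
subjects — for example, blood drawn from patients at several timepoints after
an intervention, with subjects split across two treatment groups. Two features
make per-gene inference awkward in such designs. First, counts from the same
subject are correlated, so ordinary GLM machinery understates uncertainty.
Second, the interesting questions are usually *joint*: "does this gene change
at **any** timepoint?", "does the time course **differ** between groups?".
Each of these is a multiple degree of freedom (DF) hypothesis — several linear
constraints on the coefficient vector tested at once — and the quality of the
resulting gene lists depends on how well each modelling approach calibrates
those joint tests.

`mdseq` provides (i) a synthetic-data generator with the full statistical
structure of such a study, (ii) four correlated-data estimation methods
implemented from their defining equations, (iii) the four standard joint
hypotheses with the matching test machinery, and (iv) an evaluation harness
that turns per-gene results plus simulation truth into FDR, power and
convergence summaries averaged over replicate datasets.

## Generative model

For gene $g$, subject $i$ and observation $j$,

$$Y_{gij} \sim \mathrm{NB}(\mu_{gij}, \alpha_g), \qquad
\mathrm{Var}(Y_{gij}) = \mu_{gij} + \alpha_g \mu_{gij}^2,$$

$$\log(\mu_{gij}) = \beta_{g0} + \beta_{g1} X_{1i}
 + \sum_{t=2}^{4} \beta_{g,t} X_{tij}
 + \sum_{t=2}^{4} \beta_{g,t+3} X_{1i} X_{tij} + b_{gi},
 \qquad b_{gi} \sim N(0, \sigma^2_g),$$

where $X_{1i}$ indicates the treatment group and $X_{tij}$ the timepoint.
The design is two groups of `n_per_group` subjects with four observations
each. Null genes have all non-intercept coefficients zero; 20% of genes are
differentially expressed through the interaction coefficients
$(|\beta_{g5}|, |\beta_{g6}|, |\beta_{g7}|) = (1/3,\; 2/3,\; 1)$ on the
natural-log scale — a time trend in the treatment group that is absent in the
control group.

The four joint hypotheses (`contrast_matrix()`) are:

| test | null hypothesis | rank |
|---|---|---|
| `between` | no group difference at any timepoint: $\beta_1 = \beta_1+\beta_5 = \beta_1+\beta_6 = \beta_1+\beta_7 = 0$ | 4 |
| `within` | no change over time in the treatment group: $\beta_2+\beta_5 = \beta_3+\beta_6 = \beta_4+\beta_7 = 0$ | 3 |
| `interaction` | $\beta_5 = \beta_6 = \beta_7 = 0$ | 3 |
| `global` | $\beta_1 = \dots = \beta_7 = 0$ | 7 |

The within-subject null is often written with the pairwise timepoint
differences appended; those extra equalities are linear combinations of the
three listed, so the rank-3 matrix with an identical null space is tested (a
full-row-rank requirement of the Wald/F machinery). The `within` test accepts
`within_group = "reference"` for the control-group version, since which group
is "the" group of interest depends on the coding of a real dataset.

## Gene-parameter surrogate distribution

Each gene needs a triplet (mean CPM, dispersion $\alpha_g$, random-intercept
variance $\sigma^2_g$). Real repeated-measures triplet tables can be plugged
in via `empirical_param_dist()` (a TSV with columns `mean_cpm`, `dispersion`,
`sigma2_b`, resampled with replacement). The built-in surrogate
(`surrogate_param_dist()`) draws:

* $\log_2(\text{mean CPM}) \sim N(3, 2^2)$, truncated at CPM $> 0.1$ —
  a realistic spread of expression over ~4 orders of magnitude;
* $\alpha = (0.05 + 2/\mu)\,e^{\varepsilon}$, $\varepsilon \sim N(0, 0.4^2)$ —
  the familiar decaying mean–dispersion trend of bulk RNA-seq with an
  asymptote of 0.05 and gene-level scatter;
* $\sigma^2_b \sim \mathrm{LogNormal}(\log 0.2,\; 0.8^2)$ — subject-level
  intraclass correlations spanning weak to strong.

Drawn CPMs are rescaled to sum to one million and the intercept is
$\beta_{g0} = \log(\text{scaled CPM} \times 25\times 10^6 / 10^6)$, i.e. the
log expected count under a common 25-million-read library. Two consequences
of this rule are worth knowing. With fewer genes than a full transcriptome
(this package's evaluation runs use 2,000 rather than ~15,000), rescaling to
one million inflates each gene's share, so per-gene counts are higher than in
a 15,000-gene run; and because every sample targets the same total, library
sizes are nearly constant (an optional per-sample Uniform(0.7, 1.3) factor
can be enabled through `simulate_dataset(lib_size_factors = ...)`).

The sign of the DE effects is one Rademacher draw per gene applied to all
three interaction coefficients (`effect_sign_rule = "joint"`), keeping each
DE gene's time trend monotone in direction; `"independent"` draws a sign per
coefficient. Filtering mirrors a standard expression filter: genes are kept
if CPM exceeds 1 in at least `n_per_group` samples (the size of one
group-by-timepoint cell), computed before any model is fitted.

What the generator does *not* emulate: time-decaying (autoregressive)
within-subject correlation — the single random intercept gives compound
symmetry; varying numbers of timepoints per subject; batch effects; and gene–
gene correlation. Passing tests under this generator therefore demonstrates
correct calibration under compound symmetry, not robustness to misspecified
correlation structures.

## The four estimation methods

**LMM on variance-stabilized counts** (`fit_lmm_reml()`). Counts are divided
by median-of-ratios size factors (`median_ratio_size_factors()`) and passed
through a closed-form variance-stabilizing transformation derived from a
robustly fitted dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$
(`fit_dispersion_trend()`, `vst_transform()`): the antiderivative of
$1/\sqrt{(1+a_1)\mu + a_0\mu^2}$, affinely calibrated so large counts map to
$\approx \log_2$. A gaussian random-intercept model is then fitted by REML,
profiling the variance ratio $\gamma = \sigma^2_b/\sigma^2_e$; one criterion
evaluation uses the Woodbury identity per subject, so no $N \times N$ matrix
is ever formed. Joint tests use the F statistic with Satterthwaite
denominator DF (`satterthwaite_df()`): per contrast,
$\nu = 2(l^\top C l)^2 / \mathrm{Var}(l^\top C l)$ with the variance from the
delta method over $(\sigma^2_b, \sigma^2_e)$ and their REML covariance (twice
the inverse Hessian of the $-2\ell_R$ surface); multi-row contrasts are
combined through the eigendecomposition of $L C L^\top$ and the
moment-matching rule $2E/(E-q)$.

**NBMM-AGQ** (`fit_nbmm_agq()`). The NB random-intercept marginal likelihood
integrates each subject's intercept by adaptive Gauss–Hermite quadrature
centred at the posterior mode (Newton mode-finding on a strictly concave
one-dimensional surface; `n_nodes = 1` is exactly the Laplace approximation,
and 11 nodes is the default). The likelihood and its box-constrained
quasi-Newton maximization over $(\beta, \log\alpha, \log\sigma^2_b)$ run in
compiled code with warm-started modes. Joint tests are likelihood-ratio
tests: the reduced model under $H_0: L\beta = 0$ is obtained by
reparameterizing the design onto a null-space basis of $L$ (the between and
within hypotheses are not coordinate-dropping in reference coding), and the
statistic $2(\ell_{\text{full}} - \ell_{\text{reduced}})$ is referred to
$\chi^2_{\mathrm{rank}(L)}$.

**NBMM-PL** (`fit_nbmm_pl()`). Pseudo-likelihood: the GLMM is iteratively
linearized into a weighted LMM on the working response
$z = \eta + (y-\mu)/\mu$ with weights $\mu/(1+\alpha\mu)$, where $\mu$ is the
conditional mean using current BLUPs; $(\beta, \sigma^2_b)$ come from the
weighted REML fit and $\alpha$ from matching the conditional Pearson
chi-square to its degrees of freedom (a derivative-free moment update,
bracketed and solved by `uniroot`). Convergence requires a relative change
below $10^{-8}$ in $(\beta, \sigma^2_b, \alpha)$ within 200 outer iterations.
Because the final iterate *is* a weighted LMM, the Satterthwaite F machinery
applies unchanged — the reason this estimator, rather than a second
quadrature flavour, backs the F-test path.

**GEE** (`fit_gee_exchangeable()`). A marginal overdispersed-Poisson model
(log link, variance $\phi\mu$) with exchangeable working correlation: IRLS on
the estimating equations with moment updates of $\phi$ (Pearson) and $\rho$
(within-subject residual products; initialized at 0). Wald $\chi^2$ tests use
one of three covariances: model-based, the classical robust sandwich
$A^{-1} M A^{-1}$, or (default) the Wang–Long small-sample estimator, which
replaces each subject's residual cross-product with a covariance pooled
across subjects on the standardized scale and inflates each contribution by
the leverage adjustment $(I - H_i)^{-1}$. The pooled form requires equal
cluster sizes (as in balanced longitudinal designs); unequal sizes raise an
error rather than silently degrading. Wang and Long describe several
variants; the one implemented here is the pooled + bias-corrected form, and
`gee_cov = "robust"`/`"naive"` switch it off.

### Numerical choices and degenerate inputs

* **Singularity**: a fit with $\hat\sigma^2_b/(\hat\sigma^2_b+\hat\sigma^2_e)
  < 10^{-6}$ (LMM/PL) or $\hat\sigma^2_b \le 10^{-8}$ (AGQ, the optimizer's
  box bound) is flagged `singular`. Singular and non-converged fits are both
  counted as non-convergence in the evaluation, and their tests are reported
  `computable = FALSE` rather than dropped silently.
* **Boundary Satterthwaite**: at $\hat\sigma^2_b = 0$ the statistic reduces
  to its OLS form and the residual DF $n - p$ is returned exactly; a
  non-positive-definite variance-parameter covariance also falls back to
  $n - p$ with a warning.
* **LRT sanity**: a reduced log-likelihood above the full one by more than
  $10^{-6}$ signals an optimization failure; the statistic is clipped at 0
  with a warning. A converged full fit with a failed reduced fit makes that
  one test non-computable (and feeds the reduced-model failure rate).
* **Constant genes** never crash a fitter; they return flagged results.
* **Overflowing simulation predictors** (linear predictor above
  $\log 10^{12}$) are capped and the gene ids reported.
* **Exchangeable $\rho$** is clipped to $(-1/(m-1) + 10^{-6},\ 0.99)$, the
  positive-definite range for cluster size $m$.
* **AGQ optimization noise**: with very large counts the log-likelihood is a
  sum of large cancelling terms, so finite-difference gradients use a step of
  $10^{-5}$; likelihood differences below ~$10^{-6}$ are not meaningful
  there, which is irrelevant at the $\chi^2$ scales of the tests.

## Evaluation conventions

`fdr_power()` declares genes with BH-adjusted $p < 0.05$ (adjustment per test
across genes, never pooled across tests). FDR is
$\mathrm{FP}/\max(1, \text{declared})$ — zero declarations count as FDR 0, a
convention that matters for small replicates; power is TP over the number of
truly DE genes *among computable genes*, since non-converged models are
removed before analysis. `aggregate_replicates()` averages arithmetically
across replicate datasets. For downstream profiling of significant genes,
`predicted_expression()` evaluates the fixed-effect predictor per group and
timepoint and `hierarchical_cluster()` cuts a complete-linkage tree on the
correlation distance of row-scaled profiles; the default of 7 clusters is a
display choice, not an inference, and is user-settable.

## Problem sizes

The package's own evaluation runs (the test suite and
`scripts/acceptance.R`) use 3 replicate datasets of 2,000 genes at
$n = 10$ per group — a scale chosen so a complete run fits comfortably on a
single desktop core while leaving every qualitative contrast between methods
intact. The same pipeline runs unchanged at 15,000 genes, 10 replicates and
$n \in \{3, 5, 10\}$ via `pipeline_config()`; expect roughly linear scaling
in genes × replicates × methods.

```{r, eval = FALSE}
cfg <- pipeline_config(seed = 1, n_genes = 2000, n_per_group = 10,
                       n_datasets = 3, methods = c("lmm", "gee"),
                       tests = "interaction")
run <- run_pipeline(cfg)
run$summary
```

## Known limitations

* One random intercept only: no random slopes, no autoregressive errors, no
  multiple variance components. Methods built around richer covariance
  structures would need a different simulator to be evaluated fairly.
* The NBMM Wald path is deliberately absent: joint inference for the
  quadrature fit is by LRT only, which requires the reduced-model refits the
  convergence accounting tracks.
* The dispersion trend behind the VST is a two-parameter $a_0 + a_1/\mu$
  least-squares summary, not an empirical-Bayes shrinkage procedure; it is
  plumbing for the transformation, not a dispersion estimator of record.
* Bootstrap p-values for the NB mixed model are out of scope; at
  transcriptome scale they are computationally impractical, and the LRT is
  the reference behaviour this package reproduces.
* The surrogate triplet distribution is a modelling choice. Conclusions that
  depend on the exact FDR/power numbers (rather than their direction) should
  be re-run with an empirical triplet table from data resembling the target
  study.
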