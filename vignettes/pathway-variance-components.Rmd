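---
title: "Similarity-kernel variance components for pathway analysis in pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-kernel variance components for pathway analysis in pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathwayvc)
```

## The model

`pathwayvc` asks whether the joint expression of a set of genes — a pathway —
explains phenotypic variance in family data beyond what pedigree relatedness
already explains. Instead of aggregating single-gene association results, it
summarizes each pathway as an $N \times N$ matrix $S$ of similarities between
individuals' expression profiles over the pathway's probes, and treats $S$ as
the covariance structure of an extra random effect in the standard polygenic
mixed model:

$$
y = X\beta + g + p + e, \qquad
g \sim \mathcal N(0,\ \sigma^2_A\,\Phi_2), \quad
p \sim \mathcal N(0,\ \sigma^2_P\,S), \quad
e \sim \mathcal N(0,\ \sigma^2_e I),
$$

where $\Phi_2$ is the expected-relatedness matrix (twice the kinship
coefficient, computed from the pedigree by the classic recursion with
non-inbred, mutually unrelated founders), and $X$ holds the intercept plus sex
and age. The null model omits $p$; the test of the pathway is a likelihood-ratio
test (LRT) of $\sigma^2_P = 0$. Because that null value sits on the boundary of
the parameter space, the LRT statistic's null distribution is the familiar
50:50 mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, which is the default
(`null_dist = "mixture"`); a plain $\chi^2_1$ p value is available as
`null_dist = "chi2_1"` because published analyses do not always say which
convention they used, and the plain-$\chi^2_1$ reference is the one under which
inflation factors for such scans are conventionally reported.

Heritability is read off the null fit as
$h^2 = \sigma^2_A / (\sigma^2_A + \sigma^2_e)$-type proportions
(`variance_explained()` returns each component's share of the total), and the
pathway's contribution as $\sigma^2_P / \sum \sigma^2$.

## Fitting

`fit_ml()` maximizes the exact Gaussian likelihood with $\beta$ profiled out by
generalized least squares, using bounded L-BFGS-B with analytic gradients over
the non-negative variance components. Every evaluation factorizes
$V(\theta) = \sum_k \sigma^2_k K_k + \sigma^2_e I$ by Cholesky; with two
arbitrary kernels plus the identity there is no simultaneous diagonalization,
and at pedigree scale (a few hundred to a few thousand individuals) dense
Cholesky per step is entirely adequate. Three starting points are used (equal
split of the phenotypic variance, kinship-heavy, last-kernel-heavy) because
three-kernel likelihoods can be mildly multimodal, plus an optional warm start.
`run_scan()` warm-starts every alternative fit at the null solution with the
pathway component at zero, which enforces the nesting property
$\ell_{\text{alt}} \ge \ell_{\text{null}}$ up to optimizer tolerance.
Convergence is declared at a relative likelihood change of about $10^{-9}$
(`factr = 1e7`); a residual floor of $10^{-8}\,\mathrm{var}(y)$ keeps $V$
positive definite. ML rather than REML is the default because the LRT compares
models sharing the same fixed effects; both fits use the same $X$, so the ML
statistic is the directly comparable one. A restricted-likelihood fit
(`fit_ml(..., reml = TRUE)`) is available when unbiased variance estimates are
the goal rather than testing — with the shared-$X$ nesting used here its LRT
would also be valid, but ML is the packaged convention.

All kernels — kinship included — are standardized to unit mean diagonal
(`standardize_vc_matrix()`) before fitting so the $\sigma^2$ are on one scale
and variance proportions are comparable across pathways and metrics.

## Similarity metrics

Sixteen metrics are supported (`SIMILARITY_METHODS`). Three are similarities
as-is: Pearson correlation between profiles (`corr`, each profile centered by
its own mean across the pathway's probes), cosine (`cosine`), and the extended
Jaccard / Tanimoto coefficient `ejac` $= xy/(xx + yy - xy)$. The remaining
thirteen are distances converted through $s = 1/(1+d)$: Euclidean, Manhattan,
Chebyshev, Canberra ($\sum |x-y|/(|x|+|y|)$, zero-denominator terms contribute
0), Bray–Curtis, Soergel, Chord ($\lVert \hat x - \hat y\rVert$ on
unit-normalized profiles), geodesic ($\arccos$ of cosine), Hellinger
(Bhattacharyya on $\ell_1$-normalized profiles), Whittaker
($\tfrac12\sum|x/\Sigma x - y/\Sigma y|$), Bhattacharyya
($\sqrt{\sum(\sqrt x - \sqrt y)^2}$), divergence
($\sum (x-y)^2/(x+y)^2$, zero-denominator terms 0), and Mahalanobis (probe
covariance estimated across all individuals, ridge-regularized with
$\varepsilon = 10^{-6}\times$ mean diagonal when the condition number exceeds
$10^{10}$, since pathways routinely have more probes than individuals). Each
formula is pinned in the source next to a naive double-loop oracle in the test
suite, because several of these names have more than one convention in the
literature.

Distance-derived similarity matrices are not automatically positive
semidefinite. The likelihood requires a valid covariance, so `make_psd()` clips
negative eigenvalues to zero, reassembles, and records the pre-repair minimum
eigenvalue and a repair flag; `run_scan()` applies repair by default (after
standardization, before fitting). Correlation similarity of row-standardized
profiles is a Gram matrix and needs no repair. Degenerate inputs are handled
explicitly: constant profiles under `corr` get off-diagonal 0 / diagonal 1 with
a warning, single-probe pathways are allowed with a warning, and a constant
probe scaled to all zeros contributes nothing to any distance — the
least-surprising neutral behavior for each case.

## Preprocessing

`preprocess_expression()` applies the fixed order: shift the global minimum to
1.0 and $\log_2$; quantile-normalize columns (via `limma`, ties averaged);
residualize each probe on intercept, sex, age, age$^2$ and sex$\times$age
(collinear columns dropped with a warning — e.g. a single-sex sample); select
one representative probe per gene (two probes: larger variance; three or more:
highest mean pairwise Pearson correlation with the gene's other probes,
computed on the adjusted residuals; all ties break by lexicographic probe id
for cross-platform determinism); and scale each probe to $[0,1]$ so probes are
weighted equally. Optional per-probe weights can be injected at the scaling
stage to encode prior biology; the default is 1. Missing expression values are
rejected outright rather than imputed.

## The simulator and what it does (not) emulate

`simulate_study()` generates the study conditions used for calibration and
power work: by default 20 independent three-generation families — two founders
whose mating produces three sibs, each sib marrying a new founder and producing
three children — giving 17 members per family, 340 individuals, and realized
$2\varphi$ values $\{1, 0.5, 0.25, 0.125\}$. Probe expression is an
additive-genetic value drawn exactly as multivariate normal with covariance
$h^2_{\text{probe}}\,\Phi_2$ (default 0.5) plus independent noise, scaled to
unit variance — exact MVN rather than gene-dropping, because that is precisely
the covariance structure the mixed model assumes, making parameter-recovery
checks interpretable. Phenotypes are built as effects applied to the causal
probes' *genetic* components (not their noisy observed values), plus a residual
polygenic term sized so the total additive fraction equals
`trait_heritability` (default 0.33), plus independent noise; with oversized
effects the effect vector is rescaled down with a warning. The causal genetic
values stay fixed across the replicate phenotypes — the expression data is one
realized study, as when many phenotype replicates are simulated on one real
cohort — while polygenic and environmental draws are fresh per replicate. A
null trait is `trait_heritability = 0, n_causal_probes = 0`: pure independent
noise. Ages are uniform 20–80 and sex Bernoulli(0.5), used only as covariates.
All generators are pure functions of `(config, seed)`, with sub-streams derived
deterministically from the single integer seed.

What this simulator deliberately does not model: genotypes, linkage
disequilibrium and cis-regulatory architecture; array artifacts, batch and
non-normal noise; assortative mating or inbreeding loops. Passing calibration
and recovery tests on these data therefore shows the statistical machinery is
correct under its own assumptions, not that real expression data meet those
assumptions.

`build_decile_pathways()` reconstructs the positive-control design: probes are
ranked by how many replicate phenotypes each associates with and binned into
near-equal deciles, so bin 1 is enriched for causal transcripts and bin 10 is
effectively a negative control. In the package's scaled-down power study (12
families / 204 individuals, 50 probes of which 10 are causal with effects
declining from 0.35 to 0.05, 100 counting replicates, 30 scanned replicates,
five bins), the correlation and extended-Jaccard kernels reject the top-decile
pathway more often than the average association rate of its component probes,
with rejection falling steeply down the bins — the qualitative shape the method
is designed to produce. Per-probe association counts in that study use a
partial-correlation test given sex and age; ignoring family structure there
slightly inflates the single-probe rate, which only raises the bar for the
pathway-beats-probe comparison.

## Scanning, multiple testing and diagnostics

`run_scan()` computes each (pathway, method) similarity matrix once and reuses
it across all phenotypes — the main logistical advantage of the approach when
many phenotypes share one expression data set — and fits one null model per
phenotype. Individuals are aligned across expression, phenotypes, covariates
and kinship by inner join, with dropped ids reported. `bonferroni_threshold()`
is exact $\alpha/m$; thresholds are kept at full precision and rounded only for
display. `inflation_lambda()` reports
$\lambda = \text{median(observed LRT)} / 0.4549$, the $\chi^2_1$ reference
median — the convention under which a well-calibrated null scan sits near 1 —
with a labeled alternative that sets aside the boundary mixture's mass at zero.
`size_vs_statistic()` pairs pathway size with the statistic and reports a
Spearman correlation (constant inputs are flagged and reported as 0), to check
whether big pathways win merely by capturing more of the transcriptome.

## Numerical and design choices worth knowing

- **PSD repair on by default.** Whether historical variance-component software
  repaired indefinite similarity matrices or left them to the optimizer is
  generally undocumented; explicit clipping with recorded provenance is the
  reproducible choice.
- **Mixture vs naive p values.** Both implemented; mixture is the default for
  the single-component boundary test, naive $\chi^2_1$ available for
  comparison with analyses that used it.
- **Problem sizes.** The packaged simulations use 20 families / 340 individuals
  for calibration and heritability recovery, 10–12 families for the
  three-kernel recovery and power studies, 200 replicates for calibration and
  100 for recovery — sizes chosen to mirror a single-cohort family study while
  keeping a full run on a laptop in minutes.
- **Boundary conservatism.** At these sample sizes the mixture LRT is mildly
  conservative (empirical type-I error below nominal but within the 99%
  binomial interval of 0.05 at 200 replicates); this is the known finite-sample
  behavior of boundary variance-component tests, not a calibration defect.
- **Known limitations.** One pathway kernel at a time (no multi-kernel fits or
  kernel learning); no dominance or household components; no longitudinal
  models; empirical genotype-based kinship can be supplied as a precomputed
  matrix but is not estimated here.

## A minimal session

```{r example, eval = FALSE}
cfg <- sim_config(n_families = 12, n_probes = 40, trait_heritability = 0.33,
                  n_causal_probes = 8, effect_sizes = rep(0.2, 8),
                  n_replicates = 20, seed = 42)
st <- simulate_study(cfg)
scaled <- scale_unit_interval(st$expression)
genes <- unname(st$expression$probe_to_gene)
pathways <- list(causal = genes[1:8], random = genes[33:40])
scan <- run_scan(scaled, pathways, st$phenotypes, st$covariates, st$kinship,
                 methods = c("corr", "ejac"))
head(scan$results)
aggregate(significant ~ pathway + method, scan$results, mean)
```
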