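---
title: "Linking chemical-mixture fingerprints to transcriptomic bioactivity profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking chemical-mixture fingerprints to transcriptomic bioactivity profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemolink)
```

## The problem

Surface waters carry mixtures of hundreds of chemicals at individually low
concentrations. Exposed organisms rarely show acute toxicity or strong
single-gene responses to such mixtures; instead the transcriptome shifts in
subtle, coordinated ways. `chemolink` implements a data-driven pipeline that
correlates two blocks of measurements on the same samples — a chemical
fingerprint (samples × chemicals concentrations) and a bulk RNA-seq count
matrix (genes × samples) — to ask which constituents of the mixture covary
with which coordinated transcriptional programs.

The pipeline has five stages, each usable on its own:

1. **Chemical preprocessing** — detection filtering, k-nearest-neighbour
   imputation, standardization, PCA ordination.
2. **Expression preprocessing** — count filtering and quantile-based
   normalization.
3. **Consensus coexpression network** — bootstrap-ensemble correlation
   networks thresholded for scale-free topology, with map-equation
   (Infomap) module detection.
4. **Sparse generalized canonical correlation analysis (SGCCA)** — paired
   low-dimension representations (LDRs) of the two blocks with
   squared-weight (SW) contribution scores.
5. **Enrichment** — Mann–Whitney module enrichment per LDR and chi-square
   pathway overrepresentation in the significant modules.

A synthetic-data generator with planted latent structure ties everything
together: every stage can be validated against recoverable ground truth.

## Preprocessing models and conventions

**Chemical block.** Values below the limit of detection or not measured are
both treated as missing; no substitution (such as LOD/2) is applied, since
imputation subsumes substitution. A chemical is excluded when it is missing
in *more than* half the samples (a chemical missing in exactly half is
kept). Remaining gaps are filled by kNN imputation with `k = 5`: distances
between samples are root-mean-square differences over co-observed
chemicals, computed on columns standardized with observed entries only;
neighbour ties break by sample order and averaging is unweighted (a
distance-weighted variant sits behind a flag). Imputation precedes
standardization by construction — `standardize_chemicals()` refuses missing
values — and standardization uses the sample (n−1) standard deviation.

**Gene block.** A gene is kept when its mean count is at least 5, its total
at least 10, and at most 60% of its samples are zero. Normalization is
log2 counts-per-million with a 0.5 offset followed by full quantile
normalization (ties averaged), so all samples share one value distribution.
A covariate-conditional variant first removes the smoothed dependence of
log-expression on one per-gene covariate (length or GC), estimated by
medians over equal-count covariate bins, linearly interpolated between bin
centres and extrapolated with the end-segment slopes. This is a deliberate
simplification of published conditional-quantile-normalization methods: the
downstream stages consume any normalized matrix, and the normalization
method is not this package's contribution.

## The consensus network

Correlation networks estimated from a single pass over ~30 samples are
fragile. Each ensemble run therefore (i) bootstraps the samples to the
original n, (ii) adds Gaussian noise scaled to `noise_sd` (default 0.1)
times each gene's standard deviation, (iii) computes Pearson correlations,
and (iv) thresholds |r| so the resulting graph approximates scale-free
topology. The default of 50 runs matches common practice for this kind of
ensemble; an edge enters the consensus network when it appears in at least
`consensus_frac` (default one half) of runs, and edge support becomes the
edge weight for module detection.

The scale-free criterion fits log10 p(k) against log10 k over at least 10
log-spaced degree bins of non-isolated nodes and picks the smallest
candidate threshold reaching R² ≥ 0.8 with negative slope, falling back to
the best negative-slope fit. Two degenerate regimes get sentinel behaviour
rather than an error, because they arise routinely in small planted test
data: when no candidate admits a negative slope the flattest fit is taken,
and when degree distributions are too uniform to fit at all (e.g. a near
clique) the largest non-empty threshold is taken; both warn. An error is
reserved for the genuinely unusable case in which every candidate graph is
empty.

Modules are Infomap communities (best of 10 seeded trials) of at least
`min_module_size = 10` genes, renumbered in decreasing size order; smaller
communities and isolated genes stay unassigned.

## SGCCA, LDRs and squared weights

Given blocks $X_1, \dots, X_J$ (samples × variables, centred and by
default scaled), SGCCA maximizes

$$\sum_{j<k} c_{jk}\, g\!\left(\mathrm{cov}(X_j a_j, X_k a_k)\right)$$

over weight vectors with $\|a_j\|_2 = 1$ and $\|a_j\|_1 \le s_j \sqrt{p_j}$,
where $g$ is the scheme transform (horst $x$, centroid $|x|$ — the default,
factorial $x^2$) and $C = (c_{jk})$ the block design (all-pairs by
default). The block-coordinate update replaces $a_j$ by the sparse
projection of $X_j^\top z_j$, with inner target
$z_j = \sum_k c_{jk}\, g'(\mathrm{cov}_{jk})\, X_k a_k$; each update cannot
decrease the objective, which the fit records per iteration. The sparse
projection itself — soft-threshold, renormalize, with the threshold found
by bisection to 1e-10 — is exposed as `project_l1_l2()`.

Per component, the sample scores $X_j a_j$ are the block's LDR; after
convergence every block is deflated by regressing out its own score, and
the sign convention (largest-magnitude weight entry positive) makes runs
comparable. Squared weights $a_j^2$ sum to one per block and component and
rank each variable's contribution to its LDR; the conventional reporting
cutoff is SW > 0.01. Variance explained orthogonalizes the chemical-side
scores in order and accumulates, per component, the summed per-gene R²
against total gene-block variance, so the cumulative value equals the R² of
the gene block on all scores jointly.

Two properties anchor the implementation against independent references:
on two-variable blocks the converged objective matches an exhaustive search
over the product of unit circles, and on *whitened* blocks without sparsity
the component-1 score correlation equals the first classical canonical
correlation. The whitening matters: SGCCA with unit-norm weights maximizes
covariance, which coincides with correlation maximization only once block
covariances are the identity. The defaults (`sparsity = c(0.5, 0.3)`,
centroid scheme, 5 components) are exposed prominently because no single
setting suits all data; analyses should state theirs.

## Enrichment

For each module and LDR, a one-sided Mann–Whitney test asks whether the
module's genes carry stochastically larger squared weights than the genes
outside it. With a small group (at most 8) the p-value is exact by
enumeration of all group assignments — enumeration handles ties correctly,
where the textbook exact distribution does not — and otherwise the normal
approximation with tie and continuity correction is used; the two branches
agree to within 0.02 at the boundary. Benjamini–Hochberg adjustment is
applied over the pooled (module × LDR) family by default, which is the more
conservative choice; per-LDR families sit behind a flag.

Pathway overrepresentation forms, per pathway, the 2×2 module × pathway
table over the analyzed gene universe and applies Pearson's chi-square
without continuity correction; pathways overlapping a module in fewer than
3 genes are skipped and logged, cells with expected counts below 5 are
flagged but still tested, and enrichment additionally requires the observed
overlap to exceed its expectation. Annotations arrive as GMT; genes outside
the universe are dropped.

## The synthetic-data generator

`generate_dataset()` draws orthogonalized standard-normal factor scores for
a small number of latent exposure gradients. The chemical block is a sparse
linear factor model plus Gaussian noise, then left-censored per chemical at
the `lod_quantile` empirical quantile (censored entries become missing, as
in the pipeline's treatment of below-detection values) with further
completely-at-random missingness. Gene counts are negative binomial with
log-mean equal to a log-uniform baseline plus module-structured factor
effects; the baseline range (0.5–500 mean counts) deliberately straddles
the count filter so a planted fraction of genes is removed, and the
generator records which genes should survive. Within a module, loading
magnitudes are lognormal rather than uniform: a few hub genes couple
tightly to the driving factor and most members weakly, giving the
hub-and-spoke connectivity — and hence the decaying degree distribution —
that thresholding for scale-free topology presupposes. Censoring is
rank-based (the lowest `round(q·n)` values per chemical), so the realized
censored fraction is exact rather than approximate.

What the generator does *not* emulate bounds what green tests can show:
there is no analytical-chemistry error structure (matrix effects,
ionization suppression), no read-level RNA-seq simulation (library
preparation, mapping bias beyond a single smooth covariate), no correlated
missingness, and real exposure gradients are neither orthogonal nor exactly
linear. Recovery results on synthetic data are evidence the machinery works
as specified, not that field data meet its assumptions.

## Problem sizes and numerical choices

The shipped analyses and tests run at desk scale, chosen to finish in
minutes on one core while keeping every stage's behaviour visible: the
worked analysis simulates 30 samples × 300 chemicals × 3,000 genes with 8
modules; recovery tests use up to 100 samples and 2,000 genes over 20
seeds. Key tolerances: bisection in the sparse projection to 1e-10;
objective convergence at 1e-8 (1e-12 to 1e-14 in oracle comparisons);
squared-weight sums checked to 1e-10. Degenerate inputs are handled
explicitly: zero-variance genes get zero correlations (logged), constant
chemical columns abort standardization naming the column, rank-exhausted
blocks stop component extraction early with a warning, and non-convergence
at `max_iter` is recorded in the fit rather than thrown.

Seeds flow top-down: the pipeline seed derives per-stage seeds by a fixed
stage-indexed formula, and the ensemble derives per-run seeds as seed +
run index, so stage-level reruns reproduce pipeline-level results and edge
support is invariant to run order.

## Known limitations

- The scale-free criterion is a heuristic; on strongly blocked data with
  near-uniform degrees it degrades to the documented sentinel choices, and
  threshold grids should be adapted to the correlation level of the data.
- SGCCA sparsity levels are not selected automatically; the planted-support
  recovery analyses show how strongly the selected support depends on the
  l1 budget.
- The paired-sample design is assumed complete; samples present in only one
  block are dropped with a warning.
- P-values from the chi-square overrepresentation test are asymptotic; with
  very small modules the flagged low-expected-count cells warrant caution.
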