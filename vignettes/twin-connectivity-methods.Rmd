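---
title: "Methods: twin decomposition of functional-connectivity features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin decomposition of functional-connectivity features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinconn)
```

This vignette is the package's account of its own statistics: the model
behind each stage, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical conventions that a
reader would otherwise have to reverse-engineer from the code.

## The classical twin design

Monozygotic (MZ) twins share their whole genome; dizygotic (DZ) twins
share on average half of the segregating genes. If a phenotype's variance
decomposes into additive genetics ($a^2$), dominance ($d^2$), shared
environment ($c^2$) and unique environment ($e^2$), the implied intra-pair
correlations are

$$r_{MZ} = a^2 + d^2 + c^2, \qquad
  r_{DZ} = \tfrac{1}{2} a^2 + \tfrac{1}{4} d^2 + c^2,$$

using the standard biometrical assumptions: additive genetic correlation
1 in MZ and 0.5 in DZ pairs, dominance correlation 1 and 0.25, shared
environment fully shared in both, no assortative mating, no gene–
environment interaction. $c^2$ and $d^2$ cannot be estimated from twin
correlations simultaneously (two equations, three unknowns), which is why
the classical design chooses between an ACE and an ADE model per
phenotype.

`twinconn` uses the ratio gate on features with $0 < r_{DZ} < r_{MZ}$:

* $r_{MZ} > 4 r_{DZ}$ — consistent only with multi-locus non-additive
  (epistatic) inheritance; no linear decomposition is attempted.
* $2 r_{DZ} < r_{MZ} \le 4 r_{DZ}$ — ADE: $A = 4 r_{DZ} - r_{MZ}$,
  $D = 2 r_{MZ} - 4 r_{DZ}$, $E = 1 - r_{MZ}$; broad-sense heritability
  $H^2 = A + D = r_{MZ}$.
* $r_{DZ} < r_{MZ} \le 2 r_{DZ}$ — ACE: $A = 2 (r_{MZ} - r_{DZ})$,
  $C = 2 r_{DZ} - r_{MZ}$, $E = 1 - r_{MZ}$; narrow-sense heritability
  $h^2 = A$.

Everything else — a non-positive correlation in either group, or
$r_{MZ} \le r_{DZ}$ — is labelled `UNMODELED`; no components are reported
there, and inside the gated regions the estimates are non-negative and sum
to one algebraically.

**Boundary tie-breaks.** The gating inequalities are strict on both sides
at $r_{MZ} = 2 r_{DZ}$ and $r_{MZ} = 4 r_{DZ}$, so the boundaries must be
assigned by convention. The package sends $r_{MZ} = 2 r_{DZ}$ to ACE
(where $C = 0$) and $r_{MZ} = 4 r_{DZ}$ to ADE (where $A = 0$): with this
assignment the component estimates are continuous functions of
$(r_{MZ}, r_{DZ})$ across each boundary, so an infinitesimal perturbation
of the correlations cannot jump the estimates.

## Intra-pair correlations and inference

`zygosity_correlations()` computes, per feature and per zygosity group,
the Pearson correlation between Twin 1 and Twin 2 residuals after OLS
regression on an intercept, age and sex. Covariates enter at pair level
because pairs are same-sex and share age. A constant covariate column
(e.g. sex in a single-sex cohort) is dropped with a warning and the
covariate count $k$ reduced, rather than failing on a rank-deficient
design.

Two correlations are compared one-sided ($r_{MZ} > r_{DZ}$ — the
direction every genetic scenario implies) on the Fisher scale:

$$Z = \frac{\operatorname{atanh} r_{MZ} - \operatorname{atanh} r_{DZ}}
   {\sqrt{1/(n_{MZ}-3-k) + 1/(n_{DZ}-3-k)}},$$

with the $-k$ correction for partialled covariates. Bonferroni correction
uses an explicit family size; `twin_fc()` defines families as the cells of
(spatial scale × scenario), so e.g. all link-level ADE features are one
family. Within-pair ordering follows the manifest by default; the
`double_entry = TRUE` option enters each pair in both orders (an
interclass-correlation variant) while keeping the pair count, not the row
count, in the Fisher variance.

An optional pre-filter (`require_significant_r = TRUE`, default off)
demands that $r_{MZ}$ and $r_{DZ}$ each be individually significantly
positive (one-sided t test, $df = n - 2 - k$) before any gating; features
failing it are set to `UNMODELED`.

## FC matrices and graph features

`compute_fc_matrix()` correlates all ROI pairs and derives two-sided
p-values from $t = r\sqrt{(T-2)/(1-r^2)}$ on $T-2$ degrees of freedom.
Two-sided is the conventional default and keeps significantly negative
links, which the signed-strength metrics need; the degrees of freedom do
not correct for temporal autocorrelation, a known simplification at
TR-level sampling. `significance_mask()` zeroes links with $p \ge \alpha$
(default $\alpha = 0.05$, uncorrected — masking is a per-subject
preprocessing step, not an inference). `binarize()` keeps an edge iff the
masked weight strictly exceeds $\tau$ (default 0.5, a deliberately
arbitrary positive threshold); ties at exactly $\tau$ are measure-zero,
and strictness is fixed here for reproducibility.

Node metrics (from the binary matrix): degree; clustering coefficient
$2 t_i / (k_i (k_i - 1))$, zero when $k_i < 2$; local efficiency — the
global efficiency of the subgraph induced by the node's neighbours, zero
when $k_i < 2$; betweenness centrality as raw, unnormalized
shortest-path pair counts (the connectivity-toolbox convention). Signed
strengths come from the weighted matrix: row sums of positive weights and
of absolute negative weights. Network metrics: global efficiency (mean
inverse distance over unordered pairs, $1/\infty = 0$), characteristic
path length (mean over *finite* distances only, with a `disconnected`
flag whenever any pair is unreachable — averaging infinities would be
meaningless, and the flag keeps the exclusion auditable), mean degree
$2m/N$ (the single network-level "degree" number, interpreted as the mean
nodal degree), density $2m/(N(N-1))$, and Louvain modularity.

Louvain is a greedy heuristic whose output depends on node order, so
`louvain_modularity()` runs 10 seeded node-shuffled restarts and keeps the
best partition; the reported $Q$ is always recomputed from the returned
partition via $Q = \sum_c [e_c/m - \gamma (d_c/2m)^2]$ (resolution
$\gamma = 1$), making the value self-consistent regardless of the
library's internals.

`extract_feature_table()` assembles $C(N,2)$ link weights, $6N$ nodal
values and 5 network values per subject — 4005 + 540 + 5 = 4550 features
for the default 90-region AAL parcellation — in a fixed column order
(`link:A|B` with $i<j$ row-major, then metric-major node columns, then
network metrics).

## The synthetic-data generator

`simulate_feature_cohort()` draws feature values directly from the
biometrical model: per pair, standard-normal latent factors with the A/C/D
within-pair correlations above, combined as
$y = \sqrt{a^2} A + \sqrt{c^2} C + \sqrt{d^2} D + \sqrt{e^2} E$ plus
additive age and sex effects. Defaults mirror the cohort the package
targets: 18 MZ and 25 DZ same-sex pairs, pair ages uniform on 10–30
years, pair sex Bernoulli(1/2). `simulate_timeseries_cohort()` produces
BOLD-like series: a shared base correlation template is perturbed per link
on the Fisher scale by twin-structured draws ($\sigma$ scales them),
mapped back through $\tanh$ — which keeps every entry in $(-1, 1)$ and the
matrix near positive-definite — projected to the nearest correlation
matrix (eigenvalue clipping at $10^{-8}$, renormalization to unit
diagonal), and sampled as $T = 200$ multivariate-normal volumes.

What this emulates: twin covariance with exact, known A/C/D/E structure;
covariate confounding; block-structured FC; sampling noise at realistic
$T$. What it does not: hemodynamics, temporal autocorrelation, scanner
drift, motion artefacts, spatial smoothness, or non-Gaussian BOLD
features. Tests passing on these cohorts therefore validate the
*statistical machinery* — estimator identities, gating, calibration —
not robustness to fMRI artefacts, which real pipelines handle upstream of
this package's inputs.

All randomness flows from one integer seed through derived sub-seeds
(an LCG-style mix of the base seed and a stream index), so manifest,
feature and per-subject series draws come from separate reproducible
streams; R supplies no counter-based generator, and this scheme gives the
same practical property — component draws that do not depend on
evaluation order — with base R's RNG.

## Power analysis

`monte_carlo_power()` simulates twin cohorts as bivariate-normal pairs
and reports the rejection rate of either (i) `MZ_NONZERO`, the one-sided
Fisher test of $r_{MZ} > 0$ with variance $1/(n-3)$ — under the
broad-sense reading $H^2 = r_{MZ}$ this is a test against the null of no
heritability, and it is the default — or (ii) `MZ_GT_DZ`, the one-sided
comparison of the two groups. No covariates enter the power simulation,
hence no $-k$ correction. At $n_{MZ} = 18$ and $r_{MZ} = 0.6$ the default
test yields ≈ 87% power at $\alpha = 0.05$ (10,000 replicates). The Monte
Carlo uncertainty is reported as a Wilson 95% interval; with 10,000
replicates it spans roughly ±0.7 percentage points. Common random numbers
under a shared seed make power monotone in effect size and sample size
replicate-by-replicate.

## Problem sizes in the test suite

The suite validates the graph metrics against brute-force oracles
(Floyd–Warshall distances and literal enumeration of simple paths,
written independently of the implementation): exhaustively over all
connected labelled 4-node graphs, and over seeded random samples of
5- and 6-node graphs — several hundred graphs in total, enough to cover
every metric code path (disconnection, isolated nodes, degree-1 nodes,
bridges) while keeping the oracle's exponential path enumeration cheap.
Louvain's $Q$ is checked against exhaustive best-partition search on
graphs of up to 8 nodes (Bell(8) = 4140 partitions).

Estimator calibration uses 5000 + 5000 simulated pairs per seed over 20
seeds. At that size the sampling standard deviation of the Falconer
estimators is itself ≈ 0.03 (e.g.
$\operatorname{sd}(\hat A_{ACE}) = 2\sqrt{\operatorname{var}\hat r_{MZ} +
\operatorname{var}\hat r_{DZ}}$), so correctness is asserted on the
scenario gate per seed and on the mean component estimates across seeds
(standard error ≈ 0.007) rather than on single-seed values, which would
test sampling noise rather than the estimator. Type-I behaviour is
checked under a global null ($e^2 = 1$) at the target cohort size, 4550
features × 20 seeds, where the one-sided uncorrected rejection rate must
match $\alpha$ within ±0.01.

## Known limitations

* Falconer point estimates come with no confidence intervals; at a few
  dozen pairs a structural-equation (SEM) likelihood analysis would be
  preferable but is deliberately out of scope, as are sex-limitation,
  age-moderation and multivariate twin models.
* The gate assigns exactly one scenario per feature; near the boundaries
  the choice is driven by sampling noise in $\hat r_{MZ}/\hat r_{DZ}$,
  and users should read scenario frequencies, not single-feature labels,
  at small $n$.
* The link-significance mask ignores temporal autocorrelation in the
  BOLD series, so its effective $\alpha$ on real (smoothed, filtered)
  data will exceed the nominal one.
* The shipped RSN map (`inst/extdata/rsn_map_synthetic.yaml`) is a
  placeholder built from common literature assignments; substantive
  RSN-level claims require a map matched to the user's parcellation and
  population.
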