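---
title: "Covariance networks and mediation models for regional digital histopathology"
author: "neuropathNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariance networks and mediation models for regional digital histopathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropathNet)
```

## The scientific problem

Frontotemporal lobar degeneration (FTLD) splits into two main
proteinopathy classes — tauopathies and TDP-43 proteinopathies — that are
clinically similar during life but biologically distinct at autopsy. Digital
histopathology quantifies the burden of pathological protein inclusions in a
sampled tissue region as the percent area occupied by positive pixels
(%AO), measured separately in cortical gray matter (GM) and the adjacent
deep white matter (WM) on each slide. With up to 13 cortical regions
sampled per hemisphere, each (region, compartment) pair becomes a node with
one measurement per subject.

`neuropathNet` implements a group-level network view of such data. The
working hypothesis it serves: if pathology spreads along long-range axonal
connections, WM burden should be coupled to GM burden across regions and
should mediate the anterior-to-posterior gradient of cortical pathology.
The package provides four linked analyses:

1. **Covariance graphs** per group (`buildGraph()`): edges are group-level
   Pearson correlations of ln(%AO) between nodes.
2. **Edge-wise group comparison** (`compareGraphs()`): the two-sample
   Fisher r-to-z test per node pair.
3. **Node strength vs burden** (`nodeStrength()`,
   `strengthBurdenCorrelation()`): does network integration track regional
   pathology load?
4. **Causal mediation** (`runMediationPanel()`): does averaged WM pathology
   mediate the association between anterior GM and posterior GM burden?

Because the motivating autopsy dataset is not publicly deposited, a
synthetic-cohort generator (`simulateCohort()`) reproduces the statistical
structure the analyses assume — log-normal %AO, block-structured
correlations, slide-level missingness, planted mediation chains — so every
stage is testable end to end.

## Data model and the log transform

Measurements live in a `PathologyCohort`, a `SummarizedExperiment` with
nodes as rows, subjects as columns, and assays `pctAO` and `lnAO`. %AO is
strongly right-skewed; all analyses run on the natural log scale, where the
data are approximately normal. The transform is total: a measurement of
exactly zero (possible in principle for a clean slide) is mapped to
`ln(zero_offset)` with a configurable floor (default 0.001%), and the
number of floored rows is reported in `metadata(x)$load_report`. Strictly
positive values always keep their own logarithm — the floor never perturbs
observed non-zero data. Whether genuinely zero measurements occurred in the
motivating dataset, and how they were transformed there, is unknowable from
the published record; the floor makes the package's behaviour explicit and
auditable instead.

Missingness is a first-class citizen: a node not sampled for a subject is
`NA`, and per-node availability varies widely across regions (from a
handful of legacy cases to nearly the full cohort). Long-format input (one
row per subject-region-compartment) keeps that explicit; wide input is
reshaped on load.

## Covariance graphs

For one group, the edge between nodes $i$ and $j$ is the Pearson
correlation $r_{ij}$ of ln(%AO) computed over the subjects measured at
*both* nodes (pairwise-complete estimation). Each edge therefore carries
its own sample size $n_{ij}$, which downstream tests use directly; this is
the only estimation strategy consistent with a per-edge test that
explicitly accounts for differing pairwise sample sizes. Edges with
$n_{ij}$ below `min_pairs` are marked excluded and carry no weight — the
analogue of blacked-out cells in a correlation heat map. The default
`min_pairs = 5` is deliberately conservative with a hard floor of 3 (below
which the correlation t-test has no degrees of freedom); the threshold is
configurable and recorded in the graph object, since the convention "pairs
with insufficient sample size are excluded" does not pin down a number.

Per-edge two-tailed p-values use the exact t-distribution with
$n_{ij} - 2$ degrees of freedom. On complete data, pairwise-complete and
listwise estimation coincide exactly (a property the test suite asserts).

## Comparing edges between groups

Whether a given node-pair correlation differs between groups is tested on
the variance-stabilized scale. With $z(r) = \mathrm{arctanh}(r)$ and the
classical large-sample variance $1/(n-3)$,

$$Z = \frac{z(r_1) - z(r_2)}{\sqrt{\tfrac{1}{n_1-3} + \tfrac{1}{n_2-3}}}$$

is referred to the standard normal. The per-edge $n_1$, $n_2$ are the
pairwise-complete counts, so tissue-availability imbalance between groups
is absorbed edge by edge.

Two conventions deliberately coexist and are surfaced rather than silently
resolved: scalar statistics default to two-tailed tests, while
graph-difference maps conventionally use one-tailed edge comparisons (each
direction of difference is displayed separately). `compareGraphs()` takes
`tail` explicitly and records the convention used in its result attributes
and in the pipeline summary. The default threshold is an uncorrected
$\alpha = 0.05$ — appropriate for a hypothesis-driven pattern-level
reading, not for per-edge inference; Benjamini–Hochberg correction is
available via `correction = "bh"` for users who want edge-level claims.
Edges included in only one group's graph, or degenerate edges with
$|r| = 1$ (no finite z-variance), cannot be compared and are returned in a
skipped-edges table.

## Node strength and burden

Node strength is the sum of a node's incident included edge weights —
signed by default, matching the literal definition of weighted degree as
the sum of edge weights. Negative correlations therefore subtract; whether
that is the right treatment is genuinely open (the convention is unstated
in the motivating work), so `edge_weight_mode = "absolute"` is offered and
the signed/absolute choice is a visible argument, not a buried constant.
Strength of an isolated node is 0, and the signed mode satisfies the
conservation identity $\sum_v s_v = 2\sum_{e} r_e$, asserted in tests.

`strengthBurdenCorrelation()` then correlates strength with group-mean
ln(%AO) across the nodes of one compartment (GM and WM separately, since
the two compartments' burden scales differ). With only ~13 nodes per
compartment this is a low-powered correlation and is reported with its
exact $n$; it asks a qualitative question — are the integrated nodes also
the heavy ones? — not a precise effect-size question.

## Mediation of anterior-to-posterior spread

For a triple (X = anterior GM node, Y = posterior GM node, M = WM
mediator), three OLS fits on the identical complete-case subject set give

* $a$: slope of $M \sim X$,
* $c$: the total effect, slope of $Y \sim X$,
* $c'$ and $b$: slopes of $Y \sim X + M$.

Without an interaction term, $c = c' + ab$ is an algebraic identity (the
suite checks it to $10^{-8}$), and the indirect effect is $ab$. The
mediator is the per-subject *mean of the ln-transformed* WM values of the
X and Y regions. Averaging on the ln scale (rather than taking the log of
mean %AO) keeps the mediator on the same scale as every other variable in
the globally log-transformed analysis; this is a deliberate package choice
where the averaging scale is otherwise ambiguous.

Significance of $ab$ uses a percentile bootstrap: subjects are resampled
with replacement (X, M, Y jointly), $ab$ is recomputed per resample
(default 1000), and the 95% interval is the empirical quantile pair. The
percentile variant is the default of the tradition the analysis follows
and behaves well at the modest complete-case sizes typical here;
bias-corrected variants are not implemented. Degenerate resamples (zero
variance) are redrawn and counted, capped at ten times `n_boot` draws.
Everything is deterministic given `seed`.

Classification follows the standard causal-steps reading on top of the
bootstrap: **none** if the CI for $ab$ includes 0; otherwise **full** if
$c'$ is non-significant at $\alpha$; otherwise **partial**. The classical
requirement that the premediated total effect $c$ be significant is off by
default (`require_total = FALSE`) — modern practice recognises genuine
indirect effects with non-significant totals — but can be switched on,
reproducing the stricter historical rule.

The default panel tests the three anterior frontotemporal core regions
(orbitofrontal BA11, midfrontal BA46, superior temporal BA22) against the
posterior parietal angular gyrus (BA39). Complete-case analysis per triple
is the only approach compatible with plain OLS path models; the
complete-case count is always reported alongside each result.

## The synthetic-cohort generator

The generator draws subject vectors from a multivariate normal on the ln
scale and exponentiates, so %AO is log-normal and strictly positive —
matching the empirical skew and sidestepping the zero-floor path entirely
in simulation. Three design elements matter:

* **Correlation structure.** The default family is block-exchangeable:
  one within-GM correlation, one within-WM, one GM-WM cross value. This is
  the smallest family expressing "coupled vs uncoupled compartments". The
  implied matrix must be positive semi-definite; the constructor refuses
  invalid specifications outright (no nearest-PSD repair, which would
  silently change the study conditions). The PSD boundary is real and
  binding: with 13 regions and within-block correlation $\rho$, the cross
  block cannot exceed $(1 + 12\rho)/13$ — for $\rho = 0.5$ that is 0.538,
  which is why the shipped coupled preset uses `rho_cross = 0.45` rather
  than a nominally rounder larger value. Arbitrary full correlation
  matrices are accepted for structures outside the exchangeable family.
* **Missingness is slide-level.** A subject missing a region loses both
  its GM and WM node together, mirroring how tissue availability actually
  varies. Preset per-region missingness is derived from the published
  per-region N of each group (1 − N/N~group~).
* **Planted mediation chains.** A triple replaces, after the correlated
  draw, each WM node of its X and Y regions with $aX + \varepsilon$
  (independent noise per node) and the Y GM node with
  $bM + c'X + \varepsilon'$, where $M$ is the per-subject average of those
  WM nodes — exactly the aggregate the analysis estimates, so the planted
  $(a, b, c')$ are the population path coefficients. Triples apply in list
  order and later triples overwrite shared nodes; sharing a Y region
  across triples therefore leaves only the last chain fully intact, which
  is visible in panel demos as occasional attenuation of earlier chains.

Two preset groups encode the contrast of interest: a "tau-like" group
(n = 53, cross-coupled compartments) and a "tdp-like" group (n = 66,
uncoupled), with node means/SDs taken from the published group summary
table bundled as `ftldRegionParams()`. The preset cross-correlations are
stylised, not estimates — the source correlations exist only as heat maps.

A separate single-group configuration, `wmCouplingGradientConfig()`,
demonstrates the strength-burden association. It is a latent-factor model:
GM and WM nodes load $\sqrt{0.45}$ on their compartment factor and
$0.6\lambda_r$ on a shared coupling factor, with $\lambda_r$ on a grid
over [0.3, 0.95] and WM means rising linearly in $\lambda_r$
($-4 + 3\lambda_r$ on the ln scale). Factor construction guarantees a
valid correlation matrix, and burden co-varies with coupling by design, so
WM strength-burden correlation is positive in population. Under uniform
coupling (the presets) there is no such association — a useful negative
control the test suite also relies on.

```{r generator-demo}
presets <- tauTdpPresets(seed = 7)
coh <- simulateCohort(presets)
coh
```

## Numerical and degenerate-input choices

* Correlation matrices come from `stats::cor(use =
  "pairwise.complete.obs")` with per-pair counts from an indicator
  cross-product; per-edge results are asserted against brute-force
  recomputation on the shared-subject subsets.
* OLS paths use closed-form normal equations on centred variables (fast
  enough to vectorise the bootstrap fully); they are tested to $10^{-10}$
  against `lm()`.
* Degenerate variance in X, M or Y, fewer than `min_n` (default 10)
  complete cases, fewer than 2 usable nodes, and non-PSD generator
  specifications are hard errors naming the offending quantity. Panel
  cells that error are flagged in-place; the panel continues.
* `fisherZ()` refuses $|r| \ge 1$; graph comparison skips such edges and
  reports them rather than propagating infinities.
* Bootstrap and simulation determinism: every stochastic entry point takes
  a seed; the pipeline derives per-cell seeds arithmetically from the run
  seed, and reruns produce byte-identical output bundles.

## Verification scale

The test suite validates the statistical behaviour at deliberately chosen
problem sizes: type-I calibration of the edge test from 200 two-group
replicates at n = 60/group over 26 nodes (empirical rate required inside
[0.03, 0.07]); planted coupled-vs-uncoupled recovery over 20 preset draws
at the study group sizes (53/66); mediation classification recovery and
percentile-CI coverage from 100–200 replicates at n = 50–100 with 1000
bootstrap resamples. These sizes give stable Monte-Carlo estimates while
keeping a full run of the suite around a minute.

## What passing tests do and do not show

The generator reproduces the *assumed* statistical structure: log-normal
marginals, exchangeable correlation blocks, slide-level missingness,
linear-Gaussian mediation chains. Real autopsy data differ in ways the
synthetic tests cannot certify: spatial autocorrelation beyond the block
structure, pathologic-subtype heterogeneity within groups, staining-batch
effects, non-Gaussian tails after the log transform, and informative
(rather than random) missingness in legacy sampling. Passing tests
therefore demonstrate that the estimators and tests do what they claim
under their own assumptions — not that those assumptions hold in any
particular cohort. Group-level graphs also remain group-level: with one
measurement per node per subject there are no individual networks, so all
inference is about group covariance structure.

## Known limitations

* No graph metrics beyond node strength (no clustering, path length, or
  community structure), and no permutation or network-based-statistic
  correction for the edge maps.
* Mediation is single-mediator, no moderated mediation, no
  sensitivity analysis for sequential ignorability; "causal" language
  inherits the usual observational caveats.
* The two tail conventions (one-tailed maps, two-tailed scalars) are both
  available and logged, but the package cannot decide which a given
  published figure used.
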