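---
title: "chronomiR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chronomiR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronomiR)
```

## The problem

MicroRNAs repress their target mRNAs, largely through seed-sequence
complementarity in the 3'UTR, and a single miRNA can touch hundreds of
transcripts. In a longitudinal experiment — say, per-day differential
expression of miRNAs and mRNAs after an injury — the space of candidate
miRNA–mRNA interactions is tens of thousands of pairs, far too many to
carry into gene-regulatory-network construction or bench validation.
chronomiR reduces that space to a small, pathway-focused candidate
network by combining three orthogonal signals: per-time-point pathway
overrepresentation, temporal anticorrelation between miRNA and mRNA
trajectories, and membership in curated target databases.

The package consumes *differential-expression results*, not reads or
counts: one table per gene type with a log2 fold change and an adjusted
p-value per time point (each post-baseline time point contrasted against
time zero upstream, e.g. with limma or DESeq2). Producing those tables is
out of scope here by design, as is live access to pathway or target-site
web services — pathway gene sets are read from local GMT files and target
databases from local tab-separated snapshots, so every run is offline and
reproducible.

## Significance filtering: combined and separate modes

Each gene is filtered at each time point independently of every other
time point: it enters the significant set for time point $t$ iff its
adjusted p-value at $t$ is at most `alpha`. The inclusive boundary
(`padj <= alpha`, not `<`) is deliberate and fixed; `alpha` defaults to
0.05, the conventional adjusted-p cutoff, and is configurable. The
*combined* mode pools miRNA and mRNA labels into a single set per time
point; the *separate* mode keeps one set per (time point, gene type).
The combined set at a time point is exactly the union of the two
separate sets — a property the test suite asserts.

Identifier handling: most pathway collections are curated by entrez or
ensembl gene IDs, and neither can distinguish the -3p and -5p arms of a
mature miRNA. The ID map is therefore total (every input label gets a
row, unmapped ones with absent IDs) and carries an *adjusted label*.
Because the mapping table holds no symbol column, the adjusted label is
the input label itself — unique per gene type by construction — so the
-3p/-5p suffix survives even when both arms share one entrez ID, and a
network containing both arms stays unambiguous. mRNA labels that collide
on one entrez ID are both kept (with a warning); enrichment
de-duplicates by mapped ID, so the collision cannot double-count.

## Per-time-point overrepresentation

For every context (a time point, a (time point, gene type) pair, or a
temporal cluster) and every pathway, the overlap between the context's
significant set and the pathway is tested with the one-sided
hypergeometric upper tail including the observed overlap,

$$P(X \ge k) = \sum_{i=k}^{\min(n,K)}
  \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

the standard ORA convention ($N$ universe size, $K$ pathway size, $n$
significant-set size, all after intersection with the universe). The
universe is user-adjustable; `"auto"` uses the union of all mapped genes
present in the input tables, a sensible default for "all detected
genes". Adjusted p-values are Benjamini–Hochberg within each context
across its pathways — the ecosystem default for ORA. Zero-overlap rows
carry $p = 1$ and are dropped by default (configurable).

Two numerical notes. The tail is computed by `stats::phyper`, and the
suite checks it against exhaustive enumeration of all $\binom{N}{n}$
draws for every valid $(k, K, n, N)$ with $N \le 12$, at $10^{-10}$.
And one tempting invariant is intentionally *not* asserted: re-applying
the BH step-up to an already adjusted vector is not a no-op in general
(for adjusted values $(0.11, 0.37, 0.37, 0.37)$ the re-adjusted rank-1
entry becomes 0.37), so only order preservation and the step-up formula
itself are tested.

In combined mode, miRNA identifiers are pooled into the gene list and
simply fail to overlap pathways that contain no miRNA entries; this
mirrors the mode's definition rather than special-casing gene types.

## Temporal pathway clustering

The second route to a pathway of interest ignores p-value ranking and
looks at *shapes*: for each pathway, the trajectory of significant-member
counts over time, row-standardized and soft-clustered with fuzzy
c-means. Standardization uses the sample (n−1) standard deviation —
the convention of Mfuzz-style expression clustering — and zero-variance
rows (pathways never touched, or touched identically at every time
point) are dropped and listed rather than silently kept as zeros.

Fuzzy c-means is implemented in the package because its exact semantics
are part of the contract: memberships
$u_{ic} = 1/\sum_{c'} (d_{ic}/d_{ic'})^{2/(m-1)}$ with Euclidean $d$,
centers as $u^m$-weighted means, a row coincident with a center
($d = 0$) taking membership exactly 1 there, centers initialized as $c$
distinct rows sampled without replacement under a caller seed,
convergence when the largest center movement drops below `tol`
(default 1e-6, `max_iter` 200). The per-iteration objective
$\sum_i \sum_c u_{ic}^m d_{ic}^2$ is recorded and is non-increasing —
asserted in tests — and the whole procedure is bit-reproducible under a
fixed seed. `e1071::cmeans`, run from the same initial centers, agrees
with the converged memberships to machine precision in the test suite;
it is kept as an independent cross-check rather than the implementation
so that initialization, the $d=0$ rule and the objective trace stay
under the package's contract. A membership row sums to 1 by
construction; "fitness score" in the upstream literature is read as
this membership, the only per-pathway-per-cluster quantity on $[0, 1]$
the procedure produces.

Choices left open by the method's description, fixed here: the
fuzzifier defaults to $m = 2$ (the universal fuzzy c-means default;
memberships sharpen towards hard clustering as $m \to 1^+$, which the
suite checks by entropy comparison at $m = 1.05$ versus $m = 3$); the
cluster count $c$ is supervised, i.e. always user-supplied; trajectories
are clustered on raw significant-member counts, not counts normalized by
pathway size — the count trajectory is what the method description
names — with the normalized variant available by standardization being
scale-free anyway. Cluster-number heuristics and stability analyses are
out of scope.

For designs whose differential expression is fitted over the whole
course rather than per time point (spline or likelihood-ratio designs),
the same machinery runs at gene level: genes filtered for significance
over the course are clustered on their trajectories, hard-assigned to
their maximum-membership cluster (ties to the lower-indexed cluster,
logged), and each cluster is enriched as a context. With $c = 1$ this
degenerates exactly to whole-course enrichment.

## The interaction matrix and the filter

After a pathway is selected (explicitly, or automatically as the
pathway with the smallest adjusted p summed over contexts — a
convenience heuristic, documented as such), the candidate matrix is
every input miRNA that survived significance filtering at at least one
time point, crossed with every input mRNA mapping into the pathway.
Every such mRNA is treated as a *potential* target of every candidate
miRNA; evidence then whittles the matrix down:

* **Correlation.** For each pair, the correlation between the two
  per-time-point trajectories (log2 fold changes by default; a
  user-supplied mean-expression matrix is accepted instead). Pearson is
  the default; Spearman and tie-corrected Kendall (tau-b) are
  available. Since miRNAs repress their targets, candidate interactions
  should anticorrelate: a pair is kept only if its correlation is at
  most `max_corr`, default **−0.5**, with an inclusive boundary (a pair
  at exactly −0.5 is kept — the threshold is stated as a *maximum*).
  Pairs whose trajectory has fewer than two finite values or zero
  variance get no correlation and can never pass.
* **Database votes.** Each loaded database (two predictive — TargetScan-
  and miRDB-shaped — and one functional, miRTarBase-shaped with every
  pair whose evidence contains "weak", case-insensitively, removed at
  load) flags each pair 0/1; the vote is the sum over the *selected*
  databases only. A pair is kept only if its vote count is at least
  `min_dbs`, default **1**.

Kept pairs form a bipartite miRNA/mRNA graph (an igraph object) whose
edges carry the correlation, vote count and per-database flags; the
filter is anti-monotone in both thresholds and is checked against an
independent brute-force scan in the tests. Downstream views — per-gene
trend plots with a signed highlight threshold (a gene is highlighted iff
*any* value exceeds the threshold), hierarchical clustering of network
gene trajectories (Euclidean distance on standardized rows, average
linkage by default) with a dendrogram-compatible heatmap and per-cluster
smoothing-spline overlays — all return their plotted tables so ordering
and flags are testable without reading images.

## Longitudinal pair statistics

Short series make correlation and regression statistics optimistic, so
every operation here runs a guard: fewer than **3** time points is an
error, fewer than **5** a warning (analysis proceeds), 5 or more is
clean.

* **Cross-correlation.** $\mathrm{ccf}(\ell) = \sum_t (x_t - \bar x)
  (y_{t+\ell} - \bar y) / (T s_x s_y)$ over the overlapping window,
  with full-series means and population (divisor-$T$) standard
  deviations — the classical sample-CCF normalization, under which
  $\mathrm{ccf}(0)$ equals the Pearson correlation *exactly* (no
  $T/(T-1)$ discrepancy to reconcile). Positive lag means the mRNA
  series trails the miRNA series. One caution the tests encode: for
  smooth monotone series the shrinking overlap window biases the
  maximum towards lag 0, so lag detection is only meaningful for
  series with localized features.
* **Scaled spline display.** Both series standardized and interpolated
  by a natural cubic spline (an interpolant, not a smoother: it
  reproduces the standardized points exactly) onto a 100-point grid;
  the unscaled correlation is annotated rounded to 2 decimals.
* **Regression prediction.** OLS with intercept of a selected gene on
  any user-chosen set of its predicted partners, reporting $R^2$, the
  overall F-test p-value and the fitted trajectory; collinear or
  excess predictors (more than $T - 2$) are hard errors naming the
  offenders.
* **Pair odds ratio.** For a single pair, OLS of mRNA on miRNA;
  $\mathrm{OR} = e^{\hat\beta}$ with Wald interval
  $e^{\hat\beta \pm 1.96\,\mathrm{SE}}$. Deriving an odds ratio from a
  *linear* regression coefficient is an unusual effect-size reading
  inherited from prior miRNA-association work; it is implemented
  exactly as that transform, full precision internally, rounded to 2
  decimals only at display. A numerically exact fit has SE 0, so the
  interval collapses onto the point and the fit is flagged
  `exact_fit`.

## Exports

PathVisio import files (one result type per file, one column per time
point, BridgeDb system codes "L"/"En"), a three-column filtered-miRNA
list for MAPPbuilder (adjusted label, mapped ID, system code — the
exact column dialect of the original MAPPbuilder input is unpublished,
so this documented layout makes no identity claim), and
Cytoscape-ready GraphML and SIF (+ edge-attribute sidecar). All writers
sort on stable keys, print floats at 10 significant digits and are
byte-deterministic; each has a reader-based round-trip test.

## The synthetic fixture: what it emulates and what it does not

All tests run on generated data with recorded truth. The default
fixture mirrors a five-time-point (days 1–14) injury-style course at
desk scale: 30 miRNAs × 60 mRNAs, 10 disjoint pathways of 6 mRNAs,
one pathway planted as enriched on days 3–14, pathway count
trajectories following planted shapes (monotone up for half the
pathways, down for the other half), and five planted interactions whose
target trajectories are $-0.8 x + \varepsilon$,
$\varepsilon \sim N(0, 0.2^2)$, putting their Pearson correlations
near −0.9; each planted pair is present in two databases. Decoy
database entries are restricted to pairs whose generated correlation
exceeds −0.3, so under default thresholds the filtered network equals
the planted set exactly — giving sharp recall/precision oracles. With
`noise_sd = 0` planted pairs are exactly linear (correlation −1 to
machine precision).

What passing these tests shows: the counting, testing, clustering,
filtering and export machinery do exactly what their contracts say.
What it does not show: performance on real data, where trajectories are
autocorrelated rather than white, pathway memberships overlap heavily,
database coverage is biased, and true regulation is not exactly linear.
The fixture is an instrument for correctness, not a benchmark.

Problem sizes throughout (10 pathways, ≤150 candidate pairs, 5 time
points, $N \le 12$ enumeration sweeps) were chosen so the entire suite
and the acceptance script each run in seconds on one CPU.

## Known limitations

* Pathway namespace is declared, not sniffed; a GMT line mixing
  entrez-style and ensembl-style tokens is rejected, but symbol-based
  sets pass through under whatever namespace the caller declares.
* The odds ratio is a monotone transform of the OLS slope, not a
  probability model; its Wald interval inherits the linear model's
  assumptions and is reported as an effect-size convention.
* With five time points, all longitudinal statistics are honest but
  weak; the guard warns below five for exactly this reason.
* Automatic pathway selection (smallest summed adjusted p) is a
  convenience; analyses of record should select the pathway on
  substantive grounds.
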