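---
title: "Single-sample co-expression networks: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-sample co-expression networks: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sscnet)
```

## What the package computes

`sscnet` analyses the genomic organisation of gene co-expression. For a
cohort of RNA-seq samples it infers a mutual-information (MI)
co-expression network, derives one network per sample with the LIONESS
leave-one-out equation, classifies the strongest edges by where their two
genes sit in the genome, and asks three questions:

1. **Where does co-expression concentrate?** Edges are partitioned into
   intra-cytoband, inter-cytoband CIS (same chromosome) and TRANS
   (different chromosomes); per-region "hotspot" tables count intra-region
   edges and normalise them by the number of possible intra-region pairs.
2. **How does network topology differ between phenotypes?** Clustering,
   modularity, closeness, degree, global efficiency and density of the
   largest connected component, compared across groups.
3. **Does the CIS proportion stratify survival?** Samples are split at
   the median per-sample CIS proportion and compared with Kaplan–Meier
   curves, the log-rank test and a Cox proportional-hazards model,
   optionally at a 5-year (1825-day) endpoint.

A synthetic-data generator with planted structure makes every stage
testable end to end without external data.

## The pipeline, stage by stage

### Preprocessing

Raw counts pass three sequential filters: genes whose mean raw count
falls below the 25th percentile of all gene mean raw counts
(linear-interpolation quantile); genes with zero counts everywhere; and
genes whose mean TMM-normalised count is below 50. The percentile rule is
defined on the raw gene universe, so re-filtering an already-filtered
matrix is a no-op (the output carries a `stage` tag) — this is what makes
filtering idempotent, which re-applying a quantile rule to a shrinking
matrix would otherwise violate. Between-sample normalisation is the
trimmed mean of M-values (TMM) with its canonical trims (30% of M-values,
5% of A-values) via `edgeR::calcNormFactors`; factors are rescaled to
geometric mean 1 and applied as
`count / (library size × factor) × mean library size`.

Two numerical facts worth knowing: TMM is only approximately invariant to
rescaling one library (its precision weights depend on absolute counts,
not proportions), and a single amplified gene perturbs the factor through
the library size even when its M-value is trimmed. The package's tests
assert these properties at the tolerances the arithmetic actually
supports (≈1%).

An optional within-sample GC/length loess correction is provided but off
by default; batch-effect removal is out of scope and exposed only as a
documented no-op hook.

### MI network inference

The pairwise dependence measure is a transparent, oracle-checkable MI
estimator: each expression vector is discretised into `b` equal-frequency
bins by rank (ties broken by original index; default
`b = max(2, floor(n^(1/3)))`), and the plug-in entropy of the joint
histogram gives MI in nats, floored at zero, with an optional
Miller–Madow bias correction `(m_x + m_y − m_xy − 1) / (2n)`. Perfectly
dependent vectors give `log(b)`; a coupled fair binary variable gives
`ln 2`. All `C(G, 2)` pairs are computed at once by one-hot encoding the
discretised genes and forming cross products, which is exact, independent
of sample order and of the internal block partition, and fast enough that
a 300-gene, 100-sample cohort takes well under a second.

Data-processing-inequality (DPI) pruning is available but **off by
default**: for every positive triple, edge (i,j) is zeroed when
`MI(i,j) < min(MI(i,k), MI(j,k)) × (1 − tolerance)`, with all removals
decided on the input matrix. The aggregated network is then the top
`k = 10,000` edges by weight; ties at the cutoff break lexicographically
on the gene pair so every downstream table is reproducible.

### LIONESS single-sample networks

For any deterministic edge scorer `f` and cohort of `N ≥ 3` samples, the
network of sample `q` is

$$e^{(q)} = N\,(e^{(\alpha)} - e^{(\alpha-q)}) + e^{(\alpha-q)}
         = N e^{(\alpha)} - (N-1)\,e^{(\alpha-q)},$$

where `e^(α)` scores the full cohort and `e^(α−q)` the cohort without
`q`. The scorer is pluggable: the MI scorer is the default, and a Pearson
scorer is included because for any scorer that is a per-edge mean of
per-sample statistics the average of the single-sample networks equals
the aggregated network exactly — an algebraic identity the tests verify
to 1e-9. Single-sample networks keep the top 10,000 edges ranked by
**absolute** score (LIONESS scores can be negative), preserving the sign
in the output. The aggregated matrix is computed once and each
single-sample network costs one leave-one-out scoring pass, an
`O(N · G²)` contract with no incremental shortcut (MI does not decompose
per sample).

### Hotspots

Cytoband identity is always the (chromosome, cytoband) pair — cytoband
strings are arbitrary labels and are never parsed for position. The
hotspot proportion divides the intra-region edge count by
`C(n_region_genes, 2)` over the network's gene universe: this is the only
normalisation bounded in [0, 1] at the edge level (1 exactly when the
region's genes form a clique), and matches the order of magnitude of
published per-region proportions. Regions with fewer than two genes are
flagged degenerate with proportion 0. Per-sample argmax counting credits
every region attaining the maximal proportion in that sample's top-k
network; ties credit all tied regions (so counts can exceed the cohort
size, which the output flags), and a sample with no intra-region edges
credits none.

### Topology metrics

All metrics are computed on the binary adjacency of the largest connected
component (ties on node count break by edge count, then smallest node
label): average local clustering with degree-<2 nodes contributing 0,
modularity of the greedy modularity-maximisation partition under a fixed
seed, mean normalised closeness, mean degree, global efficiency (mean
inverse shortest-path length over ordered pairs) and density
`2E/(V(V−1))`. "Centrality" is read as closeness centrality; no separate
betweenness metric is computed. Group comparison uses the two-sided
Mann–Whitney U test of each group against the reference with
Benjamini–Hochberg adjustment across the metric × group family, labelled
`***` below 0.001 and `NS` otherwise — the test and correction are
package choices, recorded in the output, since only significance stars
are conventionally displayed. Aggregated-vs-single-sample coherence is
the Jaccard index of the two top-k edge sets (empty vs empty defined
as 1).

### Survival

The per-sample CIS proportion (CIS edges / k in the sample's top-k
network) is split at the **within-subtype** median; strictly above goes
to "high", ties to "low" (so an all-tied subtype is all "low", with a
warning). Kaplan–Meier estimates use Greenwood-based intervals; the
log-rank test is the standard 1-df two-group statistic; Cox fits a single
binary covariate with Efron tie handling. The 5-year endpoint sets times
above 1825 days to 1825 with the event cleared; exactly 1825 is left
untouched. Subtypes are analysed separately, never pooled.

### Hubs

Per sample, the top 10 genes by degree in the largest component (ties
lexicographic) are "high-degree"; recurrence counts the samples in which
a gene makes that list, and recurrence aggregates conservatively to
(chromosome, cytoband) — the cytoband totals always sum to the gene
totals.

## The synthetic generator

The generator emulates the data regimes the analysis is designed to
distinguish, via a Gaussian copula over a latent correlation structure:

* **cancer-like** cohorts plant high-correlation blocks confined to
  specific cytobands: each block contributes a shared factor giving
  within-block latent correlation `rho` (default: one 30-gene block at
  `rho = 0.8` in a 30-gene cytoband of a 300-gene, 9-chromosome genome);
* **normal-like** cohorts draw `F` global factors loading every gene with
  `λ` (defaults `F = 3`, `λ = 0.25`), producing diffuse cross-chromosome
  correlation `F λ² ≈ 0.19` — TRANS-dominated structure.

The two sources are not mixed within a regime: adding the global factors
on top of a `rho = 0.8` block would push within-block correlation to
`rho + F λ² ≈ 0.99` and change the planted condition. Residual variance
`1 − rho − F λ²` must stay positive or the generator refuses, naming the
offending block. Latent Gaussians map to counts through the
negative-binomial quantile function at the Gaussian CDF value, which
preserves rank correlation (so the MI estimator sees the planted
structure) while giving exactly negative-binomial margins: gene means are
log-normal (`meanlog = 5`, `sdlog = 1`, i.e. typical counts in the tens
to thousands) and dispersion is common (`0.2`, mid-range for bulk
RNA-seq). Survival times are exponential with baseline hazard 0.001/day
(mean 1000 days, a realistic cohort scale), an optional group log-hazard
ratio, and independent exponential censoring whose rate is chosen so the
pre-event censoring probability equals `censoring_rate`.

What the generator deliberately does **not** emulate: read-level noise,
isoforms, batch effects, copy number, gene-length/GC biases coupled to
expression, or any real karyotype — cytoband labels are human-style
strings but arbitrary. Passing tests therefore demonstrate that the
pipeline recovers the statistical structure it assumes, not that any
biological claim about real tumours is reproduced.

Determinism: every generator call reseeds from the configuration's master
seed through a per-stage hash, so identical configurations give
byte-identical annotation, counts and clinical tables, and the full
pipeline re-run writes byte-identical files.

## Numerical choices and degenerate inputs

* Constant vectors occupy a single bin: MI is exactly 0 (with a warning
  in the scalar API). A cohort of identical samples yields
  `e^(q) = e^(α)` for every sample.
* All edge orderings (top-k cutoffs, hotspot tables, hub lists) break
  ties lexicographically in the C locale, making outputs locale- and
  platform-stable.
* The Gaussian CDF value is capped at `1 − 1e-12` before the
  negative-binomial quantile to avoid infinite counts.
* Monte-Carlo replicate seeds are drawn by `sample.int` from a single
  master-seeded stream rather than by arithmetic stride: stride-seeded
  Mersenne-Twister streams showed measurable inter-stream correlation in
  calibration runs.

## Problem sizes used by the test-suite and acceptance script

The suite exercises the full stack at desk scale, chosen to make every
Monte-Carlo bound sharp while keeping the default run fast: 300 genes ×
100 samples for planted-hotspot recovery (the full LIONESS pass over
44,850 pairs × 101 networks takes seconds with the vectorised MI), a
200-gene × 50-sample cohort for the 10,000-edge truncation checks,
n = 500 cohorts for copula-marginal and correlation calibration, 1000
replicates for log-rank type-I error and 300 × n = 500 for Cox recovery
of `log HR = ln 2`.

## Known limitations

* **LIONESS-MI noise amplification.** The leave-one-out equation
  multiplies the difference `e^(α) − e^(α−q)` by `N`. With a discretised
  MI estimator, removing one sample can shift equal-frequency bin
  boundaries and perturb many histogram cells at once, so null pairs
  occasionally reach large `|e^(q)|` and displace genuinely coupled edges
  from a sample's top-k list. At the 300-gene scale the planted cytoband
  still wins the per-sample argmax in the large majority of samples, but
  the per-sample rate fluctuates between simulation seeds; the aggregated
  network's hotspot ranking is far more stable. Smooth scorers (the
  Pearson plug-in) do not show this amplification.
* MI truncation keeps the strongest `k` edges with no significance
  threshold; `k` trades comparability for density and is not adaptive.
* The per-region proportion uses the network's own gene universe as
  denominator; regions sparsely represented after filtering have noisy
  proportions (the degenerate flag marks the extreme case).
* The Mann–Whitney/BH choice for metric comparisons and the greedy
  modularity algorithm are reasonable defaults, not canonical; both are
  recorded in outputs so results are interpretable.
* Survival analysis covers a single binary covariate; no multivariable
  adjustment.
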