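# sscnet

Single-sample gene co-expression networks and intra-chromosomal hotspot
analysis.

## The problem

Aggregated co-expression networks describe a phenotype, not a patient.
`sscnet` is for researchers who want to ask, per sample, *where in the
genome* co-expression concentrates: whether the strongest interactions
connect genes on the same cytoband or chromosome (CIS) or span
chromosomes (TRANS), which regions act as co-expression hotspots, how the
topology of each patient's network differs from a reference cohort, and
whether a patient's intra-chromosomal interaction proportion carries
prognostic signal.

## The method

Starting from a filtered, TMM-normalised count matrix, the package:

1. estimates mutual information for all C(G, 2) gene pairs
   (equal-frequency binning, plug-in entropy in nats, optional
   Miller–Madow correction; optional data-processing-inequality pruning)
   and keeps the top *k* = 10,000 edges as the aggregated network
   *e*^(α);
2. derives one network per sample with the LIONESS leave-one-out
   equation,

   *e*^(q) = N (*e*^(α) − *e*^(α−q)) + *e*^(α−q) = N *e*^(α) − (N−1) *e*^(α−q),

   keeping each sample's top 10,000 edges by |*e*^(q)|;
3. classifies every edge as intra-cytoband, inter-cytoband CIS or TRANS,
   builds per-chromosome / per-cytoband hotspot tables (frequency and
   proportion of possible intra-region pairs), and counts per-sample
   argmax regions;
4. computes largest-component topology metrics (clustering, modularity,
   closeness, degree, global efficiency, density) and compares groups
   (Mann–Whitney U, Benjamini–Hochberg), plus aggregated-vs-sample
   Jaccard overlap;
5. splits samples at the within-subtype median CIS proportion and
   compares survival (Kaplan–Meier, log-rank, Cox with Efron ties),
   optionally at the 5-year endpoint (1825 days);
6. ranks recurrent high-degree genes across single-sample networks and
   localises them to cytobands.

A synthetic-data module generates annotation, negative-binomial counts
(Gaussian copula over planted cytoband blocks or global trans factors)
and exponential survival data, so the entire pipeline is testable with no
external downloads. See `vignettes/sscnet-methods.Rmd` for the models,
defaults and their rationale.

## Worked example

```r
library(sscnet)

cfg    <- sim_config(seed = 7L)             # 300 genes, 100 samples,
                                            # one 30-gene cytoband block, rho = 0.8
ann    <- generate_annotation(cfg)
counts <- generate_expression(cfg, "cancer_like", annotation = ann)
clin   <- generate_clinical(cfg)

fit <- sscn(counts, ann, clinical = clin, k = 10000L,
            preprocess = FALSE, five_year = TRUE)
fit
#> Single-sample co-expression network analysis
#>   genes: 300  samples: 100  k: 10000  MI bins: 4
#>   aggregated network: CIS 14.0% / TRANS 86.0% of 10000 edges
#>   per-sample CIS proportion: median 0.128 (range 0.114-0.139)
#>   survival analysis over 1 subtype(s)

head(summary(fit)$top_cytobands, 3)
#>    region frequency proportion n_genes degenerate
#> 1 1:1p1.1       435  1.0000000      30      FALSE
#> 2 1:1q1.1        76  0.1747126      30      FALSE
#> 3 8:8p1.1        32  0.3047619      15      FALSE
```

The planted cytoband (`1:1p1.1`) is a perfect clique in the aggregated
network: all 435 of its possible gene pairs are among the top 10,000
edges (proportion 1.0), while unplanted regions sit near the background
rate. With a null hazard structure the CIS-based survival split is, as it
should be, non-significant:

```r
fit$survival$cohort$logrank$p_value
#> [1] 0.6698149
fit$survival$cohort$cox$hr
#> [1] 0.8994413
```

`run_pipeline(list(sim = cfg), "out/")` runs both the cancer-like and
normal-like regimes end to end and writes every table (edge lists,
hotspot CSVs, metrics, Jaccard, hubs, CIS proportions) plus a manifest
JSON; reruns with the same configuration are byte-identical.

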