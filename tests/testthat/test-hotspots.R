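test_that("edges classify into the three genomic categories", {
  ann <- tiny_annotation()
  edges <- data.frame(gene_a = c("g1", "g1", "g1"),
                      gene_b = c("g2", "g3", "g5"),
                      weight = 1)
  cls <- classify_edges(edges, ann)
  expect_identical(as.character(cls),
                   c("INTRA_CYTOBAND", "INTER_CYTOBAND_CIS", "TRANS"))
  expect_error(classify_edges(data.frame(gene_a = "g1", gene_b = "zz"),
                              ann), "zz")
})

test_that("cytoband identity requires the chromosome qualifier", {
  ann <- tiny_annotation()
  # same cytoband string on different chromosomes must be TRANS
  ann$cytoband[5:6] <- "8q24.3"
  cls <- classify_edges(data.frame(gene_a = "g1", gene_b = "g5"), ann)
  expect_identical(as.character(cls), "TRANS")
})

test_that("category counts partition the edge set", {
  ann <- tiny_annotation()
  set.seed(77)
  pairs <- t(combn(ann$gene_id, 2))
  edges <- data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2], weight = 1)
  s <- cis_trans_summary(edges, ann)
  expect_identical(unname(s$counts[["INTRA_CYTOBAND"]] +
                            s$counts[["INTER_CYTOBAND_CIS"]] +
                            s$counts[["TRANS"]]),
                   nrow(edges))
  expect_identical(unname(s$counts[["CIS"]]),
                   unname(s$counts[["INTRA_CYTOBAND"]] +
                            s$counts[["INTER_CYTOBAND_CIS"]]))
  # all genes on one chromosome -> no TRANS edges
  one_chr <- ann[1:4, ]
  p <- t(combn(one_chr$gene_id, 2))
  s1 <- cis_trans_summary(data.frame(gene_a = p[, 1], gene_b = p[, 2]),
                          one_chr)
  expect_identical(unname(s1$counts[["TRANS"]]), 0L)
  expect_warning(z <- cis_trans_summary(edges[0, ], ann), "empty")
  expect_identical(unname(z$counts[["total"]]), 0)
})

test_that("hotspot frequencies and pairwise proportions are exact", {
  ann <- data.frame(gene_id = paste0("g", 1:13), chromosome = "1",
                    cytoband = c(rep("1p1.1", 10), rep("1q1.1", 2),
                                 "1q2.1"),
                    start = 1:13, end = 1:13, gc = 0.5, length = 100)
  # 5 intra-band edges among the 10-gene band -> proportion 5/45
  edges <- data.frame(gene_a = paste0("g", 1:5),
                      gene_b = paste0("g", 6:10), weight = 1)
  hs <- region_hotspots(edges, ann, "cytoband")
  row <- hs[hs$region == "1:1p1.1", ]
  expect_identical(row$frequency, 5L)
  expect_equal(row$proportion, 5 / 45, tolerance = 1e-12)
  # fully connected 3-gene chromosome -> proportion 1
  ann3 <- ann[1:3, ]
  e3 <- data.frame(gene_a = c("g1", "g1", "g2"),
                   gene_b = c("g2", "g3", "g3"))
  hc <- region_hotspots(e3, ann3, "chromosome")
  expect_identical(hc$frequency, 3L)
  expect_equal(hc$proportion, 1, tolerance = 1e-12)
  # single-gene region is degenerate with zero proportion
  expect_true(hs[hs$region == "1:1q2.1", "degenerate"])
  expect_identical(hs[hs$region == "1:1q2.1", "proportion"], 0)
  expect_true(all(hs$proportion >= 0 & hs$proportion <= 1))
})

test_that("per-sample argmax credits winners and ties", {
  ann <- tiny_annotation()
  intra8 <- data.frame(gene_a = "g1", gene_b = "g2", weight = 1)
  intra17 <- data.frame(gene_a = "g5", gene_b = "g6", weight = 1)
  both <- rbind(intra8, intra17)
  trans_only <- data.frame(gene_a = "g1", gene_b = "g5", weight = 1)
  res <- per_sample_argmax_regions(list(s1 = intra8, s2 = intra8),
                                   ann, "cytoband")
  expect_identical(res$region, "8:8q24.3")
  expect_identical(res$n_samples, 2L)
  # a sample with no intra-region edge credits nothing
  res2 <- per_sample_argmax_regions(list(s1 = intra8, s2 = trans_only),
                                    ann, "cytoband")
  expect_identical(sum(res2$n_samples), 1L)
  # ties credit all tied regions and are logged
  res3 <- per_sample_argmax_regions(list(s1 = both), ann, "cytoband")
  expect_setequal(res3$region, c("8:8q24.3", "17:17q11.2"))
  expect_identical(attr(res3, "ties"), "s1")
})

test_that("cancer-like cohorts show more CIS edges than normal-like", {
  cfg <- tiny_block_config(seed = 19L, n_samples = 40L)
  ann <- generate_annotation(cfg)
  k <- 150L
  fr <- sapply(c("cancer_like", "normal_like"), function(reg) {
    x <- generate_expression(cfg, reg, annotation = ann)
    mi <- build_mi_matrix(x)
    cis_trans_summary(top_k_edges(mi, k), ann)$fractions[["CIS"]]
  })
  expect_gt(fr[["cancer_like"]], fr[["normal_like"]])
})

test_that("the planted cytoband dominates aggregated and per-sample hotspots", {
  cfg <- tiny_block_config(seed = 23L, n_samples = 50L)
  ann <- generate_annotation(cfg)
  x <- generate_expression(cfg, "cancer_like", annotation = ann)
  k <- 150L
  agg <- top_k_edges(build_mi_matrix(x), k)
  hs <- region_hotspots(agg, ann, "cytoband")
  expect_identical(hs$region[1], "1:1p1.1")
  nets <- all_sample_networks(x, mi_scorer())
  tops <- lapply(nets, top_k_abs, k = k)
  am <- per_sample_argmax_regions(tops, ann, "cytoband")
  expect_identical(am$region[1], "1:1p1.1")
  # at this reduced scale (60 genes, k = 150) LIONESS noise leaves a few
  # samples to chance; the full-scale recovery rate is asserted elsewhere
  expect_gte(am$n_samples[1], 0.6 * ncol(x))
})
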