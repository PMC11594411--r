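toy_counts <- function() {
  set.seed(42)
  m <- matrix(rnbinom(200 * 4, mu = 200, size = 5), 200, 4,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:4)))
  m
}

test_that("TMM factors: identical and scaled libraries give unit factors", {
  m <- toy_counts()
  two <- cbind(a = m[, 1], b = m[, 1])
  f <- tmm_factors(two)
  expect_equal(unname(f$factors), c(1, 1), tolerance = 1e-12)
  doubled <- cbind(a = m[, 1], b = 2L * m[, 1])
  f2 <- tmm_factors(doubled)
  expect_equal(unname(f2$factors), c(1, 1), tolerance = 1e-12)
})

test_that("a single strong outlier gene is trimmed out of the TMM factor", {
  set.seed(7)
  # 1000 unchanged genes plus one low-count gene amplified 10x in B; the
  # outlier is trimmed, so B's factor stays at 1 and the effective
  # library sizes (lib * factor) of A and B agree
  a <- c(50L, rnbinom(1000, mu = 500, size = 10) + 1L)
  b <- a
  b[1] <- a[1] * 10L
  m <- cbind(a = a, b = b)
  rownames(m) <- sprintf("g%04d", seq_len(nrow(m)))
  f <- tmm_factors(m)
  expect_lt(abs(unname(f$factors["b"] / f$factors["a"]) - 1), 0.01)
  eff <- f$lib_size * f$factors
  expect_lt(abs(eff[["b"]] / eff[["a"]] - 1), 0.01)
})

test_that("TMM factors agree with a naive trimmed-mean oracle", {
  m <- toy_counts()
  f <- tmm_factors(m)
  ref <- f$ref_sample
  for (s in setdiff(colnames(m), ref)) {
    expect_equal(unname(f$factors[s] / f$factors[ref]),
                 oracle_tmm_factor(m, s, ref), tolerance = 0.02)
  }
  expect_equal(exp(mean(log(f$factors))), 1, tolerance = 1e-12)
})

test_that("normalization algebra: unit factors and library-doubling", {
  m <- toy_counts()
  # identical columns: factors 1, equal libraries -> output equals input
  same <- m[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(tmm_normalize(same)), unname(same) + 0,
               tolerance = 1e-12)
  # doubling a sample's counts leaves its normalized profile unchanged
  doubled <- m
  doubled[, 2] <- 2L * doubled[, 2]
  n1 <- tmm_normalize(m)
  n2 <- tmm_normalize(doubled)
  # equality holds up to the small scale dependence of the TMM precision
  # weights (w depends on absolute counts, not proportions)
  expect_equal(n2[, 2] / mean(colSums(doubled)),
               n1[, 2] / mean(colSums(m)), tolerance = 0.01)
})

test_that("filter rules act sequentially and report removals", {
  # 0.25-quantile rule on the toy mean vector {1, 10, 100, 1000}
  means <- c(1, 10, 100, 1000)
  thr <- quantile(means, 0.25, names = FALSE)   # 7.75 by interpolation
  m <- matrix(rep(means, each = 6), 4, 6, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  storage.mode(m) <- "integer"
  rep_removed <- attr(filter_genes(m, min_norm_mean = 0), "removal_report")
  expect_identical(rep_removed$gene_id[rep_removed$rule == "quantile_0.25"],
                   paste0("g", which(means < thr)))
  # when >= 25% of genes are all-zero the quantile is 0 and rule 2 catches
  # the zero genes explicitly
  m3 <- matrix(rep(c(0L, 0L, 0L, 100L, 200L, 300L, 400L, 500L, 600L),
                   each = 6), 9, 6, byrow = TRUE,
               dimnames = list(paste0("g", 1:9), paste0("s", 1:6)))
  rep3 <- attr(filter_genes(m3, min_norm_mean = 0), "removal_report")
  expect_setequal(rep3$gene_id[rep3$rule == "all_zero"],
                  paste0("g", 1:3))
})

test_that("the normalized-mean threshold keeps mean 50.1 and drops 49.9", {
  # constant genes with one balanced 49/51 swap: equal libraries, unit
  # factors, so normalized counts equal raw counts and the gene means are
  # exactly 49.9 and 50.1
  lo <- rep(50L, 10); lo[1] <- 49L        # mean 49.9
  hi <- rep(50L, 10); hi[1] <- 51L        # mean 50.1
  m <- rbind(small = rep(10L, 10), lo = lo, hi = hi,
             big = rep(1000L, 10))
  colnames(m) <- paste0("s", 1:10)
  f <- filter_genes(m, min_norm_mean = 50)
  expect_true("hi" %in% rownames(f))
  expect_false("lo" %in% rownames(f))
  expect_true("big" %in% rownames(f))
})

test_that("filtering is idempotent and preserves gene order", {
  m <- toy_counts()
  m[1:5, ] <- 0L
  f1 <- filter_genes(m, min_norm_mean = 50)
  f2 <- filter_genes(f1, min_norm_mean = 50)
  expect_identical(rownames(f1), rownames(f2))
  expect_equal(f1, f2, ignore_attr = TRUE)
  expect_identical(attr(f2, "rule_counts"),
                   c(quantile_0.25 = 0L, all_zero = 0L, tmm_mean = 0L))
  expect_identical(rownames(f1),
                   rownames(m)[rownames(m) %in% rownames(f1)])
})

test_that("degenerate inputs error clearly", {
  m <- toy_counts()
  z <- m; z[, 1] <- 0L
  expect_error(tmm_factors(z), "all-zero")
  expect_error(tmm_factors(m[, 1, drop = FALSE]), "2 samples")
  expect_error(filter_genes(m, min_norm_mean = 1e9), "relax")
})

test_that("GC correction removes a planted GC dependence", {
  set.seed(31)
  G <- 1000
  ann <- data.frame(gene_id = sprintf("g%04d", 1:G),
                    chromosome = "1", cytoband = "1p1.1",
                    start = 1:G, end = 1:G,
                    gc = runif(G, 0.3, 0.7),
                    length = sample(500:5000, G, TRUE))
  counts <- matrix(round(exp(4 + 6 * ann$gc)), G, 3,
                   dimnames = list(ann$gene_id, paste0("s", 1:3)))
  corr <- gc_length_correct(counts, ann)
  expect_lt(abs(cor(corr[, 1], ann$gc, method = "spearman")), 0.05)
  # constant GC and length: identity round-trip
  ann2 <- ann; ann2$gc <- 0.5; ann2$length <- 1000L
  set.seed(32)
  counts2 <- matrix(rnbinom(G * 2, mu = 100, size = 5), G, 2,
                    dimnames = list(ann$gene_id, c("a", "b")))
  expect_equal(gc_length_correct(counts2, ann2), counts2 + 0,
               tolerance = 1e-10)
  expect_error(gc_length_correct(counts[1:5, ], ann[-1, ]), "g0001")
})
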