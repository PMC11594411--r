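mk_edges <- function(...) {
  p <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(gene_a = p[, 1], gene_b = p[, 2], weight = 1,
             stringsAsFactors = FALSE)
}

test_that("largest component selection and tie handling", {
  # two disjoint triangles plus a 4-node path: the path wins on nodes
  edges <- mk_edges("a", "b", "b", "c", "a", "c",
                    "d", "e", "e", "f", "d", "f",
                    "p", "q", "q", "r", "r", "s")
  lcc <- largest_component(edges)
  expect_setequal(unique(c(lcc$gene_a, lcc$gene_b)), c("p", "q", "r", "s"))
  # connected graph returns itself
  tri <- mk_edges("a", "b", "b", "c", "a", "c")
  expect_identical(nrow(largest_component(tri)), 3L)
  # equal components: tie flagged, smallest lexicographic node wins
  two <- mk_edges("a", "b", "c", "d")
  lcc2 <- largest_component(two)
  expect_true(attr(lcc2, "tie"))
  expect_setequal(c(lcc2$gene_a, lcc2$gene_b), c("a", "b"))
  expect_error(largest_component(tri[0, ]), "empty")
})

test_that("metrics reproduce K4 and P4 closed forms", {
  k4 <- mk_edges("a", "b", "a", "c", "a", "d", "b", "c", "b", "d",
                 "c", "d")
  m <- compute_metrics(k4)
  expect_equal(m$avg_clustering, 1, tolerance = 1e-12)
  expect_equal(m$density, 1, tolerance = 1e-12)
  expect_equal(m$global_efficiency, 1, tolerance = 1e-12)
  expect_equal(m$mean_degree, 3, tolerance = 1e-12)
  p4 <- mk_edges("a", "b", "b", "c", "c", "d")
  mp <- compute_metrics(p4)
  expect_equal(mp$density, 0.5, tolerance = 1e-12)
  expect_equal(mp$mean_degree, 1.5, tolerance = 1e-12)
  expect_equal(mp$global_efficiency, oracle_efficiency(p4),
               tolerance = 1e-12)
  expect_equal(mp$global_efficiency, (1 + 0.5 + 1 / 3 + 1 + 0.5 + 1) / 6,
               tolerance = 1e-12)
  expect_error(compute_metrics(k4[0, ]), ".")
})

test_that("two cliques joined by one edge have positive modularity", {
  c1 <- t(combn(c("a", "b", "c", "d"), 2))
  c2 <- t(combn(c("w", "x", "y", "z"), 2))
  edges <- rbind(
    data.frame(gene_a = c1[, 1], gene_b = c1[, 2], weight = 1),
    data.frame(gene_a = c2[, 1], gene_b = c2[, 2], weight = 1),
    data.frame(gene_a = "d", gene_b = "w", weight = 1))
  m <- compute_metrics(edges)
  # direct modularity of the known 2-clique partition as lower bound
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  memb <- (igraph::V(g)$name %in% c("w", "x", "y", "z")) + 1L
  known <- igraph::modularity(g, membership = memb)
  expect_gt(known, 0)
  expect_gte(m$modularity + 1e-12, known)
})

test_that("metrics stay in bounds on random graphs; modularity deterministic", {
  set.seed(99)
  for (r in 1:60) {
    g <- igraph::sample_gnp(sample(5:25, 1), runif(1, 0.1, 0.6))
    g <- igraph::set_vertex_attr(g, "name",
                                 value = sprintf("n%02d",
                                                 seq_len(igraph::vcount(g))))
    e <- igraph::as_data_frame(g)
    if (nrow(e) == 0) next
    edges <- data.frame(gene_a = e$from, gene_b = e$to, weight = 1)
    m <- compute_metrics(largest_component(edges))
    expect_true(m$avg_clustering >= 0 && m$avg_clustering <= 1)
    expect_true(m$modularity >= -0.5 && m$modularity <= 1)
    expect_true(m$global_efficiency >= 0 && m$global_efficiency <= 1)
    expect_true(m$density >= 0 && m$density <= 1)
    expect_gte(m$mean_closeness, 0)
    # single-community modularity (= 0) never beats the greedy partition
    expect_gte(m$modularity, 0 - 1e-12)
  }
  # determinism for fixed seed
  e <- mk_edges("a", "b", "b", "c", "c", "a", "c", "d", "d", "e")
  expect_identical(compute_metrics(e, seed = 42L),
                   compute_metrics(e, seed = 42L))
})

test_that("group comparison flags large shifts and not identical groups", {
  set.seed(4)
  base <- data.frame(avg_clustering = runif(30), modularity = runif(30),
                     mean_closeness = runif(30), mean_degree = runif(30),
                     global_efficiency = runif(30), density = runif(30))
  shifted <- base + 10
  res <- compare_groups(list(normal = base, cancer = shifted),
                        reference = "normal")
  expect_true(all(res$p_adjusted < 0.001))
  expect_true(all(res$label == "***"))
  same <- compare_groups(list(normal = base, other = base),
                         reference = "normal")
  expect_true(all(same$p_value > 0.9))
  expect_true(all(same$label == "NS"))
  # permuting record order changes nothing
  perm <- compare_groups(list(normal = base[sample(30), ],
                              other = base), reference = "normal")
  expect_equal(perm$p_value, same$p_value, tolerance = 1e-12)
  expect_error(compare_groups(list(normal = base, tiny = base[1:2, ]),
                              "normal"), ">= 3")
})

test_that("jaccard obeys its closed forms and symmetry", {
  a <- mk_edges("a", "b", "b", "c", "c", "d")
  expect_identical(jaccard(a, a), 1)
  b <- mk_edges("x", "y")
  expect_identical(jaccard(a, b), 0)
  # order of genes within an edge does not matter
  a_rev <- data.frame(gene_a = a$gene_b, gene_b = a$gene_a, weight = 1)
  expect_identical(jaccard(a, a_rev), 1)
  # |A intersect B| = 1, |A union B| = 3 -> 1/3
  c1 <- mk_edges("a", "b", "b", "c")
  c2 <- mk_edges("a", "b", "x", "y")
  expect_equal(jaccard(c1, c2), 1 / 3, tolerance = 1e-12)
  expect_identical(jaccard(c1, c2), jaccard(c2, c1))
  expect_identical(jaccard(a[0, ], a[0, ]), 1)
})
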