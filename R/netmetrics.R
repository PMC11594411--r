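# Topology metrics on the largest connected component of a top-k edge set.
# Edges are treated as a binary adjacency (weights ignored), matching the
# top-k truncation framing.

edges_to_graph <- function(edges) {
  igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                directed = FALSE)
}

#' Largest connected component of an edge list
#'
#' Ties on node count are broken by edge count, then by smallest
#' lexicographic node label (logged via the \code{"tie"} attribute).
#'
#' @param edges data.frame gene_a, gene_b (weight carried through).
#' @return the edge rows of the largest component.
#' @export
largest_component <- function(edges) {
  if (nrow(edges) == 0L) stop("empty edge list")
  g <- edges_to_graph(edges)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  tie <- length(best) > 1L
  if (tie) {
    # edge count per tied component, then smallest lexicographic member
    stats_ <- lapply(best, function(ci) {
      members <- names(comp$membership)[comp$membership == ci]
      sub <- edges$gene_a %in% members & edges$gene_b %in% members
      list(edges = sum(sub), minnode = min(members))
    })
    ne <- vapply(stats_, `[[`, 0, "edges")
    best <- best[ne == max(ne)]
    if (length(best) > 1L) {
      mn <- vapply(stats_[ne == max(ne)], `[[`, "", "minnode")
      best <- best[order(mn, method = "radix")[1L]]
    } else best <- best[1L]
  }
  members <- names(comp$membership)[comp$membership == best[1L]]
  out <- edges[edges$gene_a %in% members & edges$gene_b %in% members, ,
               drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tie") <- tie
  out
}

#' Topology metrics of a connected component
#'
#' Average local clustering coefficient (nodes of degree < 2 contribute
#' 0), modularity of the greedy modularity-maximization partition (fixed
#' seed, deterministic), mean closeness centrality (normalized), mean
#' degree, global efficiency (mean over ordered pairs of inverse shortest
#' path length) and density 2E / (V (V - 1)).
#'
#' @param component connected edge data.frame (e.g. from
#'   \code{\link{largest_component}}).
#' @param seed seed fixed before community detection.
#' @return one-row data.frame of metrics.
#' @export
compute_metrics <- function(component, seed = 1L) {
  g <- edges_to_graph(component)
  g <- igraph::simplify(g)
  V <- igraph::vcount(g)
  if (V < 2L) stop("metrics need a component with >= 2 nodes")
  E <- igraph::ecount(g)
  lc <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  mod <- withr_seed(seed, {
    igraph::modularity(igraph::cluster_fast_greedy(g))
  })
  closeness <- mean(igraph::closeness(g, normalized = TRUE))
  eff <- igraph::global_efficiency(g)
  data.frame(n_nodes_lcc = V,
             n_edges_lcc = E,
             avg_clustering = lc,
             modularity = mod,
             mean_closeness = closeness,
             mean_degree = mean(igraph::degree(g)),
             global_efficiency = eff,
             density = 2 * E / (V * (V - 1)))
}

# evaluate expr under a local seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Compare metric distributions between groups
#'
#' Two-sided Mann-Whitney U of every non-reference group against the
#' reference per metric, with Benjamini-Hochberg adjustment across the
#' whole metric x group family; the significance label follows the
#' three-star convention (\code{***} if adjusted p < 0.001, else
#' \code{NS}).
#'
#' @param records named list of per-group data.frames of
#'   \code{\link{compute_metrics}} rows (>= 3 records per group).
#' @param reference name of the reference group.
#' @param metrics metric columns to test.
#' @return data.frame group, metric, statistic, p_value, p_adjusted,
#'   label.
#' @export
compare_groups <- function(records, reference,
                           metrics = c("avg_clustering", "modularity",
                                       "mean_closeness", "mean_degree",
                                       "global_efficiency", "density")) {
  if (!reference %in% names(records)) stop("unknown reference group")
  if (any(vapply(records, nrow, 0L) < 3L))
    stop("every group needs >= 3 records")
  others <- setdiff(names(records), reference)
  rows <- list()
  for (grp in others) {
    for (m in metrics) {
      x <- records[[grp]][[m]]
      y <- records[[reference]][[m]]
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
      rows[[length(rows) + 1L]] <-
        data.frame(group = grp, metric = m,
                   statistic = unname(wt$statistic), p_value = wt$p.value,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$label <- ifelse(out$p_adjusted < 0.001, "***", "NS")
  out
}

#' Jaccard index of two edge sets
#'
#' Edges are unordered gene pairs; two empty sets have index 1.
#'
#' @param a,b edge data.frames (gene_a, gene_b).
#' @return |A intersect B| / |A union B| in [0, 1].
#' @export
jaccard <- function(a, b) {
  key <- function(e) {
    if (nrow(e) == 0L) return(character(0))
    lo <- pmin(e$gene_a, e$gene_b)
    hi <- pmax(e$gene_a, e$gene_b)
    unique(paste(lo, hi, sep = "|"))
  }
  ka <- key(a)
  kb <- key(b)
  u <- length(union(ka, kb))
  if (u == 0L) return(1)
  length(intersect(ka, kb)) / u
}
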