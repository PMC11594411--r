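# Independent oracles used across the suite. Each deliberately re-derives
# its quantity with naive loops, separate from the package's code paths.

# brute-force MI (nats) from two discrete vectors via explicit joint counts
oracle_mi <- function(bx, by) {
  n <- length(bx)
  ux <- sort(unique(bx)); uy <- sort(unique(by))
  mi <- 0
  for (a in ux) for (b in uy) {
    pxy <- sum(bx == a & by == b) / n
    if (pxy > 0) {
      px <- sum(bx == a) / n
      py <- sum(by == b) / n
      mi <- mi + pxy * log(pxy / (px * py))
    }
  }
  mi
}

# brute-force global efficiency: BFS shortest paths over an adjacency list
oracle_efficiency <- function(edges) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  adj <- lapply(nodes, function(v)
    c(edges$gene_b[edges$gene_a == v], edges$gene_a[edges$gene_b == v]))
  names(adj) <- nodes
  n <- length(nodes)
  total <- 0
  for (s in nodes) {
    dist <- setNames(rep(Inf, n), nodes)
    dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- character(0)
      for (v in frontier) for (w in adj[[v]])
        if (!is.finite(dist[w])) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
      frontier <- unique(nxt)
    }
    total <- total + sum(1 / dist[setdiff(nodes, s)])
  }
  total / (n * (n - 1))
}

# naive TMM factor of sample b against reference r (trim 30% M / 5% A)
oracle_tmm_factor <- function(counts, b, r, trim_m = 0.3, trim_a = 0.05) {
  xb <- counts[, b]; xr <- counts[, r]
  nb <- sum(xb); nr <- sum(xr)
  keep <- xb > 0 & xr > 0
  m <- log2((xb[keep] / nb) / (xr[keep] / nr))
  a <- 0.5 * log2((xb[keep] / nb) * (xr[keep] / nr))
  w <- (nb - xb[keep]) / (nb * xb[keep]) + (nr - xr[keep]) / (nr * xr[keep])
  lo_m <- stats::quantile(m, trim_m); hi_m <- stats::quantile(m, 1 - trim_m)
  lo_a <- stats::quantile(a, trim_a); hi_a <- stats::quantile(a, 1 - trim_a)
  sel <- m >= lo_m & m <= hi_m & a >= lo_a & a <= hi_a
  2^(sum(m[sel] / w[sel]) / sum(1 / w[sel])) # inverse-variance weighted mean
}

# small fixture: annotation with two chromosomes, two cytobands each
tiny_annotation <- function() {
  data.frame(
    gene_id = paste0("g", 1:8),
    chromosome = rep(c("8", "17"), each = 4),
    cytoband = c("8q24.3", "8q24.3", "8p11.23", "8p11.23",
                 "17q11.2", "17q11.2", "17q25.3", "17q25.3"),
    start = rep(c(1, 1001, 2001, 3001), 2),
    end = rep(c(900, 1900, 2900, 3900), 2),
    gc = 0.5, length = 900,
    stringsAsFactors = FALSE)
}

# small planted-block configuration used by several module tests
tiny_block_config <- function(seed = 11L, n_samples = 60L) {
  sim_config(n_genes = 60L, chromosome_sizes = rep(20L, 3L),
             cytobands_per_chromosome = 2L, n_samples = n_samples,
             planted_blocks = list(list(chromosome = "1",
                                        cytoband = "1p1.1",
                                        n_genes = 10L, rho = 0.8)),
             n_trans_factors = 3L, trans_loading = 0.25, seed = seed)
}
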