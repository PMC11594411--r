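# Mutual-information network inference.
#
# Estimator: rank-based equal-frequency discretization (ties broken by
# original index) into b bins, plug-in MI from the joint histogram in nats,
# optional Miller-Madow bias correction, floored at 0. The all-pairs matrix
# is computed by one-hot encoding every discretized gene and taking cross
# products, so all C(G,2) joint histograms come from dense matrix algebra.

#' Equal-frequency discretization
#'
#' Ranks (ties broken by original index) are split into \code{bins}
#' near-equal groups. A constant vector occupies a single bin.
#'
#' @param x numeric vector.
#' @param bins number of bins.
#' @return integer vector of bin indices in 1..bins.
#' @export
discretize_ef <- function(x, bins) {
  n <- length(x)
  if (bins < 1L) stop("bins must be >= 1")
  if (max(x) == min(x)) return(rep(1L, n))
  r <- rank(x, ties.method = "first")
  as.integer(floor((r - 1) * bins / n) + 1L)
}

default_bins <- function(n) max(2L, as.integer(floor(n^(1 / 3))))

# plug-in entropy (nats) of a count vector/matrix
plugin_entropy <- function(counts) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

#' Mutual information between two vectors
#'
#' Plug-in estimate (nats) on the equal-frequency joint histogram;
#' \code{miller_madow = TRUE} adds the first-order bias correction
#' \eqn{(m_x + m_y - m_{xy} - 1) / (2n)} (occupied-cell counts). Constant
#' input occupies a single bin, yielding MI = 0 with a warning.
#'
#' @param x,y numeric vectors of equal length (n >= 8).
#' @param bins bin count; default \code{max(2, floor(n^(1/3)))}.
#' @param miller_madow apply the Miller-Madow correction.
#' @return MI in nats, >= 0.
#' @export
mutual_information <- function(x, y, bins = NULL, miller_madow = FALSE) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 8L) stop("need n >= 8 observations")
  if (is.null(bins)) bins <- default_bins(n)
  if (max(x) == min(x) || max(y) == min(y))
    warning("constant vector: single occupied bin, MI = 0")
  bx <- discretize_ef(x, bins)
  by <- discretize_ef(y, bins)
  joint <- table(factor(bx, levels = 1:bins), factor(by, levels = 1:bins))
  mi <- plugin_entropy(rowSums(joint)) + plugin_entropy(colSums(joint)) -
    plugin_entropy(joint)
  if (miller_madow) {
    mi <- mi + (sum(rowSums(joint) > 0) + sum(colSums(joint) > 0) -
                  sum(joint > 0) - 1) / (2 * n)
  }
  max(mi, 0)
}

#' All-pairs mutual-information matrix
#'
#' Computes MI for every gene pair of a (normalized) expression matrix.
#' Internally each discretized gene becomes a one-hot block so that the
#' cross product of the stacked indicator matrix yields every pairwise
#' joint histogram at once; pairs are processed in gene blocks to bound
#' memory. The result is independent of sample order and of the block
#' partitioning.
#'
#' @param expr genes x samples numeric matrix.
#' @param bins bin count; default \code{max(2, floor(n_samples^(1/3)))}.
#' @param miller_madow apply the Miller-Madow correction per pair.
#' @return symmetric G x G matrix of MI values (nats), zero diagonal, with
#'   attribute \code{"estimator"} describing bins and correction.
#' @export
build_mi_matrix <- function(expr, bins = NULL, miller_madow = FALSE) {
  if (nrow(expr) < 2L) stop("need at least 2 genes")
  if (any(!is.finite(expr))) stop("non-finite values in expression matrix")
  n <- ncol(expr)
  if (n < 8L) stop("need n >= 8 samples")
  if (is.null(bins)) bins <- default_bins(n)
  G <- nrow(expr)
  b <- as.integer(bins)
  # one-hot indicator matrix: n x (G*b)
  disc <- apply(expr, 1L, discretize_ef, bins = b)   # n x G
  D <- matrix(0, n, G * b)
  idx <- rep((seq_len(G) - 1L) * b, each = n) + as.vector(disc)
  D[cbind(rep(seq_len(n), G), idx)] <- 1
  marg <- matrix(colSums(D), b, G)                   # bin counts per gene
  Hg <- apply(marg, 2L, plugin_entropy)
  occ_marg <- colSums(marg > 0)
  # aggregation matrix collapsing bin blocks back to genes
  agg <- function(M, gcols) {
    # M: (m*b) x (G*b) -> block sums (m x G); both dims collapse by b
    m1 <- rowsum(M, rep(seq_along(gcols), each = b))
    t(rowsum(t(m1), rep(seq_len(G), each = b)))
  }
  mi <- matrix(0, G, G, dimnames = list(rownames(expr), rownames(expr)))
  block <- max(1L, min(G, as.integer(2e7 / (G * b * b))))
  for (s in seq(1L, G, by = block)) {
    e <- min(G, s + block - 1L)
    gcols <- s:e
    cols <- as.vector(outer(seq_len(b), (gcols - 1L) * b, `+`))
    C <- crossprod(D[, cols, drop = FALSE], D)       # joint counts
    P <- C / n
    X <- P * log(P)
    X[C == 0] <- 0
    neg_hj <- agg(X, gcols)                          # = -H_joint per pair
    mi[gcols, ] <- Hg[gcols] + rep(Hg, each = length(gcols)) + neg_hj
    if (miller_madow) {
      occ_j <- agg((C > 0) + 0, gcols)
      mi[gcols, ] <- mi[gcols, ] +
        (outer(occ_marg[gcols], occ_marg, `+`) - occ_j - 1) / (2 * n)
    }
  }
  mi[mi < 0] <- 0
  diag(mi) <- 0
  mi <- (mi + t(mi)) / 2   # symmetrize away block-order rounding
  attr(mi, "estimator") <- list(bins = b, miller_madow = miller_madow,
                                n_samples = n,
                                n_pairs = candidate_pair_count(G))
  mi
}

#' Number of candidate gene pairs C(G, 2)
#' @param n_genes gene-universe size.
#' @return the pair count as a double.
#' @export
candidate_pair_count <- function(n_genes) choose(as.numeric(n_genes), 2)

#' Data-processing-inequality pruning (optional, default off)
#'
#' For every triple (i, j, k) with all three MI values positive, the edge
#' (i, j) is zeroed if \code{MI(i,j) < min(MI(i,k), MI(j,k)) * (1 -
#' tolerance)}. All removal decisions are made on the input matrix and
#' applied together, so the result is order-independent.
#'
#' @param mi symmetric MI matrix.
#' @param tolerance DPI tolerance in [0, 1].
#' @return pruned MI matrix.
#' @export
dpi_prune <- function(mi, tolerance = 0) {
  if (tolerance < 0 || tolerance > 1) stop("tolerance must lie in [0, 1]")
  G <- nrow(mi)
  remove <- matrix(FALSE, G, G)
  for (k in seq_len(G)) {
    mk <- mi[, k]
    pos <- mk > 0
    if (sum(pos) < 2L) next
    thr <- outer(mk, mk, pmin) * (1 - tolerance)
    cand <- mi > 0 & outer(pos, pos, `&`) & mi < thr
    cand[k, ] <- FALSE
    cand[, k] <- FALSE
    remove <- remove | cand
  }
  out <- mi
  out[remove] <- 0
  diag(out) <- 0
  attr(out, "estimator") <- attr(mi, "estimator")
  out
}

# upper-triangle edge list with lexicographically ordered gene pairs
matrix_to_edges <- function(m) {
  g <- rownames(m)
  if (is.null(g)) g <- sprintf("g%04d", seq_len(nrow(m)))
  ut <- which(upper.tri(m), arr.ind = TRUE)
  a <- g[ut[, 1L]]
  b <- g[ut[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  data.frame(gene_a = a, gene_b = b, weight = m[ut],
             stringsAsFactors = FALSE)
}

# order edges by descending key then lexicographic pair (C-locale radix)
order_edges <- function(edges, key) {
  edges[order(-key, edges$gene_a, edges$gene_b, method = "radix"), ,
        drop = FALSE]
}

#' Strongest k edges of an MI matrix or edge list
#'
#' Edges are ranked by weight descending; ties at the cutoff are broken by
#' lexicographic (gene_a, gene_b) so truncation is fully reproducible. If
#' fewer than k pairs exist, all are returned with a warning.
#'
#' @param x symmetric weight matrix or data.frame(gene_a, gene_b, weight).
#' @param k number of edges to keep.
#' @return data.frame gene_a, gene_b, weight, sorted, with attribute
#'   \code{"provenance"} = "aggregated".
#' @export
top_k_edges <- function(x, k = 10000L) {
  if (k < 1L) stop("k must be >= 1")
  edges <- if (is.matrix(x)) matrix_to_edges(x) else x
  edges <- order_edges(edges, edges$weight)
  if (nrow(edges) < k) {
    warning("only ", nrow(edges), " candidate pairs available (k = ", k, ")")
    k <- nrow(edges)
  }
  out <- edges[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- "aggregated"
  out
}
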