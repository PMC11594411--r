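# LIONESS single-sample networks.
#
# For a cohort of N samples and any deterministic edge scorer, the network
# of sample q is
#   e(q) = N * (e(alpha) - e(alpha - q)) + e(alpha - q)
#        = N * e(alpha) - (N - 1) * e(alpha - q)
# where e(alpha) scores the full cohort and e(alpha - q) the cohort with q
# held out. Scores may be negative, so single-sample truncation ranks by
# absolute value while preserving sign.

#' Default MI edge scorer
#'
#' Returns a scorer closure computing \code{\link{build_mi_matrix}} with
#' fixed estimator settings, for use with the LIONESS functions.
#'
#' @param bins bin count passed to \code{build_mi_matrix}.
#' @param miller_madow bias-correction flag.
#' @return function(expr) -> symmetric weight matrix.
#' @export
mi_scorer <- function(bins = NULL, miller_madow = FALSE) {
  function(expr) build_mi_matrix(expr, bins = bins,
                                 miller_madow = miller_madow)
}

#' Pearson-correlation edge scorer
#'
#' Linear alternative scorer (weights in [-1, 1]); useful because for any
#' scorer that is a per-edge mean of per-sample statistics the mean of the
#' single-sample networks equals the aggregated network exactly.
#'
#' @return function(expr) -> symmetric correlation matrix, zero diagonal.
#' @export
pearson_scorer <- function() {
  function(expr) {
    m <- stats::cor(t(expr))
    diag(m) <- 0
    m
  }
}

#' LIONESS network for one sample
#'
#' @param expr genes x samples cohort matrix (N >= 3).
#' @param score_fn deterministic cohort scorer (matrix -> symmetric weight
#'   matrix), e.g. \code{\link{mi_scorer}()}.
#' @param q sample ID or column index to extract.
#' @param e_alpha optional precomputed full-cohort score matrix.
#' @return object of class \code{"sample_network"}: list with sample_id,
#'   edges (gene_a, gene_b, weight), N, and the aggregated/leave-one-out
#'   weights for the identity check.
#' @export
lioness_scores <- function(expr, score_fn, q, e_alpha = NULL) {
  N <- ncol(expr)
  if (N < 3L) stop("LIONESS needs N >= 3 samples")
  if (is.character(q)) q <- match(q, colnames(expr))
  if (is.na(q) || q < 1L || q > N) stop("unknown sample")
  if (is.null(e_alpha)) e_alpha <- score_fn(expr)
  e_loo <- score_fn(expr[, -q, drop = FALSE])
  e_q <- N * e_alpha - (N - 1) * e_loo
  edges <- matrix_to_edges(e_q)
  structure(list(sample_id = colnames(expr)[q],
                 edges = edges,
                 N = N,
                 e_alpha = matrix_to_edges(e_alpha)$weight,
                 e_loo = matrix_to_edges(e_loo)$weight),
            class = "sample_network")
}

#' LIONESS networks for every sample of a cohort
#'
#' The aggregated score matrix is computed once; each sample's network then
#' needs one leave-one-out scoring pass, so the cost is N + 1 scorer calls
#' (O(N * G^2) for the MI scorer). Output order follows column order but
#' each network depends only on its own sample.
#'
#' @inheritParams lioness_scores
#' @return named list of \code{"sample_network"} objects.
#' @export
all_sample_networks <- function(expr, score_fn) {
  N <- ncol(expr)
  if (N < 3L) stop("LIONESS needs N >= 3 samples")
  e_alpha <- score_fn(expr)
  nets <- lapply(seq_len(N), function(q)
    lioness_scores(expr, score_fn, q, e_alpha = e_alpha))
  names(nets) <- colnames(expr)
  nets
}

#' Strongest k edges of a single-sample network by absolute score
#'
#' Ranks by |weight| descending (LIONESS scores may be negative), breaking
#' ties lexicographically; the signed weight is retained in the output.
#'
#' @param net a \code{"sample_network"} or data.frame of edges.
#' @param k edges to keep.
#' @return data.frame gene_a, gene_b, weight with attribute
#'   \code{"provenance"} = "single_sample".
#' @export
top_k_abs <- function(net, k = 10000L) {
  if (k < 1L) stop("k must be >= 1")
  edges <- if (inherits(net, "sample_network")) net$edges else net
  edges <- order_edges(edges, abs(edges$weight))
  k <- min(k, nrow(edges))
  out <- edges[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- "single_sample"
  out
}

#' @export
print.sample_network <- function(x, ...) {
  cat("LIONESS single-sample network for", x$sample_id,
      "(cohort N =", x$N, ")\n")
  cat(nrow(x$edges), "gene pairs; |weight| range",
      sprintf("%.4g .. %.4g\n", min(abs(x$edges$weight)),
              max(abs(x$edges$weight))))
  invisible(x)
}
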