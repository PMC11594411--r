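# Count filtering and TMM normalization.
#
# Filtering applies three rules sequentially on the shrinking matrix:
# (1) drop genes whose mean raw count falls below the 25th percentile of all
# gene mean raw counts, (2) drop genes with zero counts in every sample,
# (3) drop genes whose mean TMM-normalized count is below `min_norm_mean`
# (default 50).

#' TMM scale factors
#'
#' Trimmed mean of M-values between-sample normalization (trim 30% of
#' M-values and 5% of A-values, genes with a zero in either sample
#' excluded; reference sample = the one whose upper-quartile count fraction
#' is closest to the mean upper quartile). Computation is delegated to
#' \code{edgeR::calcNormFactors}; factors are rescaled to geometric mean 1.
#'
#' @param counts genes x samples count matrix, >= 2 samples.
#' @return list with \code{factors} (named, geometric mean 1),
#'   \code{ref_sample}, \code{lib_size}.
#' @export
tmm_factors <- function(counts) {
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  f <- f / exp(mean(log(f)))
  # reference: upper-quartile of scaled counts closest to the mean UQ
  uq <- apply(counts, 2L, function(x) stats::quantile(x / sum(x), 0.75))
  ref <- colnames(counts)[which.min(abs(uq - mean(uq)))]
  names(f) <- colnames(counts)
  list(factors = f, ref_sample = ref, lib_size = lib)
}

#' Apply TMM factors to a count matrix
#'
#' value(g, s) = count(g, s) / (lib_size(s) * factor(s)) * mean(lib_size),
#' i.e. counts rescaled to effective library sizes and re-expressed on the
#' scale of the mean library.
#'
#' @param counts genes x samples matrix.
#' @param factors result of \code{\link{tmm_factors}} (recomputed if NULL).
#' @return normalized numeric matrix of the same shape.
#' @export
tmm_normalize <- function(counts, factors = NULL) {
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- factors$lib_size * factors$factors[colnames(counts)]
  sweep(counts, 2L, eff, `/`) * mean(factors$lib_size)
}

#' Filter lowly expressed genes
#'
#' Applies, in order: the 0.25-quantile rule on gene mean raw counts
#' (linear-interpolation quantile), the all-zero rule, and the
#' mean-TMM-normalized-count threshold (strictly below
#' \code{min_norm_mean} removes). Rules act sequentially on the shrinking
#' matrix; the removal report records which rule removed each gene.
#'
#' @param counts raw genes x samples count matrix.
#' @param min_norm_mean normalized-mean threshold (default 50).
#' @return filtered matrix with attribute \code{"removal_report"}
#'   (data.frame gene_id, rule) and \code{"rule_counts"}.
#' @export
filter_genes <- function(counts, min_norm_mean = 50) {
  report <- data.frame(gene_id = character(0), rule = character(0),
                       stringsAsFactors = FALSE)
  # rule 1: below the 25th percentile of gene mean raw counts. The
  # percentile refers to the raw gene universe, so a matrix already tagged
  # as filtered skips it (this is what makes filtering idempotent; rules 2
  # and 3 are idempotent on their own).
  gm <- rowMeans(counts)
  if (identical(attr(counts, "stage"), "filtered")) {
    drop1 <- rep(FALSE, nrow(counts))
  } else {
    thr <- stats::quantile(gm, 0.25, type = 7, names = FALSE)
    drop1 <- gm < thr
  }
  report <- rbind(report, data.frame(
    gene_id = rownames(counts)[drop1],
    rule = rep("quantile_0.25", sum(drop1))))
  m <- counts[!drop1, , drop = FALSE]
  # rule 2: zero in every sample
  drop2 <- rowSums(m) == 0
  report <- rbind(report, data.frame(
    gene_id = rownames(m)[drop2],
    rule = rep("all_zero", sum(drop2))))
  m <- m[!drop2, , drop = FALSE]
  if (nrow(m) == 0L)
    stop("no genes left after zero/quantile filtering; relax thresholds")
  # rule 3: mean TMM-normalized count below threshold
  norm <- tmm_normalize(m)
  drop3 <- rowMeans(norm) < min_norm_mean
  report <- rbind(report, data.frame(
    gene_id = rownames(m)[drop3],
    rule = rep(sprintf("tmm_mean_lt_%g", min_norm_mean), sum(drop3))))
  m <- m[!drop3, , drop = FALSE]
  if (nrow(m) == 0L)
    stop("no genes left after the normalized-mean filter; ",
         "relax min_norm_mean")
  attr(m, "stage") <- "filtered"
  attr(m, "removal_report") <- report
  attr(m, "rule_counts") <- c(quantile_0.25 = sum(drop1),
                              all_zero = sum(drop2),
                              tmm_mean = sum(drop3))
  m
}

#' Optional GC / length correction (default off in the pipeline)
#'
#' Per sample, regresses log(count + 0.5) on GC fraction and then the
#' residuals on log(length) with loess smooths; residuals are re-centered
#' to the sample mean, exponentiated, and the 0.5 offset removed (floored
#' at zero). With constant GC and length the input is returned unchanged.
#'
#' @param counts genes x samples matrix.
#' @param annotation annotation with gc and length for every gene.
#' @return corrected matrix.
#' @export
gc_length_correct <- function(counts, annotation) {
  idx <- match(rownames(counts), annotation$gene_id)
  if (anyNA(idx))
    stop("annotation missing gene(s): ",
         paste(rownames(counts)[is.na(idx)], collapse = ", "))
  gc <- annotation$gc[idx]
  loglen <- log(annotation$length[idx])
  out <- counts
  for (s in seq_len(ncol(counts))) {
    l <- log(counts[, s] + 0.5)
    r <- l - mean(l)
    if (stats::sd(gc) > 0)
      r <- stats::residuals(stats::loess(r ~ gc, degree = 1))
    if (stats::sd(loglen) > 0)
      r <- stats::residuals(stats::loess(r ~ loglen, degree = 1))
    out[, s] <- pmax(exp(r + mean(l)) - 0.5, 0)
  }
  out
}
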