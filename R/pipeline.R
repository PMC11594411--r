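# End-to-end single-cohort analysis and its S3 front-end.

#' Single-sample co-expression network analysis of one cohort
#'
#' Runs the full chain on a count matrix: optional gene filtering and TMM
#' normalization, all-pairs mutual information, optional DPI pruning,
#' top-k truncation to the aggregated network, LIONESS single-sample
#' networks (top-k by absolute score each), CIS/TRANS and cytoband
#' classification, per-region hotspot tables, per-sample argmax-region
#' counts, largest-component topology metrics, aggregated-vs-sample
#' Jaccard indices, hub recurrence, and — when a clinical table is given
#' — the median-CIS survival comparison.
#'
#' @param counts genes x samples raw count matrix (or already-normalized
#'   matrix with \code{preprocess = FALSE}).
#' @param annotation gene annotation (gene_id, chromosome, cytoband, ...).
#' @param clinical optional clinical table (sample_id, time_days, event,
#'   optionally subtype).
#' @param k number of edges kept in every truncated network.
#' @param bins MI bin count (default \code{max(2, floor(n^(1/3)))}).
#' @param miller_madow MI bias-correction flag.
#' @param dpi apply DPI pruning to the aggregated MI matrix.
#' @param dpi_tolerance DPI tolerance.
#' @param preprocess run \code{filter_genes} + TMM normalization first.
#' @param min_norm_mean normalized-mean filter threshold.
#' @param top_n_hubs per-sample high-degree cutoff.
#' @param five_year truncate survival at 1825 days.
#' @param seed seed for the (deterministic-given-seed) community
#'   detection step.
#' @return object of class \code{"sscn"}.
#' @export
sscn <- function(counts, annotation, clinical = NULL, k = 10000L,
                 bins = NULL, miller_madow = FALSE, dpi = FALSE,
                 dpi_tolerance = 0.15, preprocess = TRUE,
                 min_norm_mean = 50, top_n_hubs = 10L,
                 five_year = FALSE, seed = 1L) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  expr <- counts
  removal <- NULL
  if (preprocess) {
    expr <- filter_genes(expr, min_norm_mean = min_norm_mean)
    removal <- attr(expr, "removal_report")
    expr <- tmm_normalize(expr)
  }
  ann_used <- annotation[annotation$gene_id %in% rownames(expr), ,
                         drop = FALSE]
  scorer <- mi_scorer(bins = bins, miller_madow = miller_madow)
  mi <- scorer(expr)
  mi_for_edges <- if (dpi) dpi_prune(mi, dpi_tolerance) else mi
  agg <- top_k_edges(mi_for_edges, k)
  nets <- all_sample_networks(expr, scorer)
  sample_edges <- lapply(nets, top_k_abs, k = k)
  cis <- vapply(sample_edges, function(e)
    cis_trans_summary(e, ann_used)$fractions[["CIS"]], 0)
  metrics <- do.call(rbind, lapply(names(sample_edges), function(s) {
    cbind(sample_id = s,
          compute_metrics(largest_component(sample_edges[[s]]), seed = seed))
  }))
  res <- list(
    expr = expr,
    annotation = ann_used,
    removal_report = removal,
    mi_estimator = attr(mi, "estimator"),
    aggregated = agg,
    aggregated_summary = cis_trans_summary(agg, ann_used),
    aggregated_hotspots = list(
      chromosome = region_hotspots(agg, ann_used, "chromosome"),
      cytoband = region_hotspots(agg, ann_used, "cytoband")),
    sample_networks = sample_edges,
    cis_proportion = cis,
    argmax = list(
      chromosome = per_sample_argmax_regions(sample_edges, ann_used,
                                             "chromosome"),
      cytoband = per_sample_argmax_regions(sample_edges, ann_used,
                                           "cytoband")),
    metrics = metrics,
    jaccard = sort(vapply(sample_edges, jaccard, 0, b = agg),
                   decreasing = TRUE),
    hubs = hub_recurrence(sample_edges, top_n = top_n_hubs),
    k = k,
    call = match.call()
  )
  res$hub_cytobands <- hub_cytoband_distribution(res$hubs, ann_used)
  if (!is.null(clinical))
    res$survival <- cis_survival_analysis(cis, clinical,
                                          five_year = five_year)
  class(res) <- "sscn"
  res
}

#' @export
print.sscn <- function(x, ...) {
  cat("Single-sample co-expression network analysis\n")
  cat(sprintf("  genes: %d  samples: %d  k: %d  MI bins: %d\n",
              nrow(x$expr), ncol(x$expr), x$k, x$mi_estimator$bins))
  fr <- x$aggregated_summary$fractions
  cat(sprintf("  aggregated network: CIS %.1f%% / TRANS %.1f%% of %d edges\n",
              100 * fr[["CIS"]], 100 * fr[["TRANS"]], nrow(x$aggregated)))
  cat(sprintf("  per-sample CIS proportion: median %.3f (range %.3f-%.3f)\n",
              stats::median(x$cis_proportion), min(x$cis_proportion),
              max(x$cis_proportion)))
  if (!is.null(x$survival))
    cat("  survival analysis over", length(x$survival), "subtype(s)\n")
  invisible(x)
}

#' @export
summary.sscn <- function(object, ...) {
  top_chr <- utils::head(object$aggregated_hotspots$chromosome, 3)
  top_band <- utils::head(object$aggregated_hotspots$cytoband, 3)
  out <- list(
    n_genes = nrow(object$expr),
    n_samples = ncol(object$expr),
    k = object$k,
    aggregated_counts = object$aggregated_summary$counts,
    top_chromosomes = top_chr,
    top_cytobands = top_band,
    cis_proportion = summary(object$cis_proportion),
    median_jaccard = stats::median(object$jaccard),
    top_hubs = utils::head(object$hubs, 10),
    metric_medians = vapply(
      object$metrics[, !(names(object$metrics) %in% "sample_id")],
      stats::median, 0)
  )
  class(out) <- "summary.sscn"
  out
}

#' @export
print.summary.sscn <- function(x, ...) {
  cat("sscn analysis:", x$n_genes, "genes x", x$n_samples,
      "samples, top", x$k, "edges per network\n\n")
  cat("Aggregated edge categories:\n")
  print(x$aggregated_counts)
  cat("\nTop chromosomes by intra-chromosomal edges:\n")
  print(x$top_chromosomes)
  cat("\nTop cytobands by intra-cytoband edges:\n")
  print(x$top_cytobands)
  cat("\nPer-sample CIS proportion:\n")
  print(x$cis_proportion)
  cat(sprintf("\nMedian aggregated-vs-sample Jaccard: %.3f\n",
              x$median_jaccard))
  cat("\nMost recurrent high-degree genes:\n")
  print(x$top_hubs)
  invisible(x)
}

#' Plot an sscn analysis
#'
#' Two base-graphics panels: the per-sample Jaccard indices against the
#' aggregated network in descending order, and the per-sample CIS/TRANS
#' proportions.
#'
#' @param x an \code{"sscn"} object.
#' @param ... ignored.
#' @export
plot.sscn <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$jaccard, type = "h", lwd = 2,
                 xlab = "sample (sorted)", ylab = "Jaccard index",
                 main = "Aggregated vs single-sample overlap",
                 ylim = c(0, 1))
  graphics::boxplot(list(CIS = x$cis_proportion,
                         TRANS = 1 - x$cis_proportion),
                    ylab = "fraction of top-k edges",
                    main = "Edge location per sample")
  invisible(x)
}

#' Run the full two-regime demo pipeline and write all outputs
#'
#' Convenience driver gluing the stages together from a configuration
#' list: simulates (or reads) the cohort tables, analyses each regime
#' with \code{\link{sscn}}, writes every table plus a manifest JSON, and
#' returns the analyses invisibly. Reruns with the same config are
#' byte-identical.
#'
#' @param config list with either \code{sim} (a \code{\link{sim_config}})
#'   or paths \code{expression}/\code{annotation}/\code{clinical}, plus
#'   optional k, bins, dpi, dpi_tolerance, top_n_hubs, five_year, seed.
#' @param outdir output directory.
#' @return invisibly, a named list of \code{"sscn"} objects.
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  k <- config$k %||% 10000L
  seed <- config$seed %||% 1L
  if (!is.null(config$sim)) {
    ann <- generate_annotation(config$sim)
    cohorts <- list(
      cancer_like = generate_expression(config$sim, "cancer_like",
                                        annotation = ann),
      normal_like = generate_expression(config$sim, "normal_like",
                                        annotation = ann))
    clinical <- generate_clinical(config$sim)
  } else {
    ann <- read_annotation(config$annotation)
    cohorts <- list(cohort = read_expression(config$expression))
    clinical <- if (!is.null(config$clinical))
      read_clinical(config$clinical)
  }
  analyses <- list()
  files <- character(0)
  for (nm in names(cohorts)) {
    fit <- sscn(cohorts[[nm]], ann, clinical = clinical, k = k,
                bins = config$bins, dpi = isTRUE(config$dpi),
                dpi_tolerance = config$dpi_tolerance %||% 0.15,
                preprocess = !isFALSE(config$preprocess),
                top_n_hubs = config$top_n_hubs %||% 10L,
                five_year = isTRUE(config$five_year), seed = seed)
    analyses[[nm]] <- fit
    pre <- function(f) file.path(outdir, paste0(nm, "_", f))
    write_edges(fit$aggregated, pre("aggregated_edges.tsv"))
    utils::write.csv(fit$aggregated_hotspots$chromosome,
                     pre("hotspots_chromosome.csv"), row.names = FALSE)
    utils::write.csv(fit$aggregated_hotspots$cytoband,
                     pre("hotspots_cytoband.csv"), row.names = FALSE)
    utils::write.csv(fit$metrics, pre("metrics.csv"), row.names = FALSE)
    utils::write.csv(data.frame(sample_id = names(fit$jaccard),
                                jaccard = unname(fit$jaccard)),
                     pre("jaccard.csv"), row.names = FALSE)
    utils::write.csv(fit$hubs, pre("hubs.csv"), row.names = FALSE)
    utils::write.csv(data.frame(sample_id = names(fit$cis_proportion),
                                cis_proportion =
                                  unname(fit$cis_proportion)),
                     pre("cis_proportion.csv"), row.names = FALSE)
    files <- c(files, pre(c("aggregated_edges.tsv",
                            "hotspots_chromosome.csv",
                            "hotspots_cytoband.csv", "metrics.csv",
                            "jaccard.csv", "hubs.csv",
                            "cis_proportion.csv")))
  }
  manifest <- list(
    package = "sscnet",
    version = as.character(utils::packageVersion("sscnet")),
    seed = seed, k = k,
    cohorts = names(cohorts),
    estimator = analyses[[1L]]$mi_estimator,
    files = basename(files))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(analyses)
}
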