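# Synthetic cohort generator: annotation, counts, clinical tables with the
# latent structure the downstream network analysis assumes.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator into a validated
#' object. The latent model is a Gaussian copula: each sample draws a
#' standard-normal latent vector with correlation
#' \eqn{\Sigma = I + \sum_b \rho_b} (on within-block off-diagonals)
#' \eqn{+ F \lambda^2} (from \code{n_trans_factors} global factors with
#' common loading \code{trans_loading}), which is pushed through the
#' negative-binomial quantile function to integer counts.
#'
#' @param n_genes total number of genes.
#' @param chromosome_sizes integer vector of genes per chromosome; must sum
#'   to \code{n_genes}.
#' @param cytobands_per_chromosome cytobands on every chromosome; genes are
#'   split as evenly as possible among them.
#' @param n_samples cohort size.
#' @param planted_blocks list of blocks, each a list with elements
#'   \code{chromosome}, \code{cytoband}, \code{n_genes}, \code{rho} (target
#'   within-block latent correlation in [0,1)). Blocks drive the
#'   \code{cancer_like} regime.
#' @param n_trans_factors number of global latent factors (the
#'   \code{normal_like} regime's cross-chromosome correlation source).
#' @param trans_loading common factor loading in [0,1); pairwise latent
#'   correlation induced by the factors is \code{n_trans_factors *
#'   trans_loading^2}.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   \eqn{\mu + \phi \mu^2}); shared by all genes.
#' @param mean_log_mu,sd_log_mu log-normal parameters of the per-gene mean.
#' @param seed integer master seed; every generator call derives a named
#'   substream from it, so identical configs give byte-identical output.
#' @param baseline_hazard exponential event hazard per day.
#' @param log_hazard_ratio additive log-hazard for the \code{"high"} group.
#' @param censoring_rate target probability that a subject is censored
#'   before its event, in [0,1).
#' @return an object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_genes = 300L,
                       chromosome_sizes = c(60L, rep(30L, 8L)),
                       cytobands_per_chromosome = 2L,
                       n_samples = 100L,
                       planted_blocks = list(list(chromosome = "1",
                                                  cytoband = "1p1.1",
                                                  n_genes = 30L,
                                                  rho = 0.8)),
                       n_trans_factors = 3L,
                       trans_loading = 0.25,
                       nb_dispersion = 0.2,
                       mean_log_mu = 5,
                       sd_log_mu = 1,
                       seed = 1L,
                       baseline_hazard = 0.001,
                       log_hazard_ratio = 0,
                       censoring_rate = 0.3) {
  if (n_genes < 1L) stop("n_genes must be a positive integer")
  if (sum(chromosome_sizes) != n_genes)
    stop("chromosome_sizes sum (", sum(chromosome_sizes),
         ") does not equal n_genes (", n_genes, ")")
  if (any(chromosome_sizes < 1L)) stop("every chromosome needs >= 1 gene")
  if (cytobands_per_chromosome < 1L)
    stop("cytobands_per_chromosome must be positive")
  if (n_samples < 1L) stop("n_samples must be positive")
  if (n_trans_factors < 0L) stop("n_trans_factors must be non-negative")
  if (trans_loading < 0 || trans_loading >= 1)
    stop("trans_loading must lie in [0, 1)")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (sd_log_mu <= 0) stop("sd_log_mu must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must lie in [0, 1)")
  for (b in planted_blocks) {
    if (is.null(b$chromosome) || is.null(b$cytoband) ||
        is.null(b$n_genes) || is.null(b$rho))
      stop("each planted block needs chromosome, cytoband, n_genes, rho")
    if (b$rho < 0 || b$rho >= 1)
      stop("block ", b$cytoband, ": rho must lie in [0, 1)")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    chromosome_sizes = as.integer(chromosome_sizes),
    cytobands_per_chromosome = as.integer(cytobands_per_chromosome),
    n_samples = as.integer(n_samples),
    planted_blocks = planted_blocks,
    n_trans_factors = as.integer(n_trans_factors),
    trans_loading = trans_loading,
    nb_dispersion = nb_dispersion,
    mean_log_mu = mean_log_mu,
    sd_log_mu = sd_log_mu,
    seed = as.integer(seed),
    baseline_hazard = baseline_hazard,
    log_hazard_ratio = log_hazard_ratio,
    censoring_rate = censoring_rate
  ), class = "sim_config")
}

# Deterministic per-stage substream seed: mixes the full 31-bit master seed
# with a stage-name hash, modulo 2^31 - 1 (all arithmetic exact in doubles).
stage_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 99991
  s <- abs(as.numeric(seed))
  lo <- s %% 65536
  hi <- (s - lo) / 65536
  as.integer((lo * 40503 + hi * 30103 + h * 7919) %% (2^31 - 1))
}

#' Generate a synthetic gene annotation table
#'
#' Genes are assigned to chromosomes in configuration order; within a
#' chromosome they are split as evenly as possible among its cytobands and
#' given non-overlapping, increasing 1-based coordinate intervals. Cytoband
#' labels are human-style strings ("1p1.1") but are arbitrary identifiers:
#' nothing downstream parses them for position, and a cytoband is only
#' unique together with its chromosome.
#'
#' @param config a \code{\link{sim_config}}.
#' @return data.frame with columns gene_id, chromosome, cytoband, start,
#'   end, gc, length.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "annotation"))
  G <- config$n_genes
  sizes <- config$chromosome_sizes
  nb <- config$cytobands_per_chromosome
  chrom <- rep(as.character(seq_along(sizes)), sizes)
  cyto <- character(G)
  pos <- 1L
  for (ci in seq_along(sizes)) {
    n <- sizes[ci]
    base <- n %/% nb
    extra <- n %% nb
    band_sizes <- rep(base, nb) + c(rep(1L, extra), rep(0L, nb - extra))
    arm <- ifelse(seq_len(nb) <= ceiling(nb / 2), "p", "q")
    within <- ave(seq_len(nb), arm, FUN = seq_along)
    labels <- sprintf("%d%s%d.1", ci, arm, within)
    cyto[pos:(pos + n - 1L)] <- rep(labels, band_sizes)
    pos <- pos + n
  }
  len <- as.integer(round(stats::runif(G, 500, 5000)))
  # per-chromosome increasing, non-overlapping intervals
  start <- integer(G)
  end <- integer(G)
  for (ci in as.character(seq_along(sizes))) {
    idx <- which(chrom == ci)
    gaps <- as.integer(round(stats::runif(length(idx), 100, 1000)))
    s <- cumsum(c(1L, (len[idx] + gaps)[-length(idx)]))
    start[idx] <- s
    end[idx] <- s + len[idx] - 1L
  }
  data.frame(
    gene_id = sprintf("g%04d", seq_len(G)),
    chromosome = chrom,
    cytoband = cyto,
    start = start,
    end = end,
    gc = round(stats::runif(G, 0.3, 0.7), 4),
    length = len,
    stringsAsFactors = FALSE
  )
}

# Latent loading layout for one regime; errors if the implied covariance is
# not positive semi-definite (residual variance would go negative).
latent_layout <- function(config, annotation, regime) {
  G <- config$n_genes
  rho_g <- numeric(G)
  block_id <- integer(G)
  if (regime == "cancer_like") {
    for (bi in seq_along(config$planted_blocks)) {
      b <- config$planted_blocks[[bi]]
      in_band <- which(annotation$chromosome == as.character(b$chromosome) &
                         annotation$cytoband == b$cytoband)
      if (length(in_band) < b$n_genes)
        stop("planted block ", b$cytoband, " requests ", b$n_genes,
             " genes but its cytoband holds only ", length(in_band))
      sel <- in_band[seq_len(b$n_genes)]
      if (any(block_id[sel] != 0L))
        stop("planted blocks overlap at cytoband ", b$cytoband)
      block_id[sel] <- bi
      rho_g[sel] <- b$rho
    }
  }
  nf <- if (regime == "normal_like") config$n_trans_factors else 0L
  lam <- if (nf > 0L) config$trans_loading else 0
  resid_var <- 1 - rho_g - nf * lam^2
  if (any(resid_var <= 0)) {
    bad <- unique(block_id[resid_var <= 0])
    bad <- bad[bad != 0L]
    lab <- if (length(bad)) {
      paste(vapply(config$planted_blocks[bad], `[[`, "", "cytoband"),
            collapse = ", ")
    } else "factor structure"
    stop("latent covariance not positive semi-definite (", lab,
         "): rho + n_trans_factors * trans_loading^2 must stay below 1")
  }
  list(rho_g = rho_g, block_id = block_id, n_factors = nf, lambda = lam,
       resid_sd = sqrt(resid_var))
}

#' Generate a synthetic expression count matrix
#'
#' Per-sample latent Gaussian vectors are drawn from the regime's block /
#' factor covariance and mapped through a Gaussian copula to
#' negative-binomial margins: gene-specific means are log-normal
#' (\code{mean_log_mu}, \code{sd_log_mu}) and the dispersion is common. The
#' \code{cancer_like} regime activates the planted high-correlation
#' cytoband blocks; the \code{normal_like} regime activates the global
#' (cross-chromosome) trans factors instead, so CIS structure dominates the
#' former and TRANS structure the latter.
#'
#' @param config a \code{\link{sim_config}}.
#' @param regime \code{"cancer_like"} or \code{"normal_like"}.
#' @param annotation optionally a pre-built annotation (must come from the
#'   same config); regenerated if omitted.
#' @param keep_latent if TRUE the latent Gaussian matrix (samples x genes)
#'   is attached as attribute \code{"latent"}.
#' @return integer count matrix, genes x samples, with gene/sample dimnames.
#' @export
generate_expression <- function(config,
                                regime = c("cancer_like", "normal_like"),
                                annotation = NULL,
                                keep_latent = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  regime <- match.arg(regime)
  if (is.null(annotation)) annotation <- generate_annotation(config)
  lay <- latent_layout(config, annotation, regime)
  G <- config$n_genes
  N <- config$n_samples
  set.seed(stage_seed(config$seed, paste0("expression:", regime)))
  mu <- exp(stats::rnorm(G, config$mean_log_mu, config$sd_log_mu))
  z <- matrix(stats::rnorm(N * G), N, G)
  z <- sweep(z, 2L, lay$resid_sd, `*`)
  if (any(lay$block_id > 0L)) {
    for (bi in unique(lay$block_id[lay$block_id > 0L])) {
      sel <- which(lay$block_id == bi)
      u <- stats::rnorm(N)
      z[, sel] <- z[, sel] + sqrt(lay$rho_g[sel][1]) * u
    }
  }
  if (lay$n_factors > 0L) {
    w <- matrix(stats::rnorm(N * lay$n_factors), N, lay$n_factors)
    z <- z + lay$lambda * (w %*% matrix(1, lay$n_factors, G))
  }
  u <- pmin(stats::pnorm(z), 1 - 1e-12)
  counts <- matrix(0L, G, N,
                   dimnames = list(annotation$gene_id,
                                   sprintf("s%03d", seq_len(N))))
  size <- 1 / config$nb_dispersion
  for (g in seq_len(G))
    counts[g, ] <- as.integer(stats::qnbinom(u[, g], mu = mu[g], size = size))
  attr(counts, "nb_mu") <- mu
  if (keep_latent) attr(counts, "latent") <- z
  counts
}

#' Generate a synthetic clinical table
#'
#' Event times are exponential with hazard \code{baseline_hazard *
#' exp(log_hazard_ratio * 1[group == "high"])}. Censoring is by an
#' independent exponential clock whose rate is chosen so that the
#' probability of censoring before the event equals \code{censoring_rate}
#' (for two independent exponentials that probability is
#' \eqn{\lambda_c / (\lambda_c + \lambda_e)}); \code{censoring_rate = 0}
#' disables censoring entirely.
#'
#' @param config a \code{\link{sim_config}}.
#' @param group_labels character vector, one \code{"high"}/\code{"low"} per
#'   sample.
#' @param subtype cohort label stored alongside each sample.
#' @return data.frame sample_id, time_days, event, group, subtype.
#' @export
generate_clinical <- function(config, group_labels = NULL,
                              subtype = "cohort") {
  stopifnot(inherits(config, "sim_config"))
  N <- config$n_samples
  if (N < 1L) stop("empty cohort: n_samples must be >= 1")
  if (is.null(group_labels)) group_labels <- rep("low", N)
  if (length(group_labels) != N)
    stop("need exactly one group label per sample (", N, ")")
  if (!all(group_labels %in% c("high", "low")))
    stop("group labels must be 'high' or 'low'")
  set.seed(stage_seed(config$seed, "clinical"))
  rate_e <- config$baseline_hazard *
    exp(config$log_hazard_ratio * (group_labels == "high"))
  t_event <- stats::rexp(N, rate_e)
  p <- config$censoring_rate
  if (p > 0) {
    rate_c <- rate_e * p / (1 - p)
    t_cens <- stats::rexp(N, rate_c)
  } else {
    t_cens <- rep(Inf, N)
  }
  data.frame(
    sample_id = sprintf("s%03d", seq_len(N)),
    time_days = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    group = group_labels,
    subtype = subtype,
    stringsAsFactors = FALSE
  )
}

#' Write the three synthetic tables to disk
#'
#' Counts go to \code{counts_<regime>.tsv} (genes x samples TSV),
#' annotation to \code{annotation.tsv}, clinical to \code{clinical.csv}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param outdir output directory (created if absent).
#' @param regimes regimes to simulate.
#' @return invisibly, the named vector of files written.
#' @export
simulate_cohort_files <- function(config, outdir,
                                  regimes = c("cancer_like", "normal_like")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ann <- generate_annotation(config)
  files <- c(annotation = file.path(outdir, "annotation.tsv"))
  write_annotation(ann, files[["annotation"]])
  for (r in regimes) {
    f <- file.path(outdir, paste0("counts_", r, ".tsv"))
    write_expression(generate_expression(config, r, annotation = ann), f)
    files[[paste0("counts_", r)]] <- f
  }
  clin <- generate_clinical(config)
  files[["clinical"]] <- file.path(outdir, "clinical.csv")
  utils::write.csv(clin, files[["clinical"]], row.names = FALSE, quote = FALSE)
  invisible(files)
}
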