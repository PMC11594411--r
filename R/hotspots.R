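# Genomic classification of co-expression edges and hotspot statistics.
#
# Categories partition every edge set: both genes in the same cytoband of
# the same chromosome -> INTRA_CYTOBAND; same chromosome, different
# cytoband -> INTER_CYTOBAND_CIS; different chromosomes -> TRANS. CIS =
# INTRA_CYTOBAND + INTER_CYTOBAND_CIS. Cytoband identity is always the
# (chromosome, cytoband) pair; bare cytoband strings are display only.

ann_lookup <- function(edges, annotation, genes = c(edges$gene_a,
                                                    edges$gene_b)) {
  idx <- match(genes, annotation$gene_id)
  if (anyNA(idx))
    stop("unannotated gene(s): ",
         paste(unique(genes[is.na(idx)]), collapse = ", "))
  idx
}

#' Classify edges by genomic location
#'
#' @param edges data.frame gene_a, gene_b (weight optional).
#' @param annotation annotation table covering both genes of every edge.
#' @return factor with levels INTRA_CYTOBAND, INTER_CYTOBAND_CIS, TRANS.
#' @export
classify_edges <- function(edges, annotation) {
  ia <- ann_lookup(edges, annotation, edges$gene_a)
  ib <- ann_lookup(edges, annotation, edges$gene_b)
  same_chr <- normalize_chromosome(annotation$chromosome[ia]) ==
    normalize_chromosome(annotation$chromosome[ib])
  same_band <- same_chr & annotation$cytoband[ia] == annotation$cytoband[ib]
  cat <- ifelse(same_band, "INTRA_CYTOBAND",
                ifelse(same_chr, "INTER_CYTOBAND_CIS", "TRANS"))
  factor(cat, levels = c("INTRA_CYTOBAND", "INTER_CYTOBAND_CIS", "TRANS"))
}

#' CIS/TRANS and intra/inter-cytoband edge counts and fractions
#'
#' @param edges edge data.frame.
#' @param annotation annotation table.
#' @return list with \code{counts} (named: INTRA_CYTOBAND,
#'   INTER_CYTOBAND_CIS, TRANS, CIS, total) and \code{fractions} of total.
#' @export
cis_trans_summary <- function(edges, annotation) {
  if (nrow(edges) == 0L) {
    warning("empty edge set")
    z <- c(INTRA_CYTOBAND = 0, INTER_CYTOBAND_CIS = 0, TRANS = 0,
           CIS = 0, total = 0)
    return(list(counts = z, fractions = z[1:4] * NA))
  }
  cls <- classify_edges(edges, annotation)
  tab <- table(cls)
  counts <- c(as.vector(tab), sum(tab[1:2]), nrow(edges))
  names(counts) <- c(levels(cls), "CIS", "total")
  list(counts = counts,
       fractions = counts[1:4] / counts[["total"]])
}

#' Per-region hotspot table
#'
#' For each chromosome (or chromosome-qualified cytoband), frequency is
#' the number of edges with both genes inside the region; proportion
#' normalizes by the number of possible intra-region pairs
#' \eqn{C(n_{genes}, 2)} over the network's gene universe. Regions with
#' fewer than two genes cannot host an edge: their proportion is reported
#' as 0 and flagged \code{degenerate}.
#'
#' @param edges edge data.frame.
#' @param annotation annotation table (defines the gene universe).
#' @param level "chromosome" or "cytoband".
#' @param universe optional character vector restricting the gene universe
#'   (defaults to all annotated genes).
#' @return data.frame region, frequency, proportion, n_genes, degenerate,
#'   sorted by frequency descending.
#' @export
region_hotspots <- function(edges, annotation,
                            level = c("chromosome", "cytoband"),
                            universe = NULL) {
  level <- match.arg(level)
  ann <- annotation
  if (!is.null(universe)) ann <- ann[ann$gene_id %in% universe, , drop = FALSE]
  chr <- normalize_chromosome(ann$chromosome)
  region_of <- if (level == "chromosome") chr else paste0(chr, ":", ann$cytoband)
  n_genes <- table(region_of)
  freq <- setNames(rep(0L, length(n_genes)), names(n_genes))
  if (nrow(edges) > 0L) {
    ia <- ann_lookup(edges, ann, edges$gene_a)
    ib <- ann_lookup(edges, ann, edges$gene_b)
    ra <- region_of[ia]
    rb <- region_of[ib]
    intra <- ra == rb
    if (any(intra)) {
      t2 <- table(ra[intra])
      freq[names(t2)] <- as.integer(t2)
    }
  }
  n <- as.integer(n_genes)
  possible <- n * (n - 1) / 2
  degenerate <- possible == 0
  prop <- ifelse(degenerate, 0, freq / pmax(possible, 1))
  out <- data.frame(region = names(n_genes), frequency = as.integer(freq),
                    proportion = prop, n_genes = n,
                    degenerate = degenerate, stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$region, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample argmax-region counts
#'
#' For every single-sample network (its top-k edge set), the region
#' proportions are computed and every region attaining the maximum
#' positive proportion is credited; ties credit all tied regions (so
#' counts can exceed the cohort size) and are flagged in the
#' \code{"ties"} attribute. A sample with no intra-region edges credits
#' no region.
#'
#' @param sample_edge_sets named list of edge data.frames (one per
#'   sample), e.g. \code{lapply(nets, top_k_abs, k)}.
#' @param annotation annotation table.
#' @param level "chromosome" or "cytoband".
#' @return data.frame region, n_samples, sorted descending, with
#'   attribute \code{"ties"} (sample IDs whose maximum was tied).
#' @export
per_sample_argmax_regions <- function(sample_edge_sets, annotation,
                                      level = c("chromosome", "cytoband")) {
  level <- match.arg(level)
  if (length(sample_edge_sets) == 0L) stop("need at least one network")
  counts <- list()
  ties <- character(0)
  for (s in seq_along(sample_edge_sets)) {
    hs <- region_hotspots(sample_edge_sets[[s]], annotation, level)
    mx <- max(hs$proportion)
    if (mx <= 0) next
    winners <- hs$region[hs$proportion == mx]
    if (length(winners) > 1L)
      ties <- c(ties, names(sample_edge_sets)[s] %||% as.character(s))
    for (w in winners) counts[[w]] <- (counts[[w]] %||% 0L) + 1L
  }
  out <- data.frame(region = names(counts),
                    n_samples = as.integer(unlist(counts)),
                    stringsAsFactors = FALSE)
  if (nrow(out))
    out <- out[order(-out$n_samples, out$region, method = "radix"), ,
               drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ties") <- ties
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
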