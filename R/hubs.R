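# Recurrent high-degree genes across single-sample networks and their
# cytoband localization. Degree is computed on the binary top-k edge set
# restricted to the largest connected component.

#' Top high-degree genes of one network
#'
#' Genes of the largest component ranked by degree (descending, ties by
#' lexicographic gene ID); the first \code{top_n} are returned.
#'
#' @param edges edge data.frame (a sample's top-k set).
#' @param top_n number of genes to return (default 10).
#' @return data.frame gene_id, degree, ranked.
#' @export
high_degree_genes <- function(edges, top_n = 10L) {
  if (nrow(edges) == 0L) stop("empty network")
  lcc <- largest_component(edges)
  deg <- table(c(lcc$gene_a, lcc$gene_b))
  out <- data.frame(gene_id = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene_id, method = "radix"), ,
             drop = FALSE]
  out <- out[seq_len(min(top_n, nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hub recurrence across single-sample networks
#'
#' Counts, per gene, the number of samples in which it appears among that
#' sample's \code{top_n} highest-degree genes.
#'
#' @param sample_edge_sets list of per-sample edge data.frames.
#' @param top_n per-sample cutoff (default 10).
#' @return data.frame gene_id, recurrence, sorted descending.
#' @export
hub_recurrence <- function(sample_edge_sets, top_n = 10L) {
  if (length(sample_edge_sets) == 0L) stop("need at least one network")
  hubs <- unlist(lapply(sample_edge_sets, function(e)
    high_degree_genes(e, top_n)$gene_id))
  tab <- table(hubs)
  out <- data.frame(gene_id = names(tab), recurrence = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$recurrence, out$gene_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cytoband distribution of hub recurrence
#'
#' Aggregates recurrence counts by (chromosome, cytoband); totals are
#' conserved: the sum over cytobands equals the sum over genes.
#'
#' @param records output of \code{\link{hub_recurrence}}.
#' @param annotation annotation covering every hub gene.
#' @return data.frame cytoband (chromosome-qualified), recurrence,
#'   sorted descending.
#' @export
hub_cytoband_distribution <- function(records, annotation) {
  if (nrow(records) == 0L)
    return(data.frame(cytoband = character(0), recurrence = integer(0),
                      stringsAsFactors = FALSE))
  idx <- match(records$gene_id, annotation$gene_id)
  if (anyNA(idx))
    stop("unannotated hub gene(s): ",
         paste(records$gene_id[is.na(idx)], collapse = ", "))
  band <- paste0(normalize_chromosome(annotation$chromosome[idx]), ":",
                 annotation$cytoband[idx])
  agg <- rowsum(records$recurrence, band)
  out <- data.frame(cytoband = rownames(agg), recurrence = as.integer(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$recurrence, out$cytoband, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
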