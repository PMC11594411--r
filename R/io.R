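# Readers/writers for the pipeline's delimited table formats. Delimiter is
# auto-detected between tab and comma; all coordinates are 1-based inclusive.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read an expression matrix
#'
#' Expects a delimited file with a header row of sample IDs and a first
#' column of gene IDs; tab and comma dialects are both accepted.
#'
#' @param path file path.
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicated gene IDs: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(names(df)[-1L]))
    stop("duplicated sample IDs: ",
         paste(unique(names(df)[-1L][duplicated(names(df)[-1L])]),
               collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in expression matrix")
  if (any(!is.finite(m))) stop("non-finite values in expression matrix")
  if (any(m < 0)) stop("negative values in expression matrix")
  rownames(m) <- genes
  m
}

#' Write an expression matrix as TSV (genes x samples)
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path destination.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Requires columns gene_id, chromosome, cytoband, start, end; gc and
#' length are optional. Chromosome names are normalized so "chr17" and
#' "17" refer to the same key.
#'
#' @param path file path.
#' @return data.frame of validated annotation rows.
#' @export
read_annotation <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("gene_id", "chromosome", "cytoband", "start", "end")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("annotation missing required column(s): ",
         paste(miss, collapse = ", "))
  df$chromosome <- normalize_chromosome(df$chromosome)
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene IDs in annotation: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  if (any(df$start > df$end))
    stop("start > end for gene(s): ",
         paste(df$gene_id[df$start > df$end], collapse = ", "))
  if (any(df$start < 1L)) stop("coordinates are 1-based: start must be >= 1")
  df
}

#' Normalize chromosome names ("chr17" and "17" unify to "17")
#' @param x character vector of chromosome names.
#' @return normalized character vector.
#' @export
normalize_chromosome <- function(x) sub("^chr", "", as.character(x))

#' Write an annotation table as TSV
#' @param ann annotation data.frame.
#' @param path destination.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Expects columns sample_id, time_days, event and optionally group and
#' subtype.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_clinical <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "time_days", "event")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$time_days <= 0)) stop("survival times must be positive")
  if (!all(df$event %in% c(0L, 1L))) stop("event must be 0/1")
  df
}

#' Write an edge list as 3-column TSV (gene_a, gene_b, weight)
#' @param edges data.frame with gene_a, gene_b, weight.
#' @param path destination.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges[, c("gene_a", "gene_b", "weight")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge list written by \code{write_edges}
#' @param path file path.
#' @return data.frame gene_a, gene_b, weight.
#' @export
read_edges <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene_a", "gene_b", "weight") %in% names(df)))
  df
}
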