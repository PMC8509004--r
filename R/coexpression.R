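#' Pearson correlation matrix among a region's genes
#'
#' Computes the sample Pearson correlation of expression between every pair
#' of the given genes over one region's samples — the co-expression matrix
#' used to show that genes rising with age cluster together and falling
#' genes cluster together. Genes with zero variance across the region's
#' samples carry no correlation signal and are dropped with a warning.
#'
#' @param data A \code{"brainspan_data"}/\code{"brainspan_sim"} object, a
#'   \code{"cilia_screen"}, or a list with \code{expr} and \code{samples}.
#' @param genes Gene symbols to correlate (e.g. one region's DEGAs).
#' @param region Region code whose samples are used.
#' @param order_genes Reorder rows/columns by [cluster_order()] so correlated
#'   blocks are contiguous (default TRUE).
#' @return Symmetric correlation matrix with unit diagonal, gene symbols as
#'   dimnames.
#' @export
pearson_matrix <- function(data, genes, region, order_genes = TRUE) {
  if (inherits(data, "cilia_screen")) data <- data$data
  expr <- data$expr
  samples <- data$samples
  genes <- unique(genes)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) stop("gene(s) absent from matrix: ",
                            paste(missing, collapse = ", "))
  idx <- samples$region == region
  if (sum(idx) < 2) stop("need at least 2 samples in region ", region)
  Y <- expr[genes, idx, drop = FALSE]
  v <- apply(Y, 1, stats::var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance gene(s): ",
            paste(genes[v == 0], collapse = ", "))
    Y <- Y[v > 0, , drop = FALSE]
  }
  if (nrow(Y) < 2) stop("fewer than 2 usable genes in region ", region)
  R <- stats::cor(t(Y))
  if (order_genes && nrow(R) > 2) {
    ord <- cluster_order(R)
    R <- R[ord, ord, drop = FALSE]
  }
  R
}

#' Display order from average-linkage clustering of a correlation matrix
#'
#' Orders genes by agglomerative hierarchical clustering with average
#' linkage on the dissimilarity d = 1 - R, returning the dendrogram leaf
#' order. Ties in merge heights resolve deterministically (first index
#' wins), so the order is reproducible.
#'
#' @param R Square symmetric correlation matrix.
#' @return Integer permutation of \code{seq_len(nrow(R))}.
#' @export
cluster_order <- function(R) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  n <- nrow(R)
  if (n == 1) return(1L)
  d <- stats::as.dist(1 - R)
  stats::hclust(d, method = "average")$order
}
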