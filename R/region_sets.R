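#' Region-by-region DEGA overlap matrix
#'
#' Counts, for every pair of regions, how many genes are DEGAs in both.
#' Direction is ignored for membership: a gene rising with age in one region
#' and falling in another still overlaps, the convention under which a
#' ubiquitous but direction-discordant gene counts in every intersection.
#' The diagonal holds per-region set sizes.
#'
#' @param x A \code{"cilia_screen"} or \code{"dega_sets"} object.
#' @return Symmetric integer matrix, regions x regions.
#' @export
overlap_matrix <- function(x) {
  sets <- .as_dega_sets(x)
  if (length(sets) < 2) stop("need DEGA sets for at least 2 regions")
  gene_sets <- lapply(sets, names)
  n <- length(sets)
  m <- matrix(0L, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      m[i, j] <- m[j, i] <-
        length(intersect(gene_sets[[i]], gene_sets[[j]]))
    }
  }
  m
}

#' Region-sharing profile of DEGAs
#'
#' For every gene in the DEGA union, the number k of regions where it is a
#' DEGA, with the histogram of genes per k. Genes at k = 1 are the
#' region-unique DEGAs; genes at k = number of regions are the ubiquitous
#' ones (in the atlas screen, CCDC28B alone reaches all sixteen).
#'
#' @param x A \code{"cilia_screen"} or \code{"dega_sets"} object.
#' @return List: \code{k} (named integer vector, gene -> region count),
#'   \code{histogram} (data.frame \code{k, n_genes}), \code{ubiquitous}
#'   (genes present in every region's set), \code{unique_genes} (genes in
#'   exactly one region).
#' @export
shared_in_k <- function(x) {
  sets <- .as_dega_sets(x)
  member <- table(unlist(lapply(sets, names)))
  k <- stats::setNames(as.integer(member), names(member))
  hist <- as.data.frame(table(k), stringsAsFactors = FALSE)
  names(hist) <- c("k", "n_genes")
  hist$k <- as.integer(hist$k)
  list(k = k,
       histogram = hist,
       ubiquitous = names(k)[k == length(sets)],
       unique_genes = names(k)[k == 1L])
}

#' Per-region direction profile of one DEGA
#'
#' @param x A \code{"cilia_screen"} or \code{"dega_sets"} object.
#' @param gene Gene symbol; must be a DEGA in at least one region.
#' @return Named character vector over regions with values \code{"up"},
#'   \code{"down"} or \code{"absent"}.
#' @export
direction_profile <- function(x, gene) {
  sets <- .as_dega_sets(x)
  prof <- vapply(sets, function(s) {
    if (gene %in% names(s)) unname(s[gene]) else "absent"
  }, "")
  if (all(prof == "absent")) stop(gene, " is not a DEGA in any region")
  prof
}

#' Bipartite gene-region DEGA network
#'
#' Builds the two-class graph with one node per DEGA gene and one per
#' region, an edge wherever the gene is a DEGA in that region. Node degree
#' (a gene's number of regions; a region's set size) is stored as the
#' \code{size} attribute, so plots can scale nodes by connectedness.
#' Regions with empty sets remain as isolated nodes.
#'
#' @param x A \code{"cilia_screen"} or \code{"dega_sets"} object.
#' @param graphml Optional path; when given, the graph is also written as
#'   GraphML.
#' @return An \code{igraph} bipartite graph (vertex attributes \code{name},
#'   \code{type} — TRUE for regions —, \code{size}).
#' @export
build_network <- function(x, graphml = NULL) {
  sets <- .as_dega_sets(x)
  genes <- unique(unlist(lapply(sets, names)))
  if (!length(genes)) stop("empty DEGA union; no network to build")
  edges <- do.call(rbind, lapply(names(sets), function(r) {
    g <- names(sets[[r]])
    if (!length(g)) return(NULL)
    cbind(gene = g, region = r)
  }))
  vertices <- data.frame(
    name = c(genes, names(sets)),
    type = c(rep(FALSE, length(genes)), rep(TRUE, length(sets))),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(as.data.frame(edges),
                                     directed = FALSE, vertices = vertices)
  igraph::V(g)$size <- igraph::degree(g)
  if (!is.null(graphml)) igraph::write_graph(g, graphml, format = "graphml")
  g
}
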