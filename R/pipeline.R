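#' Run the full age-screen pipeline and write every stage table
#'
#' End-to-end orchestration: load a BrainSpan-dialect dataset (or simulate
#' one), run [cilia_screen()], then write every downstream table —
#' \code{screen_results.tsv} (the single source of truth from which all
#' other tables are recomputable), \code{region_summary.tsv},
#' \code{volcano_<region>.tsv}, \code{corr_<region>.tsv},
#' \code{overlap_matrix.tsv}, \code{shared_in_k.tsv},
#' \code{network.graphml}, \code{network_edges.tsv},
#' \code{compartment_summary_all.tsv},
#' \code{compartment_summary_by_region.tsv} — plus \code{manifest.json}
#' recording the configuration, seed and output inventory. Identical inputs
#' and seed give identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param data_dir Directory with a BrainSpan CSV triplet; ignored when
#'   \code{simulate = TRUE}.
#' @param gene_list Path to the annotation TSV (default: packaged synthetic
#'   panel).
#' @param simulate Simulate the dataset instead of reading one.
#' @param sim_args List of arguments for [simulate_brainspan()] when
#'   simulating.
#' @param alpha,fdr_alpha,min_samples,fdr_scope Passed to [cilia_screen()].
#' @param seed Seed for the simulation branch.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the fitted \code{"cilia_screen"} object
#'   and the manifest.
#' @export
run_pipeline <- function(out_dir, data_dir = NULL, gene_list = NULL,
                         simulate = is.null(data_dir), sim_args = list(),
                         alpha = 0.05, fdr_alpha = 0.05, min_samples = 3,
                         fdr_scope = "global", seed = 1L, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[pipeline] ", ...)

  ann <- load_gene_list(gene_list)
  if (simulate) {
    say("simulate: generating dataset (seed ", seed, ")")
    sim_args$seed <- seed
    if (is.null(sim_args$n_genes)) sim_args$n_genes <- nrow(ann)
    data <- do.call(simulate_brainspan, sim_args)
    # name simulated genes after the panel so annotations apply
    if (nrow(data$expr) <= nrow(ann)) {
      syms <- ann$symbol[seq_len(nrow(data$expr))]
      data$truth$gene <- syms[match(data$truth$gene, rownames(data$expr))]
      rownames(data$expr) <- syms
    }
    utils::write.table(data$truth, file.path(out_dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    say("io: reading triplet from ", data_dir)
    data <- read_brainspan(data_dir, quiet = quiet)
  }

  say("screen: fitting ", nrow(data$expr), " genes")
  screen_genes <- if (simulate) rownames(data$expr) else ann
  scr <- cilia_screen(data, genes = screen_genes, alpha = alpha,
                      fdr_alpha = fdr_alpha, min_samples = min_samples,
                      fdr_scope = fdr_scope)
  wt <- function(tab, name, rownames = FALSE) {
    utils::write.table(tab, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = rownames,
                       col.names = if (rownames) NA else TRUE)
    name
  }
  files <- character()
  files <- c(files, wt(scr$results, "screen_results.tsv"))

  tab <- region_summary(scr)
  tab$union_size <- attr(tab, "union_size")
  tab$union_pct <- attr(tab, "union_pct")
  files <- c(files, wt(tab, "region_summary.tsv"))

  sets <- dega_sets(scr)
  for (r in scr$regions) {
    files <- c(files, wt(volcano_table(scr, r),
                         paste0("volcano_", r, ".tsv")))
    if (length(sets[[r]]) >= 2) {
      R <- suppressWarnings(tryCatch(pearson_matrix(scr, names(sets[[r]]), r),
                                     error = function(e) NULL))
      if (!is.null(R)) {
        files <- c(files, wt(round(R, 6), paste0("corr_", r, ".tsv"),
                             rownames = TRUE))
      }
    }
  }

  if (length(scr$regions) >= 2) {
    say("region_sets: overlaps and network")
    files <- c(files, wt(overlap_matrix(sets), "overlap_matrix.tsv",
                         rownames = TRUE))
    sk <- shared_in_k(sets)
    files <- c(files, wt(data.frame(gene = names(sk$k), k = sk$k),
                         "shared_in_k.tsv"))
    if (length(attr(sets, "union"))) {
      net <- build_network(sets, graphml = file.path(out_dir,
                                                     "network.graphml"))
      el <- igraph::as_edgelist(net)
      files <- c(files, "network.graphml",
                 wt(data.frame(gene = el[, 1], region = el[, 2]),
                    "network_edges.tsv"))
    }
  }

  say("compartments: summaries")
  files <- c(files, wt(compartment_summary(sets, ann, "ALL"),
                       "compartment_summary_all.tsv"))
  by_region <- do.call(rbind, lapply(scr$regions, function(r)
    compartment_summary(sets, ann, r)))
  files <- c(files, wt(by_region, "compartment_summary_by_region.tsv"))

  manifest <- list(
    package = "ciliascreen",
    version = as.character(utils::packageVersion("ciliascreen")),
    seed = seed,
    simulated = simulate,
    config = list(alpha = alpha, fdr_alpha = fdr_alpha,
                  min_samples = min_samples, fdr_scope = fdr_scope),
    n_genes = length(scr$genes), n_regions = length(scr$regions),
    n_fits = nrow(scr$results),
    files = files
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done: ", length(files), " tables in ", out_dir)
  invisible(list(screen = scr, manifest = manifest))
}
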