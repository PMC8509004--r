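#' Sub-structural compartment DEGA summary
#'
#' Rolls DEGA calls up to cilia compartments: for each compartment, how many
#' of its annotated genes (among the screened panel) are DEGAs, split by
#' direction, and what percentage of the compartment that is. Genes
#' annotated to several compartments count once in each — compartment
#' denominators overlap rather than partition the panel.
#'
#' At region scope a gene's direction is its direction in that region. At
#' \code{scope = "ALL"} a gene is a DEGA if it is one anywhere, and its
#' direction is the majority across its DEGA regions; genes with an exact
#' up/down tie go to the \code{n_mixed} bucket (the screen defines no
#' whole-brain direction for discordant genes).
#'
#' @param x A \code{"cilia_screen"} or \code{"dega_sets"} object.
#' @param annotations Annotation table from [load_gene_list()].
#' @param scope \code{"ALL"} (default) or a region code.
#' @param missing_annotation \code{"other"} to treat screened genes absent
#'   from the annotation table as compartment \code{"other"} (with a
#'   warning), or \code{"error"}.
#' @return data.frame: \code{compartment, scope, n_total, n_dega, n_up,
#'   n_down, n_mixed, pct_dega}.
#' @export
compartment_summary <- function(x, annotations, scope = "ALL",
                                missing_annotation = c("other", "error")) {
  missing_annotation <- match.arg(missing_annotation)
  sets <- .as_dega_sets(x)
  if (scope != "ALL" && !scope %in% names(sets)) {
    stop("unknown scope: ", scope)
  }
  screened <- attr(sets, "screened")
  ann <- stats::setNames(annotations$compartments, annotations$symbol)
  unannot <- setdiff(screened, names(ann))
  if (length(unannot)) {
    if (missing_annotation == "error") {
      stop("screened gene(s) lack annotation: ",
           paste(utils::head(unannot, 5), collapse = ", "),
           if (length(unannot) > 5) ", ...")
    }
    warning(length(unannot), " screened gene(s) lack annotation; ",
            "assigned to 'other'")
    ann[unannot] <- list("other")
  }
  ann <- ann[screened]

  if (scope == "ALL") {
    dirs <- lapply(sets, identity)
    all_dir <- vapply(attr(sets, "union"), function(g) {
      d <- unlist(lapply(dirs, function(s) s[g]))
      d <- d[!is.na(d)]
      nu <- sum(d == "up"); nd <- sum(d == "down")
      if (nu > nd) "up" else if (nd > nu) "down" else "mixed"
    }, "")
  } else {
    all_dir <- sets[[scope]]
  }

  out <- lapply(cilia_compartments(), function(comp) {
    members <- screened[vapply(ann, function(z) comp %in% z, TRUE)]
    deg <- intersect(members, names(all_dir))
    data.frame(compartment = comp, scope = scope,
               n_total = length(members), n_dega = length(deg),
               n_up = sum(all_dir[deg] == "up"),
               n_down = sum(all_dir[deg] == "down"),
               n_mixed = sum(all_dir[deg] == "mixed"),
               pct_dega = if (length(members))
                 100 * length(deg) / length(members) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[out$n_total > 0, , drop = FALSE]
}

#' Per-region direction breakdown for one compartment
#'
#' For a single compartment, the fraction of its DEGAs in each region that
#' are downregulated (and upregulated) — the view in which, e.g.,
#' cilia-associated mitochondrial DEGAs are 100% down with age in all
#' regions but the cerebellum. Regions with no DEGAs from the compartment
#' report NA fractions (undefined, not zero).
#'
#' @param x A \code{"cilia_screen"} or \code{"dega_sets"} object.
#' @param annotations Annotation table from [load_gene_list()].
#' @param compartment One label from [cilia_compartments()].
#' @return data.frame: \code{region, n_dega, frac_down, frac_up}.
#' @export
direction_breakdown <- function(x, annotations, compartment) {
  if (!compartment %in% cilia_compartments()) {
    stop("unknown compartment: ", compartment)
  }
  sets <- .as_dega_sets(x)
  members <- annotations$symbol[vapply(annotations$compartments,
                                       function(z) compartment %in% z, TRUE)]
  out <- lapply(names(sets), function(r) {
    s <- sets[[r]][intersect(names(sets[[r]]), members)]
    n <- length(s)
    data.frame(region = r, n_dega = n,
               frac_down = if (n) sum(s == "down") / n else NA_real_,
               frac_up = if (n) sum(s == "up") / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
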