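#' @export
print.cilia_screen <- function(x, ...) {
  r <- x$results
  cat("Cilia age-trend screen\n")
  cat("  ", length(x$genes), " genes x ", length(x$regions),
      " regions = ", nrow(r), " fits (",
      sum(r$status == "degenerate"), " degenerate)\n", sep = "")
  cat("  DEGA pairs (raw p < ", x$config$alpha, "): ", sum(r$dega),
      "; FDR tier (q <= ", x$config$fdr_alpha, "): ", sum(r$fdr_pass),
      "\n", sep = "")
  u <- unique(r$gene[r$dega])
  cat("  DEGA union: ", length(u), " of ", length(x$genes), " genes (",
      sprintf("%.1f%%", 100 * length(u) / length(x$genes)), ")\n", sep = "")
  invisible(x)
}

#' Summarise a cilia age screen
#'
#' @param object A \code{"cilia_screen"} object.
#' @param ... Unused.
#' @return The per-region DEGA count table from [region_summary()],
#'   invisibly, after printing it with the whole-screen union.
#' @export
summary.cilia_screen <- function(object, ...) {
  tab <- region_summary(object)
  cat("Cilia age-trend screen: per-region DEGA counts\n\n")
  print(tab, row.names = FALSE)
  cat("\nUnion across regions:", attr(tab, "union_size"), "genes (",
      sprintf("%.1f%%", attr(tab, "union_pct")), "of the panel )\n")
  invisible(tab)
}

#' Slope (regression coefficient) matrix of a screen
#'
#' @param object A \code{"cilia_screen"} object.
#' @param ... Unused.
#' @return Numeric matrix genes x regions of fitted slopes (expression units
#'   per year); NA where the fit was degenerate.
#' @export
coef.cilia_screen <- function(object, ...) {
  r <- object$results
  m <- matrix(NA_real_, length(object$genes), length(object$regions),
              dimnames = list(object$genes, object$regions))
  m[cbind(match(r$gene, object$genes), match(r$region, object$regions))] <-
    r$slope
  m
}

#' Volcano plot of one region's screen results
#'
#' Age effect (slope) against -log10 p; DEGAs coloured by direction
#' (orange up, blue down).
#'
#' @param x A \code{"cilia_screen"} object.
#' @param region Region code to plot (default: first screened region).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cilia_screen <- function(x, region = x$regions[1], ...) {
  v <- volcano_table(x, region)
  col <- c(up = "darkorange", down = "steelblue", none = "grey60")
  graphics::plot(v$slope, v$neg_log10_p,
                 col = col[v$direction], pch = 16,
                 xlab = "age effect (expression units / year)",
                 ylab = expression(-log[10] ~ p),
                 main = paste("Age screen:", region), ...)
  graphics::abline(h = -log10(x$config$alpha), lty = 2, col = "grey40")
  invisible(v)
}

#' Per-region DEGA sets with direction
#'
#' Extracts, for each screened region, the set of genes called DEGA there,
#' each tagged up or down by the sign of its slope.
#'
#' @param x A \code{"cilia_screen"} object.
#' @return Named list of class \code{"dega_sets"}: one element per region, a
#'   named character vector whose names are gene symbols and values are
#'   \code{"up"}/\code{"down"}. Attributes: \code{screened} (the full panel)
#'   and \code{union} (genes DEGA in at least one region).
#' @export
dega_sets <- function(x) {
  stopifnot(inherits(x, "cilia_screen"))
  r <- x$results[x$results$dega, , drop = FALSE]
  sets <- lapply(x$regions, function(reg) {
    sub <- r[r$region == reg, , drop = FALSE]
    stats::setNames(sub$direction, sub$gene)
  })
  names(sets) <- x$regions
  structure(sets, class = "dega_sets",
            screened = x$genes, union = unique(r$gene))
}

#' @export
print.dega_sets <- function(x, ...) {
  cat("DEGA sets over", length(x), "regions;",
      length(attr(x, "union")), "genes in the union\n")
  for (r in names(x)) {
    cat(sprintf("  %-5s %3d (%d up, %d down)\n", r, length(x[[r]]),
                sum(x[[r]] == "up"), sum(x[[r]] == "down")))
  }
  invisible(x)
}

.as_dega_sets <- function(x) {
  if (inherits(x, "cilia_screen")) dega_sets(x)
  else if (inherits(x, "dega_sets")) x
  else stop("expected a 'cilia_screen' or 'dega_sets' object")
}

#' Per-region DEGA counts and whole-screen union
#'
#' @param x A \code{"cilia_screen"} or \code{"dega_sets"} object.
#' @return data.frame with one row per region (\code{region, n_dega, n_up,
#'   n_down}); attributes \code{union_size} and \code{union_pct} (percentage
#'   of the screened panel that is DEGA somewhere).
#' @export
region_summary <- function(x) {
  sets <- .as_dega_sets(x)
  tab <- data.frame(
    region = names(sets),
    n_dega = vapply(sets, length, 1L),
    n_up = vapply(sets, function(s) sum(s == "up"), 1L),
    n_down = vapply(sets, function(s) sum(s == "down"), 1L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(tab,
            union_size = length(attr(sets, "union")),
            union_pct = 100 * length(attr(sets, "union")) /
              length(attr(sets, "screened")))
}

#' Volcano table for one region
#'
#' One row per non-degenerate gene in the region: slope, -log10 p and DEGA
#' direction — the table behind a volcano plot. Exact fits (p = 0) are
#' capped at -log10 p = 300.
#'
#' @param x A \code{"cilia_screen"} object.
#' @param region A screened region code.
#' @return data.frame with \code{gene, slope, neg_log10_p, direction},
#'   sorted by decreasing significance.
#' @export
volcano_table <- function(x, region) {
  stopifnot(inherits(x, "cilia_screen"))
  if (!region %in% x$regions) stop("unknown region: ", region)
  r <- x$results
  r <- r[r$region == region & r$status != "degenerate", , drop = FALSE]
  y <- -log10(r$p)
  y[!is.finite(y) | y > 300] <- 300
  out <- data.frame(gene = r$gene, slope = r$slope, neg_log10_p = y,
                    direction = r$direction, stringsAsFactors = FALSE)
  out[order(-out$neg_log10_p), , drop = FALSE]
}

#' Fold change between the first and last five-year age groups
#'
#' Ratio of mean expression in the last age bin over the first, with ages
#' binned as \\[0, w), \\[w, 2w), ..., with the final bin closed at 40 years.
#' With the default 5-year width this contrasts the 0-5 year group against
#' the 36-40 year group, the summary used to express, e.g., a four-fold
#' rise of SNAP-25 in primary visual cortex across life.
#'
#' @param data A \code{"brainspan_data"}/\code{"brainspan_sim"} object, a
#'   \code{"cilia_screen"} (its stored data is used), or a list with
#'   \code{expr} and \code{samples}.
#' @param gene Gene symbol.
#' @param region Region code.
#' @param bin_width Age bin width in years (default 5).
#' @return Scalar fold change (last-bin mean / first-bin mean).
#' @export
age_group_fold_change <- function(data, gene, region, bin_width = 5) {
  if (inherits(data, "cilia_screen")) data <- data$data
  expr <- data$expr
  samples <- data$samples
  if (!gene %in% rownames(expr)) stop("unknown gene: ", gene)
  idx <- samples$region == region
  if (!any(idx)) stop("no samples in region: ", region)
  ages <- samples$age_years[idx]
  vals <- expr[gene, idx]
  breaks <- seq(0, 40, by = bin_width)
  if (breaks[length(breaks)] < 40) breaks <- c(breaks, 40)
  first <- vals[ages >= breaks[1] & ages < breaks[2]]
  last <- vals[ages >= breaks[length(breaks) - 1] & ages <= 40]
  if (!length(first)) stop("first age bin is empty for region ", region)
  if (!length(last)) stop("last age bin is empty for region ", region)
  m0 <- mean(first)
  if (m0 == 0) stop("zero mean expression in the first age bin")
  mean(last) / m0
}
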