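#' Ordinary least squares age regression for one gene in one region
#'
#' Fits expression = intercept + slope * age + error by closed-form least
#' squares and tests slope = 0 with the two-sided Student t test on n - 2
#' degrees of freedom. The slope (the regression coefficient, in expression
#' units per year) is the screen's measure of age effect.
#'
#' Degenerate designs are flagged rather than dropped: fewer than
#' \code{min_samples} observations or zero age variance give status
#' \code{"degenerate"} with NA statistics. An exact fit (residual sum of
#' squares numerically zero) gives status \code{"perfect_fit"} with p = 0.
#' A constant response (total sum of squares zero) is a well-defined null
#' result: slope 0, t 0, p 1, R-squared 0.
#'
#' @param ages Numeric vector of ages in years.
#' @param expr Numeric vector of expression values, same length.
#' @param min_samples Minimum observations for a valid fit (default 3,
#'   leaving at least one residual degree of freedom).
#' @return List with \code{n, intercept, slope, se, t, p, r2, status}.
#' @export
#' @examples
#' fit_age_regression(c(1, 2, 3, 4), c(5, 7, 9, 11))  # exact line, slope 2
fit_age_regression <- function(ages, expr, min_samples = 3) {
  stopifnot(length(ages) == length(expr))
  n <- length(ages)
  out <- list(n = n, intercept = NA_real_, slope = NA_real_, se = NA_real_,
              t = NA_real_, p = NA_real_, r2 = NA_real_,
              status = "degenerate")
  if (n < min_samples) return(out)
  xbar <- mean(ages)
  sxx <- sum((ages - xbar)^2)
  if (sxx == 0) return(out)
  ybar <- mean(expr)
  sxy <- sum((ages - xbar) * (expr - ybar))
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  res <- expr - intercept - slope * ages
  rss <- sum(res^2)
  tss <- sum((expr - ybar)^2)
  out$intercept <- intercept
  out$slope <- slope
  if (tss == 0) {
    out[c("slope", "se", "t", "r2")] <- list(0, 0, 0, 0)
    out$p <- 1
    out$status <- "ok"
    return(out)
  }
  if (rss <= 1e-12 * tss) {
    out[c("se", "t", "p", "r2")] <- list(0, Inf * sign(slope), 0, 1)
    out$status <- "perfect_fit"
    return(out)
  }
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- slope / se
  out$se <- se
  out$t <- tval
  out$p <- 2 * stats::pt(-abs(tval), df = n - 2)
  out$r2 <- 1 - rss / tss
  out$status <- "ok"
  out
}

# Vectorised OLS over all genes of one region: same arithmetic as
# fit_age_regression, one design matrix shared by every gene.
.fit_region <- function(ages, Y, min_samples = 3) {
  n <- length(ages)
  g <- nrow(Y)
  blank <- data.frame(n = rep(n, g), intercept = rep(NA_real_, g),
                      slope = rep(NA_real_, g), se = rep(NA_real_, g),
                      t = rep(NA_real_, g), p = rep(NA_real_, g),
                      r2 = rep(NA_real_, g),
                      status = rep("degenerate", g),
                      stringsAsFactors = FALSE)
  if (g == 0L) return(blank)
  if (n < min_samples) return(blank)
  xc <- ages - mean(ages)
  sxx <- sum(xc^2)
  if (sxx == 0) return(blank)
  ybar <- rowMeans(Y)
  Yc <- Y - ybar
  sxy <- as.vector(Yc %*% xc)
  slope <- sxy / sxx
  intercept <- ybar - slope * mean(ages)
  rss <- rowSums((Yc - outer(slope, xc))^2)
  tss <- rowSums(Yc^2)
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  tval <- ifelse(se > 0, slope / se, 0)
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, 0)
  out <- data.frame(n = n, intercept = intercept, slope = slope, se = se,
                    t = tval, p = p, r2 = r2, status = "ok",
                    stringsAsFactors = FALSE)
  const <- tss == 0
  if (any(const)) {
    out$slope[const] <- 0; out$se[const] <- 0; out$t[const] <- 0
    out$p[const] <- 1; out$r2[const] <- 0
    out$intercept[const] <- ybar[const]
  }
  perfect <- !const & rss <= 1e-12 * tss
  if (any(perfect)) {
    out$se[perfect] <- 0
    out$t[perfect] <- Inf * sign(out$slope[perfect])
    out$p[perfect] <- 0
    out$r2[perfect] <- 1
    out$status[perfect] <- "perfect_fit"
  }
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' Maps raw p-values to q-values (the smallest false-discovery-rate level at
#' which each test is rejected) by the Benjamini-Hochberg step-up rule:
#' sort ascending, take the running minimum from the largest rank of
#' p(j) * m / j, map back to input order.
#'
#' @param p Numeric vector of p-values in \\[0, 1\\].
#' @return Numeric vector of q-values, same order as the input.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.2))  # 0.04 0.04 0.04 0.20
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(is.numeric(p), all(is.finite(p)), all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Screen a gene panel for linear age trends across brain regions
#'
#' The central fit of the package: for every gene in the panel and every
#' region, expression is regressed on age in years by ordinary least squares
#' and the slope tested against zero (see [fit_age_regression()]). Every
#' gene-region pair yields one row — pairs that cannot be fit (gene absent
#' from the matrix, too few samples, no age spread) are flagged
#' \code{"degenerate"}, never silently dropped, so a 445-gene panel over 16
#' regions always enumerates 7120 fits. Q-values are attached by
#' Benjamini-Hochberg over all non-degenerate pairs (jointly across regions
#' by default; per-region correction via \code{fdr_scope = "region"}).
#'
#' A pair is called a DEGA (differentially expressed gene with age) when its
#' raw p-value falls below \code{alpha}; direction is the sign of the slope.
#' Pairs additionally passing \code{q <= fdr_alpha} carry the
#' \code{fdr_pass} flag, the screen's higher-confidence tier.
#'
#' @param data A \code{"brainspan_data"} or \code{"brainspan_sim"} object,
#'   or any list with \code{expr} (matrix, rownames gene symbols) and
#'   \code{samples} (data.frame with \code{age_years}, \code{region}).
#' @param genes Gene symbols to screen: a character vector, or an annotation
#'   data.frame from [load_gene_list()] (its \code{symbol} column is used).
#'   Default: all rows of the matrix.
#' @param regions Regions to screen (default: all regions present).
#' @param alpha Raw p-value cutoff defining a DEGA (default 0.05).
#' @param fdr_alpha FDR threshold for the confidence tier (default 0.05).
#' @param min_samples Minimum samples per fit (default 3).
#' @param fdr_scope \code{"global"} (one BH correction over the whole
#'   screen) or \code{"region"} (per region).
#' @return Object of class \code{"cilia_screen"} with \code{results} (one
#'   data.frame row per gene-region pair), the configuration, and the data.
#'   Methods: [print.cilia_screen()], [summary.cilia_screen()],
#'   [coef.cilia_screen()], [plot.cilia_screen()].
#' @export
#' @examples
#' sim <- simulate_brainspan(n_genes = 30, regions = c("PVC", "OFC"),
#'                           seed = 2)
#' scr <- cilia_screen(sim)
#' summary(scr)
cilia_screen <- function(data, genes = NULL, regions = NULL,
                         alpha = 0.05, fdr_alpha = 0.05, min_samples = 3,
                         fdr_scope = c("global", "region")) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(alpha > 0, alpha < 1, fdr_alpha > 0, fdr_alpha < 1,
            min_samples >= 3)
  expr <- data$expr
  samples <- data$samples
  stopifnot(is.matrix(expr), is.data.frame(samples),
            ncol(expr) == nrow(samples))
  if (is.null(genes)) genes <- rownames(expr)
  if (is.data.frame(genes)) genes <- genes$symbol
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("empty gene list")
  if (is.null(regions)) regions <- intersect(brain_regions(),
                                             unique(samples$region))
  if (!length(regions)) stop("no usable regions")

  present <- genes[genes %in% rownames(expr)]
  chunks <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    idx <- which(samples$region == regions[i])
    fit <- .fit_region(samples$age_years[idx],
                       expr[present, idx, drop = FALSE], min_samples)
    full <- data.frame(gene = genes, region = regions[i],
                       n = length(idx), intercept = NA_real_,
                       slope = NA_real_, se = NA_real_, t = NA_real_,
                       p = NA_real_, r2 = NA_real_, status = "degenerate",
                       stringsAsFactors = FALSE)
    full[match(present, genes), names(fit)] <- fit
    chunks[[i]] <- full
  }
  res <- do.call(rbind, chunks)
  rownames(res) <- NULL

  res$q <- NA_real_
  usable <- res$status != "degenerate"
  if (fdr_scope == "global") {
    res$q[usable] <- bh_fdr(res$p[usable])
  } else {
    for (r in regions) {
      sel <- usable & res$region == r
      res$q[sel] <- bh_fdr(res$p[sel])
    }
  }
  res$dega <- usable & res$p < alpha
  res$fdr_pass <- res$dega & res$q <= fdr_alpha
  res$direction <- ifelse(!res$dega, "none",
                          ifelse(res$slope > 0, "up", "down"))
  res <- res[c("gene", "region", "n", "intercept", "slope", "se", "t",
               "p", "q", "r2", "status", "dega", "fdr_pass", "direction")]

  structure(list(
    results = res,
    genes = genes,
    regions = regions,
    config = list(alpha = alpha, fdr_alpha = fdr_alpha,
                  min_samples = min_samples, fdr_scope = fdr_scope),
    data = list(expr = expr, samples = samples)
  ), class = "cilia_screen")
}
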