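test_that("fit_age_regression handles exact, null and degenerate inputs", {
  fit <- fit_age_regression(c(1, 2, 3, 4), c(5, 7, 9, 11))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 3)
  expect_equal(fit$p, 0)
  expect_equal(fit$status, "perfect_fit")

  flat <- fit_age_regression(c(1, 2, 3, 4), c(5, 5, 5, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$t, 0)
  expect_equal(flat$p, 1)
  expect_equal(flat$r2, 0)
  expect_equal(flat$status, "ok")

  expect_equal(fit_age_regression(c(1, 2), c(1, 2))$status, "degenerate")
  expect_equal(fit_age_regression(c(2, 2, 2), c(1, 2, 3))$status,
               "degenerate")
})

test_that("OLS matches the normal-equations + t-CDF oracle to 1e-10", {
  # the atlas-style fixed design first
  ages <- c(0.33, 1, 5, 13, 21, 40)
  y <- c(12.1, 14.0, 13.2, 19.8, 22.5, 30.1)
  fit <- fit_age_regression(ages, y)
  ora <- ols_oracle(ages, y)
  for (f in c("intercept", "slope", "se", "t", "p", "r2")) {
    expect_equal(fit[[f]], unname(ora[[f]]), tolerance = 1e-10)
  }
  # and a confirmatory second route through lm()
  lmf <- summary(lm(y ~ ages))
  expect_equal(fit$slope, unname(coef(lmf)[2, 1]), tolerance = 1e-10)
  expect_equal(fit$p, unname(coef(lmf)[2, 4]), tolerance = 1e-10)

  set.seed(101)
  for (i in 1:250) {
    n <- sample(3:12, 1)
    x <- runif(n, 0.33, 40)
    y <- rnorm(n, 10 + 0.5 * x, 3)
    fit <- fit_age_regression(x, y)
    ora <- ols_oracle(x, y)
    expect_equal(fit$slope, unname(ora$slope), tolerance = 1e-10)
    expect_equal(fit$se, unname(ora$se), tolerance = 1e-10)
    expect_equal(fit$t, unname(ora$t), tolerance = 1e-10)
    expect_equal(fit$p, unname(ora$p), tolerance = 1e-10)
  }
})

test_that("slope-test p equals the Pearson correlation-test p", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    x <- runif(n, 0.33, 40)
    y <- rnorm(n, 5 + x, 10)
    fit <- fit_age_regression(x, y)
    ct <- cor.test(x, y)
    expect_equal(fit$p, ct$p.value, tolerance = 1e-10)
    r <- ct$estimate
    expect_equal(fit$t, unname(r * sqrt((n - 2) / (1 - r^2))),
                 tolerance = 1e-10)
  }
})

test_that("scaling the response scales the slope but not t, p or R2", {
  set.seed(6)
  x <- runif(15, 0.33, 40)
  y <- rnorm(15, 20 + 2 * x, 5)
  f1 <- fit_age_regression(x, y)
  f2 <- fit_age_regression(x, 3.7 * y)
  expect_equal(f2$slope, 3.7 * f1$slope)
  expect_equal(f2$t, f1$t, tolerance = 1e-12)
  expect_equal(f2$p, f1$p, tolerance = 1e-12)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-12)
})

test_that("bh_fdr reproduces the step-up rule", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.5, 0.5, 0.5)), c(0.5, 0.5, 0.5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.2)), c(0.04, 0.04, 0.04, 0.2))
  expect_error(bh_fdr(c(0.5, 1.2)))

  # exhaustive check against the textbook oracle on all permutations
  base <- c(0.001, 0.02, 0.04, 0.2, 0.9)
  perms <- matrix(unlist(combinat_perms(seq_along(base))), ncol = 5,
                  byrow = TRUE)
  for (i in seq_len(nrow(perms))) {
    p <- base[perms[i, ]]
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  # permutation invariance on random p-sets
  set.seed(7)
  p <- runif(30)
  o <- sample(30)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]), tolerance = 1e-12)
})

test_that("the screen enumerates every gene-region pair, flagged not dropped", {
  sim <- toy_sim()
  scr <- cilia_screen(sim, genes = c(rownames(sim$expr), "ABSENT1"))
  expect_equal(nrow(scr$results), 26 * 3)
  deg <- scr$results[scr$results$gene == "ABSENT1", ]
  expect_true(all(deg$status == "degenerate"))
  expect_true(all(is.na(deg$q)))
  expect_true(all(!deg$dega))
  # q present on every non-degenerate pair, from a global BH pass
  ok <- scr$results$status != "degenerate"
  expect_equal(scr$results$q[ok], bh_oracle(scr$results$p[ok]),
               tolerance = 1e-12)
})

test_that("single-pair screens and per-region FDR scope work", {
  sim <- toy_sim(regions = "PVC", n_genes = 1)
  scr <- cilia_screen(sim)
  expect_equal(nrow(scr$results), 1)

  sim <- toy_sim()
  g <- cilia_screen(sim, fdr_scope = "global")$results
  r <- cilia_screen(sim, fdr_scope = "region")$results
  for (reg in unique(r$region)) {
    sel <- r$region == reg & r$status != "degenerate"
    expect_equal(r$q[sel], bh_oracle(r$p[sel]), tolerance = 1e-12)
  }
  expect_equal(g$p, r$p)  # scope only changes q
})

test_that("DEGA calls carry direction from the slope sign", {
  sim <- toy_sim(frac_age_linear = 0.5, noise_sd = 0.5, seed = 13)
  scr <- cilia_screen(sim)
  r <- scr$results
  expect_true(all(r$direction[r$dega & r$slope > 0] == "up"))
  expect_true(all(r$direction[r$dega & r$slope < 0] == "down"))
  expect_true(all(r$direction[!r$dega] == "none"))
  expect_true(all(r$p[r$dega] < 0.05))
  expect_true(all(r$q[r$fdr_pass] <= 0.05))
})

test_that("region summary counts match set cardinalities", {
  sim <- toy_sim(frac_age_linear = 0.4, seed = 17)
  scr <- cilia_screen(sim)
  tab <- region_summary(scr)
  sets <- dega_sets(scr)
  expect_equal(tab$n_dega, unname(vapply(sets, length, 1L)))
  expect_equal(tab$n_up + tab$n_down, tab$n_dega)
  expect_equal(attr(tab, "union_size"),
               length(unique(scr$results$gene[scr$results$dega])))
  expect_equal(attr(tab, "union_pct"),
               100 * attr(tab, "union_size") / length(scr$genes))
})

test_that("volcano tables transform p as -log10 with the p = 0 cap", {
  sim <- toy_sim()
  scr <- cilia_screen(sim)
  # splice known p-values through a handmade screen object
  scr$results$p[1:3] <- c(0.01, 1, 0)
  scr$results$status[3] <- "perfect_fit"
  v <- volcano_table(scr, scr$results$region[1])
  got <- v$neg_log10_p[match(scr$results$gene[1:3], v$gene)]
  expect_equal(got, c(2, 0, 300))
  expect_error(volcano_table(scr, "XXX"), "unknown region")
  # every row recomputable from the results table
  r <- scr$results[scr$results$region == "OFC" &
                     scr$results$status != "degenerate", ]
  v <- volcano_table(scr, "OFC")
  expect_equal(v$slope[match(r$gene, v$gene)], r$slope)
  expect_equal(v$neg_log10_p[match(r$gene, v$gene)],
               pmin(-log10(r$p), 300))
})

test_that("age-group fold change is the ratio of bin means", {
  samples <- data.frame(
    sample_id = paste0("s", 1:6), donor_id = paste0("d", 1:6),
    age_years = c(1, 3, 4, 37, 38, 40), region = "PVC",
    sex = "M", stringsAsFactors = FALSE)
  expr <- matrix(c(10, 10, 10, 40, 40, 40), 1,
                 dimnames = list("SNAP25", samples$sample_id))
  expect_equal(age_group_fold_change(list(expr = expr, samples = samples),
                                     "SNAP25", "PVC"), 4)
  expr[1, ] <- 7
  expect_equal(age_group_fold_change(list(expr = expr, samples = samples),
                                     "SNAP25", "PVC"), 1)
  # analytic oracle: linear gene over dense uniform ages
  set.seed(30)
  n <- 4000
  samples <- data.frame(sample_id = paste0("s", 1:n),
                        donor_id = paste0("d", 1:n),
                        age_years = runif(n, 0, 40), region = "PVC",
                        sex = "M", stringsAsFactors = FALSE)
  b <- 20; s <- 2
  expr <- matrix(b + s * samples$age_years, 1,
                 dimnames = list("G1", samples$sample_id))
  fc <- age_group_fold_change(list(expr = expr, samples = samples),
                              "G1", "PVC")
  expect_equal(fc, (b + 37.5 * s) / (b + 2.5 * s), tolerance = 0.02)
})
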