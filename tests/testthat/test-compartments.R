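# annotation table builder
make_ann <- function(symbols, comps) {
  data.frame(symbol = symbols,
             compartments = I(lapply(comps, identity)),
             stringsAsFactors = FALSE)
}

# sets helper shared with region-set tests lives there; rebuild minimal here
sets_of <- function(lst, screened) {
  structure(lst, class = "dega_sets", screened = screened,
            union = unique(unlist(lapply(lst, names))))
}

test_that("compartment percentages follow counts of annotated DEGAs", {
  # 90-gene compartment with 63 DEGAs -> 70%
  genes <- sprintf("bb%02d", 1:90)
  ann <- make_ann(genes, rep(list("basal body"), 90))
  degas <- stats::setNames(rep("up", 63), genes[1:63])
  sets <- sets_of(list(PVC = degas), screened = genes)
  tab <- compartment_summary(sets, ann, "ALL")
  bb <- tab[tab$compartment == "basal body", ]
  expect_equal(bb$n_total, 90)
  expect_equal(bb$n_dega, 63)
  expect_equal(bb$pct_dega, 70)

  # 25-gene compartment with 21 DEGAs -> 84%
  genes <- sprintf("gp%02d", 1:25)
  ann <- make_ann(genes, rep(list("GPCR"), 25))
  sets <- sets_of(list(OFC = stats::setNames(rep("down", 21), genes[1:21])),
                  screened = genes)
  tab <- compartment_summary(sets, ann, "ALL")
  expect_equal(tab$pct_dega[tab$compartment == "GPCR"], 84)

  # no DEGAs -> 0%
  sets <- sets_of(list(OFC = stats::setNames(character(), character())),
                  screened = genes)
  tab <- compartment_summary(sets, ann, "ALL")
  expect_equal(tab$pct_dega[tab$compartment == "GPCR"], 0)
})

test_that("multi-compartment genes count once per compartment", {
  ann <- make_ann(c("a", "b"), list(c("axoneme", "basal body"), "axoneme"))
  sets <- sets_of(list(PVC = c(a = "up", b = "up")), screened = c("a", "b"))
  tab <- compartment_summary(sets, ann, "ALL")
  expect_equal(tab$n_dega[tab$compartment == "axoneme"], 2)
  expect_equal(tab$n_dega[tab$compartment == "basal body"], 1)
  # the per-compartment sum exceeds the union when annotations overlap
  expect_gte(sum(tab$n_dega), 2)
})

test_that("ALL-scope direction is the majority vote with a mixed bucket", {
  ann <- make_ann("g", list("nucleus"))
  sets <- sets_of(list(A = c(g = "up"), B = c(g = "up"), C = c(g = "down")),
                  screened = "g")
  tab <- compartment_summary(sets, ann, "ALL")
  nu <- tab[tab$compartment == "nucleus", ]
  expect_equal(nu$n_up, 1)
  expect_equal(nu$n_mixed, 0)

  sets <- sets_of(list(A = c(g = "up"), B = c(g = "down")), screened = "g")
  nu <- compartment_summary(sets, ann, "ALL")
  expect_equal(nu$n_mixed[nu$compartment == "nucleus"], 1)
  expect_equal(nu$n_up[nu$compartment == "nucleus"], 0)
})

test_that("region scope counts that region's calls only", {
  ann <- make_ann(c("a", "b"), list("dynein", "dynein"))
  sets <- sets_of(list(PVC = c(a = "up"), OFC = c(a = "down", b = "down")),
                  screened = c("a", "b"))
  tab <- compartment_summary(sets, ann, "PVC")
  expect_equal(tab$n_dega[tab$compartment == "dynein"], 1)
  tab <- compartment_summary(sets, ann, "OFC")
  expect_equal(tab$n_dega[tab$compartment == "dynein"], 2)
  expect_error(compartment_summary(sets, ann, "XXX"), "unknown scope")
})

test_that("unannotated screened genes warn and fall to 'other'", {
  ann <- make_ann("a", list("axoneme"))
  sets <- sets_of(list(PVC = c(a = "up", z = "up")),
                  screened = c("a", "z"))
  expect_warning(tab <- compartment_summary(sets, ann, "ALL"), "lack annotation")
  expect_equal(tab$n_dega[tab$compartment == "other"], 1)
  expect_error(compartment_summary(sets, ann, "ALL",
                                   missing_annotation = "error"),
               "lack annotation")
})

test_that("direction breakdown reports per-region fractions, NA when empty", {
  ann <- make_ann(c("m1", "m2", "m3"), rep(list("mitochondria"), 3))
  sets <- sets_of(list(
    PVC = c(m1 = "down", m2 = "down", m3 = "down"),
    Cer = c(m1 = "up", m2 = "down"),
    Hipp = stats::setNames(character(), character())
  ), screened = c("m1", "m2", "m3"))
  tab <- direction_breakdown(sets, ann, "mitochondria")
  expect_equal(tab$frac_down[tab$region == "PVC"], 1)
  expect_equal(tab$frac_down[tab$region == "Cer"], 0.5)
  expect_true(is.na(tab$frac_down[tab$region == "Hipp"]))
  expect_equal(tab$frac_up + tab$frac_down,
               ifelse(tab$n_dega > 0, 1, NA_real_))
  expect_error(direction_breakdown(sets, ann, "flagellum"),
               "unknown compartment")
})

test_that("compartment totals bound the annotated DEGA union", {
  set.seed(81)
  genes <- paste0("g", 1:40)
  comps <- lapply(seq_along(genes), function(i)
    sample(cilia_compartments(), sample(1:2, 1)))
  ann <- make_ann(genes, comps)
  deg <- sample(genes, 18)
  sets <- sets_of(list(PVC = stats::setNames(
    sample(c("up", "down"), 18, TRUE), deg)), screened = genes)
  tab <- compartment_summary(sets, ann, "ALL")
  expect_gte(sum(tab$n_dega), length(deg))
  expect_true(all(tab$n_dega <= tab$n_total))
  expect_true(all(tab$n_up + tab$n_down + tab$n_mixed == tab$n_dega))
})
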