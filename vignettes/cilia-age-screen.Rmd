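---
title: "Screening cilia gene expression for linear age trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cilia gene expression for linear age trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliascreen)
```

## The model

Primary cilia are microtubule-based sensory organelles present on most
brain cells, and the expression of the genes encoding their structural and
functional components changes across the human lifespan. `ciliascreen`
quantifies those changes with the simplest defensible model of biological
ageing: for each gene $g$ and each brain region $r$, expression is
regressed on chronological age in years,

$$ y_{gri} = \beta_{0,gr} + \beta_{1,gr}\,\mathrm{age}_i + \varepsilon_{gri},
   \qquad \varepsilon_{gri} \sim N(0, \sigma_{gr}^2), $$

over that region's postnatal samples (ages from 4 months, coded 1/3 year,
to 40 years). The slope $\beta_1$ — the regression coefficient, in
expression units per year — is the age effect; the two-sided $t$-test of
$\beta_1 = 0$ on $n-2$ degrees of freedom gives the pair's p-value. A pair
with raw $p < 0.05$ is called a DEGA (differentially expressed gene with
age), directed up or down by the sign of the slope. Benjamini–Hochberg
q-values computed jointly over all non-degenerate pairs mark a
higher-confidence tier (`fdr_pass`); the raw-p tier defines membership
because every downstream count — per-region totals, overlaps,
compartment percentages — flows from it, with the FDR flag carried
alongside as corroborating evidence.

Expression stays on the provided RPKM-like scale with no log transform:
the model is deliberately the untransformed univariate regression, with no
donor random effects and no sex covariate. Slopes are therefore
interpretable directly (a slope of 22 means 22 expression units gained per
year of life).

## Choices a user can change

* `alpha` (default 0.05): raw p cutoff defining DEGAs.
* `fdr_alpha` (default 0.05): q threshold for the confidence tier.
* `fdr_scope` (default `"global"`): BH correction is applied once across
  the whole screen, matching a search over all gene-region pairs; a
  per-region correction is available but off by default, since the screen
  is a single joint search.
* `min_samples` (default 3): the smallest design with a residual degree of
  freedom. Pairs below it, and pairs with no age spread, are flagged
  `degenerate` and excluded from BH, never silently dropped, so a
  445-gene, 16-region screen always enumerates 7120 rows.

Numerical edge cases are defined rather than erroneous: a constant
response is a true null (slope 0, $p = 1$, $R^2 = 0$); an exact linear fit
(residual sum of squares numerically zero, tolerance $10^{-12}$ relative
to the total sum of squares) is flagged `perfect_fit` with $p = 0$ and its
$-\log_{10} p$ capped at 300 in volcano tables. Perfect fits count as
DEGA-eligible: a zero-residual trend is the strongest possible linear
evidence, and excluding it on a status technicality would make calls
non-monotone in evidence.

## What the simulator emulates — and what it does not

`simulate_brainspan()` generates data shaped like the atlas design: 42
donors by default (sexes split 19 F / 23 M), ages uniform on the postnatal
range and snapped to whole months so they survive the `"N mos"/"N yrs"`
file dialect exactly, 16 regions with incomplete donor-by-region coverage
(default 20% of combinations missing), and one age per donor shared across
regions — one brain, many dissections — which induces the cross-region
dependence that makes overlap counts non-independent. A configurable
fraction of gene-region pairs (default 0.18, the share of significant
pairs in the screen the simulator is shaped after: 1288 of 7120) carries a
true linear effect with slope magnitude uniform on 0.1–5 units/year,
bracketing the coefficient range such screens report; the rest are null.
Noise is additive Gaussian on the raw scale (default SD 10) and values are
truncated at zero with a logged count — genes with negative slopes start
from an elevated baseline so truncation stays rare and OLS recovery exact.

The simulator does not emulate count overdispersion, donor covariates
beyond age/sex/region, nonlinear trajectories, or correlated noise between
genes. Passing tests therefore demonstrate that the screen's statistics
are correct and calibrated under its own model assumptions; they do not
certify behaviour under the heavier tails or batch structure of real
RNA-seq, where the linear model is an approximation by design.

## Downstream summaries

`dega_sets()` extracts per-region membership with direction;
`overlap_matrix()` counts pairwise intersections ignoring direction (a
gene rising in one region and falling in another still overlaps — the
convention under which a ubiquitous but discordant gene reaches every
region); `shared_in_k()` histograms genes by how many regions share them;
`build_network()` exports the bipartite gene-region graph (GraphML + edge
list; node size = degree; layout is presentation, not analysis, and is
not computed). `pearson_matrix()` correlates raw expression of a region's
DEGAs over that region's samples and orders genes by average-linkage
clustering on $1 - R$ — linkage and distance are our choice (the display
convention is not dictated by the model) and both are configurable
through `cluster_order()`. `compartment_summary()` rolls calls up to
cilia sub-structures; genes annotated to several compartments count once
in each, so compartment denominators overlap rather than partition the
panel, and a whole-brain direction is the majority across a gene's DEGA
regions with exact ties reported in an explicit `mixed` bucket rather
than forced to a side.

`power_slope_test()` gives the noncentral-$t$ power of the slope test
(noncentrality $\beta_1\sqrt{S_{xx}}/\sigma$), parameterised by slope,
noise SD and design — the parameterisation closest to the screen itself —
with a Monte-Carlo companion. At slope 0 it equals the test size exactly.

## Problem sizes used in the tests

The packaged checks run the full 445-gene, 16-region enumeration (7120
fits), a 10,000-pair null calibration at $n = 42$, slope-recovery coverage
over 560 planted-effect pairs, and oracle comparisons on 1,000 random
small regressions — sizes chosen to exercise the study design at full
scale while keeping each property estimable with tight binomial error.

## Worked example

```{r example}
sim <- simulate_brainspan(n_genes = 60, n_donors = 42,
                          regions = c("PVC", "OFC", "Hipp"), seed = 1)
scr <- cilia_screen(sim)
scr
head(summary(scr))
ov <- overlap_matrix(scr)
ov
```

## Known limitations

Linearity is an assumption, not a finding: genes with U-shaped or
saturating trajectories are under-called. The raw-p DEGA tier accepts a
5% false positive rate per pair by construction — the FDR flag exists
precisely to mark the subset that survives multiplicity control. The
packaged gene panel is a synthetic stand-in (real cilia gene symbols
seeded per compartment, remainder placeholders) for a curated 445-gene
list; analyses of real data should supply their own annotation TSV via
`load_gene_list()`.
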