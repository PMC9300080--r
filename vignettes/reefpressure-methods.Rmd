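---
title: "Methods: cumulative impact, management indices, and the synthetic study system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cumulative impact, management indices, and the synthetic study system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefpressure)
```

This vignette is the package's own account of its methods: the cumulative
human impact (CHI) model and its assumptions, the management-index
construction, the association analyses, what the synthetic study system
emulates (and deliberately does not), and the numerical and design choices
made where the method left room.

## The impact model

CHI in a grid cell is the sum over anthropogenic stressors of the
stressor's rescaled intensity multiplied by the vulnerability of the
habitats present:

$$\mathrm{CHI}(c) = \sum_s p_s(c)\,
  \frac{\sum_h \mathbf{1}[h \in c]\, \mu_{h,s}}{\max(1, n_{\mathrm{hab}}(c))}$$

* **Intensities** $p_s \in [0,1]$. Raw layers are $\log(x+1)$-transformed,
  clipped at the `clip_quantile` value (default 0.9999 per layer), and
  divided by it. The global CHI literature this model follows distributes
  pre-rescaled layers without publishing the exact internals, so both the
  transform and the quantile are exposed as configuration rather than baked
  in.
* **Habitat aggregation.** The product form — intensity times each present
  habitat's vulnerability — does not by itself say whether multi-habitat
  cells sum or average. The default here divides by the number of habitats present
  (mean-over-present-habitats), the convention of the cumulative-impact
  mapping literature; `habitat_agg = "sum"` preserves the alternative. This
  is a genuinely open point and is left as a switch rather than guessed
  silently.
* **Categories.** Every stressor belongs to exactly one source category —
  climate, land, or marine — declared in a registry
  (`default_stressor_registry()`), never inferred from names: the
  categorization is a scientific choice, not a string-matching exercise.
  Category rasters are summed first and the total is their sum, so the
  partition is conserved to floating-point exactness by construction, and a
  test asserts it cell-wise.
* **Missing data.** A cell missing in one stressor contributes zero to the
  sums (with a logged count); a cell missing in *every* stressor is missing
  in every output. This keeps sparse single-layer gaps from deleting whole
  cells while still propagating genuinely unobserved areas.

## Snapshot versus change

The 2013 snapshot rescales each layer within its own period; the 2008–2013
change analysis rescales each stressor over both periods pooled
(`rescale_periods()`), so the two periods share one scale and their
difference is meaningful. Snapshot statistics are thus rescaled by one
period and change statistics by two — the only reading under which period
differences are comparable.

ΔCHI sums differences over **change-eligible** stressors only. The default
registry flags seven of the 19 as ineligible — sea-level rise, shipping,
invasive species, and ocean pollution (no data in both periods), plus ocean
acidification, artisanal fishing, and inorganic pollution (no difference
between periods). Ineligible stressors contribute exactly zero, and a test
verifies that a world in which *only* ineligible layers change yields an
identically zero ΔCHI raster. Because seven stressors are excluded, ΔCHI
understates true change; that bias is inherited from the method, not
introduced here.

## Zonal statistics

BCU polygons are clipped to EEZ polygons (the EEZs end at the 200-nautical-
mile limit, so clipping also restricts the analysis to the portions of BCUs
within 200 nm of shore), producing one `bcu_country_portion` zone per
non-empty intersection.

* **Cell inclusion** is by cell-center-in-polygon, not "all touched":
  unbiased for interior zones and the common zonal-statistics default. The
  synthetic plane snaps polygon edges to cell boundaries, so centers never
  sit exactly on an edge and the even-odd ray-cast is unambiguous.
* **BCU summaries** pool the cells of all of a BCU's portions: a BCU is one
  ecological unit, and its published per-BCU statistics are unit-level, not
  portion-level.
* **Country summaries** default to the unweighted mean over the country's
  portion means, reading a country's statistic as an average across the
  BCUs in its waters. Whether such averages should instead pool every cell
  of the country's portions is genuinely ambiguous, so
  `method = "pooled"` reports the alternative; on the synthetic world the
  two differ by a few percent.
* Geometry is validated at construction (simple rings, positive area), and
  clipping uses Sutherland–Hodgman against convex EEZs. The plane is
  declared equal-area Cartesian ("synthetic, unit = km"), so areas and
  means need no reprojection — the analysis contract, not Earth's shape, is
  what the package tests.

## The management index

For each category, each metric is min-max normalized across the analyzed
country set — $(X - X_{\min})/(X_{\max} - X_{\min})$, inverted for
lower-is-better metrics such as emissions-change — then missing scores are
imputed, then components are averaged with equal weight.

Choices worth stating explicitly:

* **Direction flags are data**, a column in the metric table. A
  normalized score of 1 is always the better score, so which metrics invert
  (emissions growth, for instance, is better when lower) must be declared; `default_metric_registry()` ships a registry mirroring
  the real indices' composition (four climate, four marine, two land
  metrics).
* **Inversion order.** Inverting before or after min-max is mathematically
  identical for this transform; the package inverts after, and a test pins
  the equivalence ($\mathrm{hi} + \mathrm{lo} = 1$).
* **Imputation operates on normalized scores**, not raw values: the
  regional average being borrowed is an average of scores, and averaging
  raw values would mix heterogeneous scales. A region with no observed
  value falls back to the global mean; observed scores are never altered.
* **Normalization bounds** come from the analyzed country set only, not
  hypothetical global ranges: the real analysis normalized across its 28
  countries.
* **Collinearity** is diagnosed with Pearson correlations and the standard
  two-sided t-test on $r$ with $n-2$ degrees of freedom (the method names
  no test; this is the default choice). Flagged pairs are reported and
  *kept* with equal weights, matching the published decision. On the
  synthetic world the within-category metrics are strongly correlated by
  construction — they share one latent commitment — so flags there are
  expected, not alarming.

## Association and quadrants

Mean impact (or mean change) is regressed on the index per category by OLS.
**Adjusted** R² is the headline statistic because near-null fits are
reported downstream with negative values, which only adjusted R² produces;
raw R² is also emitted. The slope p-value is the usual two-sided t-test.

Outlier sensitivity supports two modes: a 1.5×IQR fence rule on either
variable (default), and a caller-named exclusion list — the published
sensitivity analysis names its outlier countries without stating a rule, so
both semantics are provided rather than guessing the rule.

Quadrant classification splits both axes at the across-unit median with
**ties counting as high**: a unit exactly at the median is classified into
the high group on that axis. A property test
checks agreement with an independent straight-line comparator on rounded
data where ties are frequent.

## The synthetic study system

`world_config()` + `generate_world()` produce a fully self-contained world
with known ground truth:

* **Geometry.** A 64×64 grid of 10-km cells by default: a land strip along
  the north, country EEZs tiling the band from shore to the 200-nm limit,
  high seas beyond. BCUs are cell-aligned rectangles placed on a slot grid
  spanning 1–3 *adjacent* countries with probabilities 0.76/0.16/0.08 —
  the observed frequencies in the real 50-BCU table — and some
  southernmost BCUs extend past the 200-nm limit so the clipping step has
  real work. The generator emits its membership table alongside the
  geometry, and a test checks the clipped portion count equals it.
* **Stressors.** Smooth seeded random fields (Gaussian-blurred white noise,
  min-max rescaled) shaped by a per-category exponent: climate layers are
  near-saturated everywhere (exponent 0.3), marine layers are sparse
  hotspot fields (exponent 3), land layers sit between (1.5) and decay
  exponentially with distance from shore. These shapes reproduce the
  observed structure in which the climate category dominates CHI with
  marine second and land least; on the default world the mean contributions
  are roughly 61/25/13% climate/marine/land against the reported
  69/24/7%.
* **Trends.** 2013 = 2008 + category trend + centered smooth noise, clipped
  to [0,1]. Defaults are climate +0.35, land +0.005, marine −0.02 —
  following the reported directions (climate strongly rising, land
  approximately flat, marine slightly falling) and their relative
  magnitudes, under which overall CHI rises in nearly all units. A
  property test confirms the injected signs are recovered by the full
  change analysis in ≥ 9 of 10 seeds.
* **Metrics.** Each country has one latent management commitment per
  category; metric raw values are affine maps of it on heterogeneous scales
  (negated for lower-is-better metrics) plus noise, with 15% of cells
  blanked to missing by default. With noise and missingness switched off,
  the recomputed index reproduces the latent rank order exactly — the
  recovery test for the whole index chain.

**What passing tests do and do not show.** The generator emulates the
*contracts* of the real data — value ranges, category structure, trend
directions, membership patterns, missingness — not coastline geometry, real
stressor magnitudes, spatial covariance of real pressures, or the
political realities behind metric values. Green tests certify the pipeline
computes its statistics correctly and reproducibly on data with this
structure; they say nothing about the real-world magnitudes, which require
the original global rasters.

## Numerical choices and degenerate inputs

* Determinism: every generator stage seeds the RNG from `seed` plus a fixed
  stage offset, so stages are reproducible independently of call order;
  serialized numbers are formatted at fixed precision, so identical worlds
  and identical runs are byte-identical on disk (tested file-by-file).
* A clip value of 0 (all-zero layer) yields an all-zero output with a
  warning rather than 0/0. An all-missing raster is an error.
* `Xmax = Xmin` in normalization scores all observed countries 0.5 with a
  warning — no information, so no ranking.
* A constant index component makes its correlations undefined; they are
  reported as `NA`, unflagged.
* Zones containing no cell centers produce `NA` with a warning; countries
  whose portions are all empty are excluded with a warning.
* Percent contributions are undefined (`NA`) where mean CHI is 0; otherwise
  they sum to 1 within 1e-9 by construction and by test.

## Problem sizes

The default world is 64×64 cells with 6 countries and 10 BCUs; property
suites use 32×32 worlds, 5×5 micro-worlds for oracle comparisons, and
28-country tables (the real analysis's country count) for the regression
coverage (500 replicates) and collinearity false-positive (1000 replicates)
studies. These sizes give stable Monte-Carlo rates while keeping the whole
suite fast enough to run habitually.

## Known limitations

* The membership fixture reports direct counts. A published summary
  statistic put the share of countries containing a single BCU at 28%,
  which does not match a direct count on the published table itself (13 of
  28 countries — 46% — contain exactly one BCU); the package reports the
  direct count and documents the discrepancy rather than reconciling it.
* Synthetic EEZs are convex rectangles; the clipping routine requires
  convex clip polygons. Real EEZ polygons are accepted as inputs only if
  convex or pre-decomposed.
* The change analysis inherits the underestimation from the seven excluded
  stressors.
* The indices measure management *intent*, not effectiveness; the package
  computes associations, and none of its outputs support causal readings.
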