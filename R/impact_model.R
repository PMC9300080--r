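#' Rescale a raw stressor layer to [0, 1]
#'
#' Applies the standard cumulative-impact preprocessing: a log(x + 1)
#' transform, clipping at a high quantile to tame outliers, and division by
#' the clip value. For the two-period change analysis the clip value must be
#' pooled over both periods so the periods stay comparable; pass the other
#' period's raster as \code{ref} ("rescaled by two periods"). A snapshot
#' analysis rescales within its own period ("rescaled by one period").
#'
#' @param raw an \code{rp_raster} of nonnegative raw intensities.
#' @param clip_quantile quantile in (0, 1] at which values are clipped.
#' @param ref optional second \code{rp_raster} pooled with \code{raw} when
#'   computing the clip value (joint-period rescaling).
#' @return an \code{rp_raster} with values in [0, 1]; NA cells stay NA.
#' @export
rescale_stressor <- function(raw, clip_quantile = 0.9999, ref = NULL) {
  stopifnot(inherits(raw, "rp_raster"), clip_quantile > 0, clip_quantile <= 1)
  v <- raw$values
  if (all(is.na(v))) stop("rescale_stressor: all-missing raster")
  lv <- log1p(v)
  pool <- lv
  if (!is.null(ref)) {
    stopifnot(inherits(ref, "rp_raster"))
    if (!same_grid(raw, ref)) stop("rescale_stressor: ref on a different grid")
    pool <- c(lv, log1p(ref$values))
  }
  clip <- stats::quantile(pool, clip_quantile, na.rm = TRUE, names = FALSE)
  if (clip == 0) {
    warning("rescale_stressor: clip value 0; returning all-zero layer")
    return(raster_like(raw, ifelse(is.na(v), NA_real_, 0)))
  }
  raster_like(raw, pmin(lv, clip) / clip)
}

#' Rescale both periods of one stressor jointly
#'
#' @param r2008,r2013 \code{rp_raster}s of the two periods.
#' @param clip_quantile clip quantile; the clip value is pooled over both
#'   periods.
#' @return list with elements \code{`2008`} and \code{`2013`}.
#' @export
rescale_periods <- function(r2008, r2013, clip_quantile = 0.9999) {
  list(`2008` = rescale_stressor(r2008, clip_quantile, ref = r2013),
       `2013` = rescale_stressor(r2013, clip_quantile, ref = r2008))
}

category_of <- function(stressors) {
  stats::setNames(vapply(stressors, `[[`, "", "category"),
                  vapply(stressors, `[[`, "", "name"))
}

#' Compute the cumulative human impact stack
#'
#' Per-stressor impact at a cell is the stressor intensity times the summed
#' vulnerability of the habitats present there, divided (by default) by the
#' number of habitats present, so a cell's impact is the mean impact over
#' its habitats. Cells with no habitat score 0. The total CHI raster is the
#' sum over stressors, partitioned into climate, land, and marine category
#' rasters.
#'
#' Missing intensity cells contribute 0 to the sums unless every stressor is
#' missing at that cell, in which case the cell is missing in every output
#' raster; a count of partially-missing cells is attached as an attribute.
#'
#' @param stressors list of stressor layers for one period (each with
#'   \code{name}, \code{category}, \code{raster}).
#' @param habitats list of habitat layers (\code{name}, \code{presence}).
#' @param vuln vulnerability matrix, rows = habitat names, columns = stressor
#'   names.
#' @param habitat_agg "mean" (divide by habitats present; the default) or
#'   "sum" (straight summation over habitats).
#' @return an \code{impact_stack}: list with \code{total} (\code{rp_raster}),
#'   \code{per_category} (named list of rasters), \code{per_stressor} (named
#'   list), and \code{categories} (stressor name to category map).
#' @export
compute_impact <- function(stressors, habitats, vuln,
                           habitat_agg = c("mean", "sum")) {
  habitat_agg <- match.arg(habitat_agg)
  stopifnot(length(stressors) >= 1, length(habitats) >= 1)
  template <- stressors[[1]]$raster
  for (s in stressors)
    if (!same_grid(template, s$raster))
      stop("compute_impact: grid mismatch in stressor '", s$name, "'")
  for (h in habitats)
    if (!same_grid(template, h$presence))
      stop("compute_impact: grid mismatch in habitat '", h$name, "'")
  snames <- vapply(stressors, `[[`, "", "name")
  hnames <- vapply(habitats, `[[`, "", "name")
  missing_mu <- setdiff(snames, colnames(vuln))
  if (length(missing_mu) || !all(hnames %in% rownames(vuln)))
    stop("compute_impact: vulnerability matrix lacks entries for: ",
         paste(c(missing_mu, setdiff(hnames, rownames(vuln))), collapse = ", "))
  if (any(vuln < 0)) stop("compute_impact: negative vulnerability weight")

  nr <- nrow(template$values); ncells <- length(template$values)
  pres <- lapply(habitats, function(h) h$presence$values)
  n_present <- Reduce(`+`, pres)
  denom <- if (habitat_agg == "mean") pmax(1, n_present) else 1

  per_stressor <- vector("list", length(stressors))
  names(per_stressor) <- snames
  all_na <- matrix(TRUE, nr, ncol(template$values))
  n_partial_missing <- 0L
  for (i in seq_along(stressors)) {
    s <- stressors[[i]]
    w <- matrix(0, nr, ncol(template$values))
    for (h in seq_along(habitats))
      w <- w + pres[[h]] * vuln[hnames[h], s$name]
    intensity <- s$raster$values
    na_here <- is.na(intensity)
    all_na <- all_na & na_here
    n_partial_missing <- n_partial_missing + sum(na_here)
    intensity[na_here] <- 0
    per_stressor[[i]] <- intensity * w / denom
  }
  if (n_partial_missing > 0)
    message("compute_impact: ", n_partial_missing,
            " missing intensity cells treated as 0")

  cat_map <- category_of(stressors)
  per_category <- lapply(c(climate = "climate", land = "land",
                           marine = "marine"), function(cat) {
    members <- per_stressor[names(cat_map)[cat_map == cat]]
    if (!length(members)) matrix(0, nr, ncol(template$values))
    else Reduce(`+`, members)
  })
  total <- Reduce(`+`, per_category)
  total[all_na] <- NA_real_
  per_category <- lapply(per_category, function(m) {
    m[all_na] <- NA_real_; raster_like(template, m)
  })
  per_stressor <- lapply(per_stressor, function(m) {
    m[all_na] <- NA_real_; raster_like(template, m)
  })
  structure(list(total = raster_like(template, total),
                 per_category = per_category,
                 per_stressor = per_stressor,
                 categories = cat_map),
            class = "impact_stack")
}

#' @export
print.impact_stack <- function(x, ...) {
  cat(sprintf("<impact_stack: %d stressors (%s)>\n", length(x$per_stressor),
              paste(sprintf("%s=%d", names(table(x$categories)),
                            as.integer(table(x$categories))), collapse = ", ")))
  print(x$total)
  invisible(x)
}

#' Change in cumulative impact between two periods
#'
#' Sums per-stressor impact differences (2013 minus 2008) over the
#' change-eligible stressors only; stressors flagged ineligible (those
#' lacking comparable data across both periods) contribute exactly zero.
#' Both stacks must come from jointly-rescaled layers so the difference is
#' meaningful.
#'
#' @param stack_2008,stack_2013 \code{impact_stack}s built on the same grid
#'   from the same stressor set.
#' @param eligibility named logical vector over stressor names.
#' @return list with \code{total} (delta raster), \code{per_category}, and
#'   \code{per_stressor}.
#' @export
change_in_impact <- function(stack_2008, stack_2013, eligibility) {
  snames <- names(stack_2008$per_stressor)
  stopifnot(identical(snames, names(stack_2013$per_stressor)))
  if (!all(snames %in% names(eligibility)))
    stop("change_in_impact: eligibility flag missing for: ",
         paste(setdiff(snames, names(eligibility)), collapse = ", "))
  template <- stack_2008$total
  zero <- matrix(0, nrow(template$values), ncol(template$values))
  deltas <- lapply(snames, function(nm) {
    if (!eligibility[[nm]]) return(zero)
    stack_2013$per_stressor[[nm]]$values - stack_2008$per_stressor[[nm]]$values
  })
  names(deltas) <- snames
  cat_map <- stack_2008$categories
  per_category <- lapply(c(climate = "climate", land = "land",
                           marine = "marine"), function(cat) {
    members <- deltas[names(cat_map)[cat_map == cat]]
    raster_like(template, if (!length(members)) zero else Reduce(`+`, members))
  })
  total <- Reduce(`+`, lapply(per_category, `[[`, "values"))
  list(total = raster_like(template, total),
       per_category = per_category,
       per_stressor = lapply(deltas, raster_like, template = template))
}
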