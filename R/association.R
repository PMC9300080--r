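#' Ordinary least squares of mean impact on a management index
#'
#' Fits y ~ x by OLS across countries and reports the adjusted R-squared as
#' the headline statistic (adjusted R-squared can be negative, which matches
#' how near-null fits are reported downstream) together with the raw
#' R-squared and the two-sided t-test p-value on the slope.
#'
#' @param x numeric vector, the management index per unit (predictor).
#' @param y numeric vector, the mean impact (or mean change in impact) per
#'   unit (response).
#' @param ids optional unit identifiers, used in sensitivity reporting.
#' @return list of class \code{rp_regression}: slope, intercept, r_squared,
#'   r_squared_adj, p_value, n, outliers_removed.
#' @export
fit_index_regression <- function(x, y, ids = NULL) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (!is.null(ids)) ids <- ids[ok]
  n <- length(x)
  if (n < 3) stop("fit_index_regression: need at least 3 complete pairs")
  if (stats::sd(x) == 0) stop("fit_index_regression: zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) < 2 || is.nan(sm$coefficients[2, 4])) NA_real_
  else sm$coefficients[2, 4]
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 r_squared_adj = sm$adj.r.squared,
                 p_value = p, n = n,
                 slope_se = sm$coefficients[2, 2],
                 outliers_removed = character(0)),
            class = "rp_regression")
}

#' @export
print.rp_regression <- function(x, ...) {
  cat(sprintf("OLS y ~ x: slope %.4g, adj R^2 = %.3g, p = %.3g, n = %d\n",
              x$slope, x$r_squared_adj, x$p_value, x$n))
  if (length(x$outliers_removed))
    cat("  outliers removed:", paste(x$outliers_removed, collapse = ", "), "\n")
  invisible(x)
}

#' Median-split quadrant classification
#'
#' Units at or above the median on an axis are "high" on that axis (ties at
#' the median classify as high). Medians are computed across the supplied
#' unit set.
#'
#' @param ids unit identifiers.
#' @param x,y numeric axis values (complete).
#' @param x_name,y_name axis labels carried into the output.
#' @return list with \code{labels} (data frame: unit_id, x, y, quadrant) and
#'   \code{counts} (named counts for the four quadrants).
#' @export
classify_quadrants <- function(ids, x, y, x_name = "x", y_name = "y") {
  stopifnot(length(ids) == length(x), length(x) == length(y),
            !anyNA(x), !anyNA(y))
  if (length(ids) < 2) stop("classify_quadrants: need at least 2 units")
  mx <- stats::median(x); my <- stats::median(y)
  hx <- x >= mx; hy <- y >= my
  quadrant <- ifelse(hx & hy, "high_x_high_y",
                     ifelse(hx & !hy, "high_x_low_y",
                            ifelse(!hx & hy, "low_x_high_y", "low_x_low_y")))
  labels <- data.frame(unit_id = ids, x = x, y = y,
                       x_axis = x_name, y_axis = y_name,
                       quadrant = quadrant, stringsAsFactors = FALSE)
  lvls <- c("high_x_high_y", "high_x_low_y", "low_x_high_y", "low_x_low_y")
  counts <- table(factor(quadrant, levels = lvls))
  list(labels = labels, counts = counts,
       median_x = mx, median_y = my)
}

#' Outlier-removal sensitivity refit
#'
#' Identifies outliers either by the 1.5 x IQR fence rule applied to each
#' variable (a point is an outlier if it lies beyond the fences on either
#' axis) or by a caller-supplied list of unit identifiers (matching how
#' published sensitivity analyses name their excluded countries), then
#' refits the regression without them.
#'
#' @param x,y numeric vectors (complete pairs used).
#' @param ids unit identifiers.
#' @param rule "iqr" or "named".
#' @param k fence multiplier for the IQR rule.
#' @param named identifiers to exclude when \code{rule = "named"}.
#' @return list with \code{outliers} (identifiers) and \code{fit} (the
#'   refit \code{rp_regression}; identical to the full fit when nothing is
#'   excluded).
#' @export
sensitivity_refit <- function(x, y, ids, rule = c("iqr", "named"),
                              k = 1.5, named = NULL) {
  rule <- match.arg(rule)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; ids <- ids[ok]
  if (length(x) < 5) stop("sensitivity_refit: need at least 5 complete pairs")
  if (rule == "iqr") {
    fence <- function(v) {
      q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
      v < q[1] - k * diff(q) | v > q[2] + k * diff(q)
    }
    out <- fence(x) | fence(y)
  } else {
    if (is.null(named)) stop("sensitivity_refit: rule 'named' needs `named`")
    out <- ids %in% named
  }
  keep <- !out
  if (sum(keep) < 3)
    stop("sensitivity_refit: outlier rule leaves fewer than 3 points")
  fit <- fit_index_regression(x[keep], y[keep], ids[keep])
  fit$outliers_removed <- ids[out]
  list(outliers = ids[out], fit = fit)
}
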