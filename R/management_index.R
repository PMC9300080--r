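#' Directional min-max normalization of one metric
#'
#' Scores are (X - Xmin) / (Xmax - Xmin) over the non-missing values of the
#' analyzed country set, so 1 is always the better score; for
#' lower-is-better metrics the score is one minus that quantity. Missing
#' values stay missing (imputation is a separate step).
#'
#' @param values named numeric vector of raw per-country values (may contain
#'   NA).
#' @param direction "higher_better" or "lower_better".
#' @return numeric vector of scores in [0, 1] with NAs preserved.
#' @export
normalize_metric <- function(values, direction = c("higher_better",
                                                   "lower_better")) {
  direction <- match.arg(direction)
  obs <- values[!is.na(values)]
  if (length(obs) < 1) stop("normalize_metric: no observed values")
  rng <- range(obs)
  if (diff(rng) == 0) {
    warning("normalize_metric: degenerate spread (Xmax = Xmin); ",
            "scoring all observed values 0.5")
    out <- ifelse(is.na(values), NA_real_, 0.5)
    return(stats::setNames(out, names(values)))
  }
  score <- (values - rng[1]) / diff(rng)
  if (direction == "lower_better") score <- 1 - score
  score
}

#' Regional imputation of missing normalized scores
#'
#' Each missing score is replaced by the mean score of the countries sharing
#' its UN-style geopolitical region; if a whole region is missing, the global
#' mean of observed scores is used. Observed scores are never altered.
#'
#' @param scores named numeric vector of normalized scores (NAs to fill).
#' @param regions character vector of region labels, parallel to
#'   \code{scores}.
#' @return list with \code{scores} (completed) and \code{imputed} (logical
#'   flags).
#' @export
impute_regional <- function(scores, regions) {
  stopifnot(length(scores) == length(regions), !anyNA(regions))
  if (all(is.na(scores)))
    stop("impute_regional: all countries missing; metric unusable")
  imputed <- is.na(scores)
  global_mean <- mean(scores, na.rm = TRUE)
  for (i in which(imputed)) {
    peers <- scores[regions == regions[i]]
    fill <- mean(peers, na.rm = TRUE)
    scores[i] <- if (is.nan(fill)) global_mean else fill
  }
  list(scores = scores, imputed = imputed)
}

#' Equal-weight index from normalized, imputed components
#'
#' @param components numeric matrix (countries x metrics) of complete scores
#'   in [0, 1].
#' @return numeric vector: the arithmetic mean across metrics per country.
#' @export
compute_index <- function(components) {
  components <- as.matrix(components)
  if (ncol(components) < 1) stop("compute_index: zero components")
  if (anyNA(components))
    stop("compute_index: components must be complete (impute first)")
  rowMeans(components)
}

#' Build the per-country management indices from a raw metric table
#'
#' For each category (climate, marine, land): normalize every metric by
#' directional min-max over the analyzed countries, impute missing scores
#' from regional means, and average the components with equal weight. Also
#' runs the pairwise collinearity diagnostics; correlated components are
#' reported but never dropped (equal weighting is retained throughout).
#'
#' @param metric_table long data frame with columns \code{country},
#'   \code{region}, \code{category}, \code{metric}, \code{raw_value},
#'   \code{direction}.
#' @return list with \code{index} (country, category, score),
#'   \code{components} (long: country, category, metric, score, imputed),
#'   and \code{collinearity} (one diagnostic row per component pair per
#'   category).
#' @export
build_management_index <- function(metric_table) {
  need <- c("country", "region", "category", "metric", "raw_value", "direction")
  stopifnot(all(need %in% names(metric_table)))
  if (anyDuplicated(metric_table[, c("country", "metric")]))
    stop("build_management_index: duplicate (country, metric) rows")
  countries <- sort(unique(metric_table$country))
  regions <- metric_table$region[match(countries, metric_table$country)]

  index_rows <- list(); comp_rows <- list(); coll_rows <- list()
  for (cat in c("climate", "marine", "land")) {
    sub <- metric_table[metric_table$category == cat, ]
    if (!nrow(sub)) stop("build_management_index: no metrics for category ", cat)
    metrics <- unique(sub$metric)
    comp <- matrix(NA_real_, length(countries), length(metrics),
                   dimnames = list(countries, metrics))
    imput <- matrix(FALSE, length(countries), length(metrics),
                    dimnames = dimnames(comp))
    for (m in metrics) {
      rows <- sub[sub$metric == m, ]
      vals <- stats::setNames(rep(NA_real_, length(countries)), countries)
      vals[rows$country] <- rows$raw_value
      scr <- normalize_metric(vals, unique(rows$direction))
      imp <- impute_regional(scr, regions)
      comp[, m] <- imp$scores
      imput[, m] <- imp$imputed
    }
    score <- compute_index(comp)
    index_rows[[cat]] <- data.frame(country = countries, category = cat,
                                    score = score, stringsAsFactors = FALSE)
    comp_rows[[cat]] <- data.frame(
      country = rep(countries, times = length(metrics)),
      category = cat,
      metric = rep(metrics, each = length(countries)),
      score = as.vector(comp), imputed = as.vector(imput),
      stringsAsFactors = FALSE)
    cc <- collinearity_check(comp)
    coll_rows[[cat]] <- cbind(category = rep(cat, nrow(cc)), cc)
  }
  list(index = do.call(rbind, c(index_rows, make.row.names = FALSE)),
       components = do.call(rbind, c(comp_rows, make.row.names = FALSE)),
       collinearity = do.call(rbind, c(coll_rows, make.row.names = FALSE)))
}

#' Pairwise collinearity diagnostics for index components
#'
#' Pearson correlation for every pair of components, with the standard
#' two-sided t-test on r (n - 2 degrees of freedom). Pairs with p < 0.05 are
#' flagged; nothing is dropped. Constant components make r undefined and are
#' reported as such.
#'
#' @param components numeric matrix (countries x metrics).
#' @param alpha flagging threshold on the p-value.
#' @return data frame: metric_a, metric_b, n, r, r_squared, p_value, flagged.
#' @export
collinearity_check <- function(components, alpha = 0.05) {
  components <- as.matrix(components)
  m <- ncol(components)
  if (m < 2)
    return(data.frame(metric_a = character(0), metric_b = character(0),
                      n = integer(0), r = numeric(0), r_squared = numeric(0),
                      p_value = numeric(0), flagged = logical(0)))
  out <- list()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      x <- components[, i]; y <- components[, j]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        out[[length(out) + 1L]] <- data.frame(
          metric_a = colnames(components)[i], metric_b = colnames(components)[j],
          n = n, r = NA_real_, r_squared = NA_real_, p_value = NA_real_,
          flagged = FALSE, stringsAsFactors = FALSE)
        next
      }
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      out[[length(out) + 1L]] <- data.frame(
        metric_a = colnames(components)[i], metric_b = colnames(components)[j],
        n = n, r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
        p_value = ct$p.value, flagged = ct$p.value < alpha,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
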