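#' Clip BCUs to EEZ waters and split them by country
#'
#' Intersects every BCU polygon with every (convex) EEZ polygon, yielding one
#' zone per non-empty BCU-by-country portion. This implements the rule that
#' only the portions of BCUs within 200 nautical miles of shore are analyzed:
#' EEZ polygons end at the 200-nm limit, so anything beyond it (or over land)
#' is dropped. The union of a BCU's portions equals the BCU intersected with
#' all EEZs.
#'
#' @param bcu_polygons list of \code{rp_zone} of kind "bcu".
#' @param eez_polygons list of \code{rp_zone} of kind "eez" (convex,
#'   non-overlapping).
#' @return list of \code{rp_zone} of kind "bcu_country_portion" carrying both
#'   \code{bcuid} and \code{country}.
#' @export
clip_bcus <- function(bcu_polygons, eez_polygons) {
  portions <- list()
  for (b in bcu_polygons) {
    for (e in eez_polygons) {
      ring <- clip_polygon_convex(b$ring, e$ring)
      if (is.null(ring)) next
      portions[[length(portions) + 1L]] <-
        rp_zone(sprintf("%s_%s", b$zone_id, e$country),
                "bcu_country_portion", ring,
                bcuid = b$bcuid, country = e$country)
    }
  }
  portions
}

#' Indices of raster cells whose centers fall inside a zone
#'
#' @param raster an \code{rp_raster}.
#' @param zone an \code{rp_zone}.
#' @return integer vector of cell indices into \code{raster$values}.
#' @export
zone_cells <- function(raster, zone) {
  cc <- cell_centers(raster)
  bb <- apply(zone$ring, 2, range)
  cand <- which(cc$x >= bb[1, 1] & cc$x <= bb[2, 1] &
                  cc$y >= bb[1, 2] & cc$y <= bb[2, 2])
  if (!length(cand)) return(integer(0))
  cand[points_in_polygon(cc$x[cand], cc$y[cand], zone$ring)]
}

#' Zonal mean of a raster over a zone
#'
#' Mean over non-missing cells whose centers fall inside the zone geometry
#' (cell-center rule, not all-touched).
#'
#' @param raster an \code{rp_raster}.
#' @param zone an \code{rp_zone} on the same plane.
#' @return the mean, or \code{NA} with a warning if the zone contains no
#'   cell centers.
#' @export
zonal_mean <- function(raster, zone) {
  idx <- zone_cells(raster, zone)
  if (!length(idx)) {
    warning("zonal_mean: zone '", zone$zone_id, "' contains no cell centers")
    return(NA_real_)
  }
  mean(raster$values[idx], na.rm = TRUE)
}

summarize_cells <- function(idx, stack, delta = NULL) {
  pick <- function(r) mean(r$values[idx], na.rm = TRUE)
  mean_chi <- pick(stack$total)
  mean_cat <- vapply(stack$per_category, pick, numeric(1))
  pct <- if (isTRUE(mean_chi > 0)) mean_cat / mean_chi
  else stats::setNames(rep(NA_real_, 3), names(mean_cat))
  out <- data.frame(mean_chi = mean_chi,
                    mean_climate = mean_cat[["climate"]],
                    mean_land = mean_cat[["land"]],
                    mean_marine = mean_cat[["marine"]],
                    pct_climate = pct[["climate"]],
                    pct_land = pct[["land"]],
                    pct_marine = pct[["marine"]])
  if (!is.null(delta)) {
    out$delta_chi <- mean(delta$total$values[idx], na.rm = TRUE)
    out$delta_climate <- mean(delta$per_category$climate$values[idx], na.rm = TRUE)
    out$delta_land <- mean(delta$per_category$land$values[idx], na.rm = TRUE)
    out$delta_marine <- mean(delta$per_category$marine$values[idx], na.rm = TRUE)
  }
  out
}

#' Per-BCU impact summaries
#'
#' Pools the cells of all of a BCU's country portions (a BCU is one
#' ecological unit) and reports mean CHI, per-category means, percent
#' contributions, and, when a delta stack is supplied, the change in each.
#'
#' @param portions list of \code{rp_zone} of kind "bcu_country_portion".
#' @param stack an \code{impact_stack}.
#' @param delta optional output of \code{\link{change_in_impact}}.
#' @return data frame, one row per BCU (column \code{bcuid}).
#' @export
summarize_bcu <- function(portions, stack, delta = NULL) {
  ids <- sort(unique(vapply(portions, `[[`, 0L, "bcuid")))
  rows <- lapply(ids, function(b) {
    idx <- unique(unlist(lapply(portions[vapply(portions, `[[`, 0L, "bcuid") == b],
                                zone_cells, raster = stack$total)))
    cbind(data.frame(bcuid = b, n_cells = length(idx)),
          summarize_cells(idx, stack, delta))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-country impact summaries
#'
#' A country's value is, by default, the unweighted mean over the means of
#' the BCU portions in its waters ("averaged across BCUs in each country");
#' \code{method = "pooled"} instead pools every cell of the country's
#' portions.
#'
#' @param portions list of \code{rp_zone} of kind "bcu_country_portion".
#' @param stack an \code{impact_stack}.
#' @param delta optional output of \code{\link{change_in_impact}}.
#' @param method "mean_of_portions" (default) or "pooled".
#' @return data frame, one row per country.
#' @export
summarize_country <- function(portions, stack, delta = NULL,
                              method = c("mean_of_portions", "pooled")) {
  method <- match.arg(method)
  countries <- sort(unique(vapply(portions, `[[`, "", "country")))
  rows <- lapply(countries, function(ctry) {
    mine <- portions[vapply(portions, `[[`, "", "country") == ctry]
    cells <- lapply(mine, zone_cells, raster = stack$total)
    keep <- lengths(cells) > 0
    if (!any(keep)) {
      warning("summarize_country: country '", ctry,
              "' has no portions with cells; excluded")
      return(NULL)
    }
    if (method == "pooled") {
      smry <- summarize_cells(unique(unlist(cells[keep])), stack, delta)
    } else {
      per <- lapply(cells[keep], summarize_cells, stack = stack, delta = delta)
      per <- do.call(rbind, per)
      smry <- as.data.frame(as.list(colMeans(per)))
      # percent contributions recomputed from the averaged category means so
      # they still sum to one
      if (isTRUE(smry$mean_chi > 0)) {
        smry$pct_climate <- smry$mean_climate / smry$mean_chi
        smry$pct_land <- smry$mean_land / smry$mean_chi
        smry$pct_marine <- smry$mean_marine / smry$mean_chi
      }
    }
    cbind(data.frame(country = ctry, n_portions = sum(keep)), smry)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Counts derivable from a BCU-country membership table
#'
#' @param table data frame with columns \code{country} (or \code{iso3}) and
#'   \code{bcuid}; duplicate (country, bcuid) pairs are a fixture-integrity
#'   error.
#' @return list with \code{n_countries}, \code{n_bcus}, \code{n_rows},
#'   \code{bcus_per_country} (named integer vector), and
#'   \code{countries_per_bcu} (histogram: how many BCUs span 1, 2, 3...
#'   countries).
#' @export
membership_counts <- function(table) {
  stopifnot(nrow(table) >= 1)
  key <- if ("iso3" %in% names(table)) "iso3" else "country"
  pairs <- table[, c(key, "bcuid")]
  if (anyDuplicated(pairs))
    stop("membership_counts: duplicate (country, bcuid) rows")
  per_bcu <- table(tapply(pairs[[key]], pairs$bcuid, length))
  list(n_countries = length(unique(pairs[[key]])),
       n_bcus = length(unique(pairs$bcuid)),
       n_rows = nrow(pairs),
       bcus_per_country = sort(table(pairs[[key]]), decreasing = TRUE),
       countries_per_bcu = per_bcu)
}
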