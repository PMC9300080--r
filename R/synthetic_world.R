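#' Configuration for a synthetic study system
#'
#' Describes a self-contained world on an abstract equal-area plane: a strip
#' of land along the northern edge, a band of EEZ waters reaching the
#' declared 200-nautical-mile limit, and high seas beyond it. Countries are
#' vertical strips; BCUs are reef planning units placed in EEZ waters and
#' spanning the waters of 1-3 adjacent countries, mirroring the observed
#' membership structure of real bioclimatic units.
#'
#' Default category trends follow the directions observed in the source
#' system: climate stressor intensities rising between the two periods,
#' marine intensities falling, land intensities approximately flat.
#'
#' @param grid_shape integer (rows, cols) of the raster grid.
#' @param cell_size cell edge length in plane units (km).
#' @param n_countries number of countries (>= 2).
#' @param n_bcus number of BCUs (>= 1).
#' @param n_stressors named integer vector: stressor counts for
#'   \code{climate}, \code{land}, \code{marine}.
#' @param n_habitats number of habitat presence layers (>= 1); the first is
#'   a reef habitat concentrated inside BCUs.
#' @param trend named numeric vector: signed mean intensity shift of each
#'   category between period 1 (2008) and period 2 (2013).
#' @param intensity_shape named numeric vector: per-category exponent
#'   applied to the [0, 1] fields. Exponents below 1 push intensities toward
#'   saturation (climate anomaly layers are elevated almost everywhere);
#'   exponents above 1 make layers sparse hotspot fields (individual fishing
#'   and shipping layers are low over most cells). The defaults reproduce
#'   the observed dominance of the climate category in cumulative impact.
#' @param trend_noise_sd per-cell standard deviation of the smooth noise
#'   field added on top of the category trend.
#' @param smooth_sigma Gaussian smoothing bandwidth (cells) of the random
#'   fields.
#' @param metric_missing_rate fraction of metric cells blanked to missing,
#'   in [0, 1).
#' @param metric_noise_sd noise on metric values, as a fraction of each
#'   metric's scale.
#' @param seed integer RNG seed; identical configs reproduce identical
#'   worlds file-for-file.
#' @return a validated list of class \code{world_config}.
#' @export
world_config <- function(grid_shape = c(64, 64), cell_size = 10,
                         n_countries = 6, n_bcus = 10,
                         n_stressors = c(climate = 4, land = 5, marine = 10),
                         n_habitats = 5,
                         trend = c(climate = 0.35, land = 0.005, marine = -0.02),
                         intensity_shape = c(climate = 0.3, land = 1.5,
                                             marine = 3),
                         trend_noise_sd = 0.03, smooth_sigma = 2,
                         metric_missing_rate = 0.15, metric_noise_sd = 0.1,
                         seed = 1) {
  if (length(grid_shape) != 2 || any(grid_shape < 8))
    stop("grid_shape must be (rows, cols) with both >= 8")
  if (n_countries < 2) stop("n_countries must be >= 2")
  if (n_bcus < 1) stop("n_bcus must be >= 1")
  if (metric_missing_rate < 0 || metric_missing_rate >= 1)
    stop("metric_missing_rate must be in [0, 1)")
  cats <- c("climate", "land", "marine")
  if (!all(cats %in% names(n_stressors)))
    stop("n_stressors needs entries for climate, land, marine")
  if (!all(cats %in% names(trend)))
    stop("trend needs entries for climate, land, marine")
  if (!all(cats %in% names(intensity_shape)))
    stop("intensity_shape needs entries for climate, land, marine")
  if (any(intensity_shape <= 0)) stop("intensity_shape must be positive")
  structure(list(grid_shape = as.integer(grid_shape), cell_size = cell_size,
                 n_countries = as.integer(n_countries),
                 n_bcus = as.integer(n_bcus),
                 n_stressors = n_stressors[cats], n_habitats = n_habitats,
                 trend = trend[cats], intensity_shape = intensity_shape[cats],
                 trend_noise_sd = trend_noise_sd,
                 smooth_sigma = smooth_sigma,
                 metric_missing_rate = metric_missing_rate,
                 metric_noise_sd = metric_noise_sd,
                 seed = as.integer(seed)),
            class = "world_config")
}

# ---- random fields ---------------------------------------------------------

gauss_kernel <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k / sum(k)
}

conv1_reflect <- function(v, k) {
  h <- (length(k) - 1L) / 2L
  n <- length(v)
  vp <- c(v[h:1], v, v[n:(n - h + 1)])
  out <- stats::filter(vp, k, sides = 2)
  as.numeric(out[(h + 1):(h + n)])
}

#' Seeded smooth random field in [0, 1]
#'
#' White noise blurred with a separable Gaussian kernel (reflection padding)
#' and min-max rescaled, giving simple spatial autocorrelation.
#'
#' @param nr,nc grid dimensions.
#' @param sigma smoothing bandwidth in cells.
#' @return a numeric matrix in [0, 1]. Uses the current RNG stream.
#' @export
smooth_field <- function(nr, nc, sigma = 2) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  k <- gauss_kernel(sigma)
  z <- apply(z, 2, conv1_reflect, k = k)
  z <- t(apply(z, 1, conv1_reflect, k = k))
  rng <- range(z)
  if (diff(rng) == 0) return(matrix(0.5, nr, nc))
  (z - rng[1]) / diff(rng)
}

# world vertical layout, in whole rows: land strip on top, EEZ band,
# high seas at the bottom; the EEZ/high-seas boundary is the 200-nm limit
world_layout <- function(config) {
  nr <- config$grid_shape[1]
  land_rows <- max(2L, round(0.15 * nr))
  hs_rows <- max(2L, round(0.10 * nr))
  eez_rows <- nr - land_rows - hs_rows
  if (eez_rows < 6) stop("grid too small for land/EEZ/high-seas layout")
  list(land_rows = land_rows, hs_rows = hs_rows, eez_rows = eez_rows)
}

country_codes <- function(n) sprintf("C%02d", seq_len(n))

# ---- geometry --------------------------------------------------------------

#' Generate the synthetic world's polygon layers
#'
#' Lays out \code{n_countries} vertical strips. Each country owns a land
#' polygon (northern strip) and an EEZ polygon reaching from the shore to the
#' 200-nm limit; EEZs tile the EEZ band without overlap. BCU rectangles are
#' placed in EEZ waters on a slot grid so that each spans the waters of 1-3
#' adjacent countries (membership frequencies mirror the real Table of BCU
#' membership: roughly 76/16/8 percent for 1/2/3 countries). Some BCUs in the
#' southernmost band extend past the 200-nm limit into high seas, so the
#' 200-nm clipping step downstream has real work to do.
#'
#' @param config a \code{world_config}.
#' @return list with \code{eez}, \code{land}, \code{bcus} (lists of
#'   \code{rp_zone}), a \code{membership} data frame (country, bcuid),
#'   \code{limit_y} (y of the 200-nm limit), the layout, and grid metadata.
#' @export
generate_geometry <- function(config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  cs <- config$cell_size
  lay <- world_layout(config)
  H <- nr * cs
  shore_y <- H - lay$land_rows * cs
  limit_y <- lay$hs_rows * cs

  # vertical country strips, in whole columns
  cuts <- round(seq(0, nc, length.out = config$n_countries + 1))
  if (any(diff(cuts) < 2)) stop("grid too narrow for n_countries strips")
  codes <- country_codes(config$n_countries)
  xs <- cuts * cs

  land <- lapply(seq_len(config$n_countries), function(i) {
    rp_zone(paste0("land_", codes[i]), "land",
            rect_ring(xs[i], xs[i + 1], shore_y, H), country = codes[i])
  })
  eez <- lapply(seq_len(config$n_countries), function(i) {
    rp_zone(paste0("eez_", codes[i]), "eez",
            rect_ring(xs[i], xs[i + 1], limit_y, shore_y), country = codes[i])
  })

  # BCU slot grid inside the EEZ band
  bcu_h <- max(3L, lay$eez_rows %/% 5L)
  n_bands <- lay$eez_rows %/% bcu_h
  if (config$n_bcus > n_bands * config$n_countries)
    stop("cannot place ", config$n_bcus, " BCUs: only ",
         n_bands * config$n_countries, " slots available under the ",
         "1-3 adjacent-country placement rule")
  occupied <- matrix(FALSE, n_bands, config$n_countries)
  strip_cols <- diff(cuts)

  bcus <- vector("list", config$n_bcus)
  membership <- list()
  p_k <- c(0.76, 0.16, 0.08)[seq_len(min(3L, config$n_countries))]
  for (b in seq_len(config$n_bcus)) {
    placed <- FALSE
    k <- sample.int(length(p_k), 1, prob = p_k)
    for (kk in seq(k, 1)) {  # fall back to narrower spans if needed
      free <- list()
      for (bd in seq_len(n_bands))
        for (c0 in seq_len(config$n_countries - kk + 1))
          if (!any(occupied[bd, c0:(c0 + kk - 1)]))
            free[[length(free) + 1L]] <- c(c0, bd)
      if (!length(free)) next
      pick <- free[[sample.int(length(free), 1)]]
      c0 <- pick[1]; bd <- pick[2]
      occupied[bd, c0:(c0 + kk - 1)] <- TRUE
      # cell-aligned rectangle: inset inside anchor and end strips so the
      # BCU overlaps each member country's EEZ by at least one column
      in_l <- sample.int(max(1L, floor(0.3 * strip_cols[c0])), 1) - 1L
      in_r <- sample.int(max(1L, floor(0.3 * strip_cols[c0 + kk - 1])), 1) - 1L
      x1 <- (cuts[c0] + in_l) * cs
      x2 <- (cuts[c0 + kk] - in_r) * cs
      band_top_row <- lay$land_rows + (bd - 1L) * bcu_h   # rows from grid top
      it <- sample.int(2L, 1) - 1L                         # 0-1 cell insets
      ib <- sample.int(2L, 1) - 1L
      y2 <- H - (band_top_row + it) * cs
      y1 <- H - (band_top_row + bcu_h - ib) * cs
      if (bd == n_bands && stats::runif(1) < 0.4) {
        # southernmost band: push past the 200-nm limit into high seas
        y1 <- limit_y - sample.int(max(1L, lay$hs_rows %/% 2L), 1) * cs
      }
      bcus[[b]] <- rp_zone(paste0("bcu_", b), "bcu",
                           rect_ring(x1, x2, y1, y2), bcuid = b)
      membership[[b]] <- data.frame(country = codes[c0:(c0 + kk - 1)],
                                    bcuid = b, stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("cannot place BCU ", b, ": no free slot run of 1-3 adjacent ",
           "countries remains (reduce n_bcus or enlarge the grid)")
  }

  list(eez = eez, land = land, bcus = bcus,
       membership = do.call(rbind, membership),
       limit_y = limit_y, shore_y = shore_y, layout = lay,
       grid = list(nrow = nr, ncol = nc, cellsize = cs, xll = 0, yll = 0),
       strips = xs, countries = codes)
}

# ---- stressor and habitat rasters ------------------------------------------

#' Default stressor registry
#'
#' Names and categorizes the 19 standard anthropogenic pressures (4 climate,
#' 5 land, 10 marine) and flags the seven that are excluded from the
#' two-period change analysis: four lacking data in both periods (sea-level
#' rise, shipping, invasive species, ocean pollution) and three that do not
#' differ between periods (ocean acidification, artisanal fishing, inorganic
#' pollution). When a category's requested count differs from the default
#' list, generic change-eligible names are appended or the list truncated.
#'
#' @param n_stressors named counts per category (defaults to the full 19).
#' @return data frame with columns \code{name}, \code{category},
#'   \code{change_eligible}.
#' @export
default_stressor_registry <- function(n_stressors = c(climate = 4, land = 5,
                                                      marine = 10)) {
  base <- list(
    climate = c("sst_anomaly", "uv_anomaly", "ocean_acidification",
                "sea_level_rise"),
    land = c("nutrient_pollution", "organic_chemical_pollution",
             "inorganic_pollution", "direct_human_impact",
             "coastal_engineering"),
    marine = c("demersal_destructive_fishing",
               "demersal_nondest_high_bycatch",
               "demersal_nondest_low_bycatch",
               "pelagic_high_bycatch", "pelagic_low_bycatch",
               "artisanal_fishing", "shipping", "invasive_species",
               "ocean_pollution", "night_lights"))
  ineligible <- c("sea_level_rise", "shipping", "invasive_species",
                  "ocean_pollution", "ocean_acidification",
                  "artisanal_fishing", "inorganic_pollution")
  rows <- lapply(names(base), function(cat) {
    n <- n_stressors[[cat]]
    nm <- base[[cat]]
    if (n <= length(nm)) nm <- nm[seq_len(n)]
    else nm <- c(nm, sprintf("%s_extra_%d", cat, seq_len(n - length(nm))))
    data.frame(name = nm, category = cat,
               change_eligible = !(nm %in% ineligible),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

clip01 <- function(m) pmin(pmax(m, 0), 1)

#' Generate stressor intensity rasters for both periods
#'
#' Each stressor is a smooth seeded random field in [0, 1]. Land-category
#' stressors decay exponentially with distance from the land strip. The
#' second period equals the first plus the category's mean trend plus a
#' centered smooth noise field, clipped back to [0, 1].
#'
#' @param config a \code{world_config}.
#' @param geometry output of \code{\link{generate_geometry}}.
#' @return list of stressor layers; each layer is a list with \code{name},
#'   \code{category}, \code{period} ("2008" or "2013"), \code{raster}
#'   (\code{rp_raster}), and \code{change_eligible}.
#' @export
generate_stressors <- function(config, geometry) {
  set.seed(config$seed + 1L)
  g <- geometry$grid
  reg <- default_stressor_registry(config$n_stressors)
  lay <- geometry$layout
  row_idx <- matrix(seq_len(g$nrow), g$nrow, g$ncol)
  dist_from_land <- pmax(0, row_idx - lay$land_rows)   # rows; land strip on top
  land_decay <- exp(-dist_from_land / (lay$eez_rows / 3))

  layers <- list()
  for (i in seq_len(nrow(reg))) {
    f08 <- smooth_field(g$nrow, g$ncol,
                        config$smooth_sigma)^config$intensity_shape[[reg$category[i]]]
    if (reg$category[i] == "land") f08 <- f08 * land_decay
    noise <- smooth_field(g$nrow, g$ncol, config$smooth_sigma)
    noise <- noise - mean(noise)
    s <- stats::sd(noise)
    if (s > 0) noise <- noise * (config$trend_noise_sd / s)
    f13 <- clip01(f08 + config$trend[[reg$category[i]]] + noise)
    mk <- function(v, per) list(name = reg$name[i], category = reg$category[i],
                                period = per,
                                raster = rp_raster(v, g$xll, g$yll, g$cellsize),
                                change_eligible = reg$change_eligible[i])
    layers[[length(layers) + 1L]] <- mk(f08, "2008")
    layers[[length(layers) + 1L]] <- mk(f13, "2013")
  }
  layers
}

#' Generate habitat presence rasters
#'
#' The first habitat is a reef habitat concentrated inside BCU footprints;
#' the rest are thresholded smooth random fields. Habitats occur only on
#' marine cells (everything seaward of the shore).
#'
#' @param config a \code{world_config}.
#' @param geometry output of \code{\link{generate_geometry}}.
#' @return list of habitat layers (\code{name}, \code{presence} raster with
#'   values in {0, 1}).
#' @export
generate_habitats <- function(config, geometry) {
  set.seed(config$seed + 2L)
  g <- geometry$grid
  lay <- geometry$layout
  marine <- matrix(seq_len(g$nrow), g$nrow, g$ncol) > lay$land_rows
  template <- rp_raster(matrix(0, g$nrow, g$ncol), g$xll, g$yll, g$cellsize)
  cc <- cell_centers(template)

  in_bcu <- matrix(FALSE, g$nrow, g$ncol)
  for (z in geometry$bcus) {
    bb <- apply(z$ring, 2, range)
    cand <- which(cc$x >= bb[1, 1] & cc$x <= bb[2, 1] &
                    cc$y >= bb[1, 2] & cc$y <= bb[2, 2])
    if (length(cand))
      in_bcu[cand] <- in_bcu[cand] |
        points_in_polygon(cc$x[cand], cc$y[cand], z$ring)
  }

  habs <- vector("list", config$n_habitats)
  for (h in seq_len(config$n_habitats)) {
    f <- smooth_field(g$nrow, g$ncol, config$smooth_sigma)
    if (h == 1) {
      pres <- (in_bcu | f > stats::quantile(f, 0.9)) & marine
      nm <- "coral_reef"
    } else {
      pres <- f > stats::quantile(f, 0.6) & marine
      nm <- sprintf("habitat_%02d", h)
    }
    habs[[h]] <- list(name = nm,
                      presence = rp_raster(pres * 1, g$xll, g$yll, g$cellsize))
  }
  habs
}

#' Generate a habitat-by-stressor vulnerability matrix
#'
#' Nonnegative weights, uniform on [0.2, 1] so every habitat has some
#' sensitivity to every stressor.
#'
#' @param config a \code{world_config}.
#' @param habitats,stressor_names habitat layer list and stressor names.
#' @return numeric matrix, rows = habitats, columns = stressors.
#' @export
generate_vulnerability <- function(config, habitats, stressor_names) {
  set.seed(config$seed + 3L)
  nh <- length(habitats)
  mu <- matrix(stats::runif(nh * length(stressor_names), 0.2, 1),
               nh, length(stressor_names))
  rownames(mu) <- vapply(habitats, `[[`, "", "name")
  colnames(mu) <- stressor_names
  mu
}

#' Default management-metric registry
#'
#' Metric names echo the composition of the real indices: the climate index
#' draws on ecosystem-based adaptation counts, coastal mentions in national
#' contributions, and emissions-change metrics (which are better when lower);
#' the marine index on reef MPA coverage, fisheries management, reef-initiative
#' membership, and conservation funding; the land index on integrated coastal
#' management policies and terrestrial protected areas.
#'
#' @return data frame with columns \code{metric}, \code{category},
#'   \code{direction} ("higher_better"/"lower_better"), and \code{scale}
#'   (heterogeneous raw-value scale).
#' @export
default_metric_registry <- function() {
  data.frame(
    metric = c("eba_strategies", "ndc_coastal_mention", "co2_change_per_gdp",
               "co2_change_per_capita",
               "mpa_strict_reef_pct", "fisheries_mgmt_effectiveness",
               "icri_member", "reef_conservation_funding",
               "icm_policies_avg", "terrestrial_pa_pct"),
    category = c(rep("climate", 4), rep("marine", 4), rep("land", 2)),
    direction = c("higher_better", "higher_better", "lower_better",
                  "lower_better", "higher_better", "higher_better",
                  "higher_better", "higher_better", "higher_better",
                  "higher_better"),
    scale = c(20, 3, 0.5, 0.5, 40, 10, 1, 5e6, 6, 30),
    stringsAsFactors = FALSE)
}

#' Generate a country-by-metric management table with latent truth
#'
#' Each country holds one latent management commitment per category in
#' [0, 1]. A metric's raw value is an affine map of that commitment on the
#' metric's own scale (negated for lower-is-better metrics) plus noise, and a
#' fraction of cells is blanked to missing. The latent commitments are
#' returned so recovery tests can compare recomputed indices against ground
#' truth.
#'
#' @param config a \code{world_config}.
#' @param countries character vector of country codes.
#' @return list with \code{table} (long data frame: country, region,
#'   category, metric, raw_value, direction), \code{latent} (country,
#'   category, commitment), and \code{registry}.
#' @export
generate_metrics <- function(config, countries) {
  if (config$metric_missing_rate >= 1) stop("metric_missing_rate must be < 1")
  set.seed(config$seed + 4L)
  n <- length(countries)
  n_regions <- max(1L, ceiling(n / 3))
  region <- sample(rep(paste0("Region_", LETTERS[seq_len(n_regions)]),
                       length.out = n))
  reg <- default_metric_registry()
  latent <- expand.grid(country = countries,
                        category = c("climate", "land", "marine"),
                        stringsAsFactors = FALSE)
  latent$commitment <- stats::runif(nrow(latent))

  rows <- lapply(seq_len(nrow(reg)), function(i) {
    lat <- latent$commitment[latent$category == reg$category[i]][
      match(countries, latent$country[latent$category == reg$category[i]])]
    sgn <- if (reg$direction[i] == "lower_better") -1 else 1
    raw <- reg$scale[i] * (0.1 + sgn * lat) +
      stats::rnorm(n, sd = config$metric_noise_sd * reg$scale[i])
    miss <- stats::runif(n) < config$metric_missing_rate
    if (all(miss)) miss[sample.int(n, 1)] <- FALSE  # keep every metric usable
    raw[miss] <- NA_real_
    data.frame(country = countries, region = region,
               category = reg$category[i], metric = reg$metric[i],
               raw_value = raw, direction = reg$direction[i],
               stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), latent = latent, registry = reg)
}

# ---- orchestration ---------------------------------------------------------

#' Generate a complete synthetic world
#'
#' Runs geometry, stressor, habitat, vulnerability, and metric generation
#' under one seed, optionally serializing everything (ASCII-grid rasters,
#' GeoJSON polygons, CSV tables) under \code{out_dir}.
#'
#' @param config a \code{world_config}.
#' @param out_dir optional output directory; created if missing.
#' @return list with \code{geometry}, \code{stressors}, \code{habitats},
#'   \code{vulnerability}, \code{metrics}, and \code{config}.
#' @export
generate_world <- function(config, out_dir = NULL) {
  geometry <- generate_geometry(config)
  stressors <- generate_stressors(config, geometry)
  habitats <- generate_habitats(config, geometry)
  snames <- unique(vapply(stressors, `[[`, "", "name"))
  vuln <- generate_vulnerability(config, habitats, snames)
  metrics <- generate_metrics(config, geometry$countries)
  world <- list(geometry = geometry, stressors = stressors,
                habitats = habitats, vulnerability = vuln,
                metrics = metrics, config = config)
  if (!is.null(out_dir)) write_world(world, out_dir)
  world
}

#' Serialize a synthetic world to disk
#'
#' @param world output of \code{\link{generate_world}}.
#' @param out_dir output directory.
#' @return \code{out_dir}, invisibly.
#' @export
write_world <- function(world, out_dir) {
  dir.create(file.path(out_dir, "rasters"), recursive = TRUE,
             showWarnings = FALSE)
  g <- world$geometry
  write_zones_geojson(g$eez, file.path(out_dir, "eez.geojson"))
  write_zones_geojson(g$land, file.path(out_dir, "land.geojson"))
  write_zones_geojson(g$bcus, file.path(out_dir, "bcus.geojson"))
  utils::write.csv(g$membership, file.path(out_dir, "membership.csv"),
                   row.names = FALSE)
  for (s in world$stressors)
    write_ascii_grid(s$raster, file.path(out_dir, "rasters",
                                         sprintf("%s_%s.asc", s$name, s$period)))
  for (h in world$habitats)
    write_ascii_grid(h$presence, file.path(out_dir, "rasters",
                                           sprintf("habitat_%s.asc", h$name)))
  utils::write.csv(as.data.frame(world$vulnerability),
                   file.path(out_dir, "vulnerability.csv"))
  utils::write.csv(world$metrics$table, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(world$metrics$latent, file.path(out_dir, "latent_truth.csv"),
                   row.names = FALSE)
  reg <- unique(data.frame(
    name = vapply(world$stressors, `[[`, "", "name"),
    category = vapply(world$stressors, `[[`, "", "category"),
    change_eligible = vapply(world$stressors, `[[`, TRUE, "change_eligible"),
    stringsAsFactors = FALSE))
  utils::write.csv(reg, file.path(out_dir, "stressor_registry.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
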