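TABLE1_MD5 <- "e1af65f0a42895ef67cec7eb4332ad7f"

#' Load the packaged BCU-country membership table
#'
#' The packaged transcription of the published membership table: one row per
#' (country, BCU) pair, 66 rows over 50 BCUs and 28 countries. A checksum
#' guards against accidental edits of the fixture.
#'
#' @return data frame with columns \code{country}, \code{iso3}, \code{bcuid}.
#' @export
load_membership_fixture <- function() {
  path <- system.file("extdata", "table1_membership.csv",
                      package = "reefpressure")
  if (path == "") stop("membership fixture not found in installed package")
  if (unname(tools::md5sum(path)) != TABLE1_MD5)
    stop("membership fixture checksum mismatch: file corrupted")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$bcuid <- as.integer(tab$bcuid)
  tab
}

#' Read a serialized world back from disk
#'
#' Inverse of \code{\link{write_world}}: reads the GeoJSON polygon layers,
#' ASCII-grid rasters, registries, and tables of a world directory.
#'
#' @param dir directory written by \code{\link{write_world}}.
#' @return a world list with the same shape as \code{\link{generate_world}}
#'   output (without \code{config}; \code{metrics$latent} present only if the
#'   truth table was serialized).
#' @export
load_world <- function(dir) {
  eez <- read_zones_geojson(file.path(dir, "eez.geojson"))
  land <- read_zones_geojson(file.path(dir, "land.geojson"))
  bcus <- read_zones_geojson(file.path(dir, "bcus.geojson"))
  membership <- utils::read.csv(file.path(dir, "membership.csv"),
                                stringsAsFactors = FALSE)
  reg <- utils::read.csv(file.path(dir, "stressor_registry.csv"),
                         stringsAsFactors = FALSE)
  stressors <- list()
  for (i in seq_len(nrow(reg))) {
    for (per in c("2008", "2013")) {
      f <- file.path(dir, "rasters", sprintf("%s_%s.asc", reg$name[i], per))
      if (!file.exists(f)) stop("load_world: missing raster ", f)
      stressors[[length(stressors) + 1L]] <-
        list(name = reg$name[i], category = reg$category[i], period = per,
             raster = read_ascii_grid(f),
             change_eligible = reg$change_eligible[i])
    }
  }
  hfiles <- list.files(file.path(dir, "rasters"), pattern = "^habitat_",
                       full.names = TRUE)
  habitats <- lapply(hfiles, function(f) {
    list(name = sub("^habitat_(.*)\\.asc$", "\\1", basename(f)),
         presence = read_ascii_grid(f))
  })
  vdf <- utils::read.csv(file.path(dir, "vulnerability.csv"), row.names = 1,
                         check.names = FALSE)
  vuln <- as.matrix(vdf)
  metrics <- list(table = utils::read.csv(file.path(dir, "metrics.csv"),
                                          stringsAsFactors = FALSE))
  lt <- file.path(dir, "latent_truth.csv")
  if (file.exists(lt))
    metrics$latent <- utils::read.csv(lt, stringsAsFactors = FALSE)
  list(geometry = list(eez = eez, land = land, bcus = bcus,
                       membership = membership,
                       countries = sort(unique(vapply(eez, `[[`, "", "country")))),
       stressors = stressors, habitats = habitats, vulnerability = vuln,
       metrics = metrics)
}

default_run_options <- function() {
  list(habitat_agg = "mean", clip_quantile = 0.9999,
       country_method = "mean_of_portions",
       outlier_rule = list(rule = "iqr", k = 1.5, named = NULL))
}

validate_run_config <- function(config) {
  problems <- character(0)
  if (is.null(config$simulate) && is.null(config$input_dir))
    problems <- c(problems, "one of `simulate` or `input_dir` is required")
  if (!is.null(config$simulate) && !is.null(config$input_dir))
    problems <- c(problems, "`simulate` and `input_dir` are exclusive")
  opts <- config$options
  if (!is.null(opts$habitat_agg) && !opts$habitat_agg %in% c("mean", "sum"))
    problems <- c(problems, "options.habitat_agg must be 'mean' or 'sum'")
  if (!is.null(opts$country_method) &&
      !opts$country_method %in% c("mean_of_portions", "pooled"))
    problems <- c(problems,
                  "options.country_method must be 'mean_of_portions' or 'pooled'")
  if (!is.null(opts$clip_quantile) &&
      (opts$clip_quantile <= 0 || opts$clip_quantile > 1))
    problems <- c(problems, "options.clip_quantile must be in (0, 1]")
  if (length(problems))
    stop("invalid run config:\n  - ", paste(problems, collapse = "\n  - "))
  invisible(TRUE)
}

check_registry_cover <- function(world, config) {
  snames <- unique(vapply(world$stressors, `[[`, "", "name"))
  reg <- config$stressor_registry
  if (!is.null(reg)) {
    missing <- setdiff(snames, reg$name)
    if (length(missing))
      stop("stressor(s) absent from the category registry: ",
           paste(missing, collapse = ", "))
    idx <- match(vapply(world$stressors, `[[`, "", "name"), reg$name)
    for (i in seq_along(world$stressors)) {
      world$stressors[[i]]$category <- reg$category[idx[i]]
      world$stressors[[i]]$change_eligible <- reg$change_eligible[idx[i]]
    }
  }
  mtab <- world$metrics$table
  mreg <- config$metric_registry
  if (!is.null(mreg)) {
    missing <- setdiff(unique(mtab$metric), mreg$metric)
    if (length(missing))
      stop("metric(s) absent from the metric registry: ",
           paste(missing, collapse = ", "))
  }
  world
}

#' Run the full pipeline: simulate, impact, zones, index, association
#'
#' Orchestrates every stage as one configured, reproducible run. The config
#' is a list (or a path to a YAML file) with a \code{simulate} block (world
#' parameters) or an \code{input_dir} pointing at a serialized world, an
#' optional \code{stressor_registry} / \code{metric_registry} override, an
#' \code{options} block (\code{habitat_agg}, \code{clip_quantile},
#' \code{country_method}, \code{outlier_rule}), an output directory
#' \code{out}, and a \code{seed}.
#'
#' Stages: (1) obtain the world; (2) snapshot impact for 2013 with
#' within-period rescaling; (3) change in impact 2008-2013 with joint
#' two-period rescaling and the change-eligibility exclusions; (4) clip BCUs
#' to EEZs and summarize by BCU and country; (5) build the management
#' indices; (6) regressions of mean impact (and mean change) on the index
#' per category, with outlier sensitivity refits, plus median-split quadrant
#' classifications. All tables are written as CSV under \code{out} together
#' with a JSON run manifest; rerunning an identical config reproduces
#' byte-identical CSVs.
#'
#' @param config list or YAML file path.
#' @return the run manifest (list), invisibly; stage outputs are also
#'   returned in the \code{results} element.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_run_config(config)
  opts <- utils::modifyList(default_run_options(), config$options %||% list())
  out_dir <- config$out %||% stop("run config needs an `out` directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  # -- stage 1: world --------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    if (!is.null(config$seed)) sim$seed <- config$seed
    if (!is.null(sim$grid_shape)) sim$grid_shape <- unlist(sim$grid_shape)
    for (nm in c("n_stressors", "trend"))
      if (!is.null(sim[[nm]])) sim[[nm]] <- unlist(sim[[nm]])
    wc <- do.call(world_config, sim)
    world <- generate_world(wc)
    note("simulated world: ", wc$grid_shape[1], "x", wc$grid_shape[2],
         " grid, ", wc$n_countries, " countries, ", wc$n_bcus, " BCUs, seed ",
         wc$seed)
  } else {
    world <- load_world(config$input_dir)
    note("loaded world from ", config$input_dir)
  }
  world <- check_registry_cover(world, config)

  per <- vapply(world$stressors, `[[`, "", "period")
  s08 <- world$stressors[per == "2008"]
  s13 <- world$stressors[per == "2013"]
  eligibility <- vapply(s13, `[[`, TRUE, "change_eligible")
  names(eligibility) <- vapply(s13, `[[`, "", "name")

  # -- stage 2: snapshot impact (within-period rescale) ----------------------
  snap13 <- lapply(s13, function(s) {
    s$raster <- rescale_stressor(s$raster, opts$clip_quantile); s
  })
  stack13 <- compute_impact(snap13, world$habitats, world$vulnerability,
                            habitat_agg = opts$habitat_agg)

  # -- stage 3: change in impact (joint two-period rescale) ------------------
  joint08 <- s08; joint13 <- s13
  for (i in seq_along(s08)) {
    stopifnot(s08[[i]]$name == s13[[i]]$name)
    rs <- rescale_periods(s08[[i]]$raster, s13[[i]]$raster, opts$clip_quantile)
    joint08[[i]]$raster <- rs$`2008`
    joint13[[i]]$raster <- rs$`2013`
  }
  jstack08 <- compute_impact(joint08, world$habitats, world$vulnerability,
                             habitat_agg = opts$habitat_agg)
  jstack13 <- compute_impact(joint13, world$habitats, world$vulnerability,
                             habitat_agg = opts$habitat_agg)
  delta <- change_in_impact(jstack08, jstack13, eligibility)
  note("change analysis: ", sum(!eligibility), " of ", length(eligibility),
       " stressors excluded (", paste(names(eligibility)[!eligibility],
                                      collapse = ", "), ")")

  # -- stage 4: zones --------------------------------------------------------
  portions <- clip_bcus(world$geometry$bcus, world$geometry$eez)
  note(length(portions), " BCU-country portions from ",
       length(world$geometry$bcus), " BCUs")
  bcu_summary <- summarize_bcu(portions, stack13, delta)
  country_summary <- summarize_country(portions, stack13, delta,
                                       method = opts$country_method)

  # -- stage 5: management index ---------------------------------------------
  idx <- build_management_index(world$metrics$table)
  note(sum(idx$components$imputed), " component scores imputed regionally")

  # -- stage 6: association & quadrants --------------------------------------
  assoc <- list(); quad_rows <- list()
  for (cat in c("climate", "land", "marine")) {
    xi <- idx$index[idx$index$category == cat, ]
    m <- match(country_summary$country, xi$country)
    x <- xi$score[m]
    for (kind in c("impact", "delta")) {
      y <- if (kind == "impact") country_summary[[paste0("mean_", cat)]]
      else country_summary[[paste0("delta_", cat)]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 5) { note("skipping ", cat, "/", kind, ": n < 5"); next }
      fit <- fit_index_regression(x[ok], y[ok])
      sens <- sensitivity_refit(x[ok], y[ok], country_summary$country[ok],
                                rule = opts$outlier_rule$rule %||% "iqr",
                                k = opts$outlier_rule$k %||% 1.5,
                                named = opts$outlier_rule$named)
      assoc[[length(assoc) + 1L]] <- data.frame(
        category = cat, response = kind, n = fit$n,
        slope = fit$slope, intercept = fit$intercept,
        r_squared = fit$r_squared, r_squared_adj = fit$r_squared_adj,
        p_value = fit$p_value,
        outliers = paste(sens$outliers, collapse = ";"),
        slope_no_outliers = sens$fit$slope,
        r_squared_adj_no_outliers = sens$fit$r_squared_adj,
        p_value_no_outliers = sens$fit$p_value,
        stringsAsFactors = FALSE)
      q <- classify_quadrants(country_summary$country[ok], x[ok], y[ok],
                              x_name = paste0(cat, "_index"),
                              y_name = paste0(cat, "_", kind))
      quad_rows[[length(quad_rows) + 1L]] <- q$labels
    }
  }
  # land-vs-marine quadrants for BCUs and countries
  qb <- classify_quadrants(bcu_summary$bcuid, bcu_summary$mean_land,
                           bcu_summary$mean_marine, "land_impact",
                           "marine_impact")
  qc <- classify_quadrants(country_summary$country, country_summary$mean_land,
                           country_summary$mean_marine, "land_impact",
                           "marine_impact")
  quad_rows <- c(quad_rows, list(qb$labels, qc$labels))
  association <- do.call(rbind, assoc)
  quadrants <- do.call(rbind, quad_rows)

  # -- outputs ---------------------------------------------------------------
  wcsv <- function(df, name) utils::write.csv(
    df, file.path(out_dir, name), row.names = FALSE)
  wcsv(bcu_summary, "bcu_summary.csv")
  wcsv(country_summary, "country_summary.csv")
  wcsv(idx$index, "management_index.csv")
  wcsv(idx$components, "index_components.csv")
  wcsv(idx$collinearity, "collinearity.csv")
  wcsv(association, "association.csv")
  wcsv(quadrants, "quadrants.csv")
  wcsv(world$geometry$membership, "membership.csv")

  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("reefpressure")),
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = config$seed %||% config$simulate$seed %||% NA,
    n_bcus = nrow(bcu_summary), n_countries = nrow(country_summary),
    n_portions = length(portions),
    n_stressors = length(eligibility),
    n_cells = length(stack13$total$values),
    log = log)
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$results <- list(world = world, stack13 = stack13, delta = delta,
                           portions = portions, bcu_summary = bcu_summary,
                           country_summary = country_summary, index = idx,
                           association = association, quadrants = quadrants)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
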