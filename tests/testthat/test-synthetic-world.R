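test_that("config validation enforces the documented bounds", {
  expect_error(world_config(n_countries = 1), "n_countries")
  expect_error(world_config(n_bcus = 0), "n_bcus")
  expect_error(world_config(metric_missing_rate = 1), "missing_rate")
  expect_error(world_config(grid_shape = c(4, 64)), "grid_shape")
  expect_error(world_config(intensity_shape = c(climate = -1, land = 1,
                                                marine = 1)), "positive")
})

test_that("geometry satisfies the 1-3 country membership rule and validity", {
  g <- generate_geometry(world_config(n_countries = 3, n_bcus = 4, seed = 7))
  expect_length(g$bcus, 4)
  spans <- table(g$membership$bcuid)
  expect_true(all(spans >= 1 & spans <= 3))
  for (z in c(g$bcus, g$eez, g$land)) {
    expect_s3_class(z, "rp_zone")
    expect_gt(polygon_area(z$ring), 0)
  }
})

test_that("a single BCU wholly inside one EEZ yields a one-row membership table", {
  g <- generate_geometry(world_config(n_bcus = 1, seed = 1))
  expect_equal(nrow(g$membership), 1)
  portions <- clip_bcus(g$bcus, g$eez)
  expect_length(portions, 1)
  expect_equal(portions[[1]]$country, g$membership$country[1])
})

test_that("overfull placement fails with an error naming the constraint", {
  expect_error(generate_geometry(world_config(n_bcus = 500)),
               "1-3 adjacent-country")
})

test_that("EEZs tile the EEZ band: every cell there belongs to exactly one EEZ", {
  g <- generate_geometry(small_world_config(seed = 3))
  template <- rp_raster(matrix(0, 32, 32), cellsize = 10)
  cover <- matrix(0L, 32, 32)
  for (e in g$eez) {
    idx <- zone_cells(template, e)
    cover[idx] <- cover[idx] + 1L
  }
  cc <- cell_centers(template)
  in_band <- cc$y > g$limit_y & cc$y < g$shore_y
  expect_true(all(cover[in_band] == 1L))
  expect_true(all(cover[!in_band] == 0L))
})

test_that("identical configs serialize byte-identical worlds", {
  cfg <- small_world_config(seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_world(cfg, out_dir = d1)
  generate_world(cfg, out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  expect_gt(length(f1), 40)  # rasters + polygons + tables
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("stressor fields respect [0,1] bounds, trends, and land decay", {
  cfg <- small_world_config(seed = 5)
  geom <- generate_geometry(cfg)
  layers <- generate_stressors(cfg, geom)
  for (l in layers) {
    expect_true(all(l$raster$values >= 0 & l$raster$values <= 1),
                label = paste(l$name, l$period))
  }
  per <- vapply(layers, `[[`, "", "period")
  cat_of <- vapply(layers, `[[`, "", "category")
  marine_rows <- seq(geom$layout$land_rows + 1, 32)
  mean_over_sea <- function(ls) mean(vapply(ls, function(l)
    mean(l$raster$values[marine_rows, ]), numeric(1)))
  m08 <- function(cat) mean_over_sea(layers[per == "2008" & cat_of == cat])
  m13 <- function(cat) mean_over_sea(layers[per == "2013" & cat_of == cat])
  expect_gt(m13("climate"), m08("climate"))   # rising climate trend
  expect_lt(m13("marine"), m08("marine"))     # falling marine trend
  # land stressors decay away from shore: nearshore EEZ rows beat offshore
  land08 <- layers[per == "2008" & cat_of == "land"]
  near <- geom$layout$land_rows + seq_len(3)
  far <- 32 - seq_len(3) + 1
  expect_gt(mean(vapply(land08, function(l) mean(l$raster$values[near, ]),
                        numeric(1))),
            mean(vapply(land08, function(l) mean(l$raster$values[far, ]),
                        numeric(1))))
  # the documented exclusion set is flagged change-ineligible
  inel <- unique(vapply(layers, `[[`, "", "name")[
    !vapply(layers, `[[`, TRUE, "change_eligible")])
  expect_setequal(inel, c("sea_level_rise", "ocean_acidification",
                          "shipping", "invasive_species", "ocean_pollution",
                          "artisanal_fishing", "inorganic_pollution"))
})

test_that("zero trend and zero noise reproduce period one exactly", {
  cfg <- small_world_config(seed = 9,
                            trend = c(climate = 0, land = 0, marine = 0),
                            trend_noise_sd = 0)
  geom <- generate_geometry(cfg)
  layers <- generate_stressors(cfg, geom)
  per <- vapply(layers, `[[`, "", "period")
  l08 <- layers[per == "2008"]; l13 <- layers[per == "2013"]
  for (i in seq_along(l08))
    expect_equal(l13[[i]]$raster$values, l08[[i]]$raster$values)
})

test_that("metric tables honor the missing rate and regenerate identically", {
  cfg0 <- small_world_config(seed = 2, metric_missing_rate = 0)
  m0 <- generate_metrics(cfg0, country_codes_for_test(4))
  expect_false(anyNA(m0$table$raw_value))
  cfg <- small_world_config(seed = 2, metric_missing_rate = 0.3)
  m1 <- generate_metrics(cfg, country_codes_for_test(4))
  m2 <- generate_metrics(cfg, country_codes_for_test(4))
  expect_identical(m1$table, m2$table)
  expect_gt(sum(is.na(m1$table$raw_value)), 0)
})

test_that("noiseless metrics let the index recover latent commitment ranks", {
  cfg <- small_world_config(seed = 4, metric_missing_rate = 0,
                            metric_noise_sd = 0, n_countries = 6)
  m <- generate_metrics(cfg, country_codes_for_test(6))
  idx <- build_management_index(m$table)
  for (cat in c("climate", "marine", "land")) {
    sc <- idx$index[idx$index$category == cat, ]
    lat <- m$latent[m$latent$category == cat, ]
    lat <- lat[match(sc$country, lat$country), ]
    expect_equal(order(sc$score), order(lat$commitment),
                 label = paste("rank order,", cat))
  }
})

test_that("injected category trends are recovered downstream over many seeds", {
  signs <- vapply(1:10, function(s) {
    res <- run_small_change_analysis(seed = s)
    c(climate = res$climate, marine = res$marine)
  }, numeric(2))
  expect_gte(mean(signs["climate", ] > 0), 0.9)
  expect_gte(mean(signs["marine", ] < 0), 0.9)
})
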