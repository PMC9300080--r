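test_that("a BCU inside one EEZ clips to a single portion of equal area", {
  eez <- list(rp_zone("eez_A", "eez", rect_ring(0, 50, 0, 50), country = "A"),
              rp_zone("eez_B", "eez", rect_ring(50, 100, 0, 50), country = "B"))
  bcu <- list(rp_zone("bcu_1", "bcu", rect_ring(10, 40, 10, 30), bcuid = 1L))
  p <- clip_bcus(bcu, eez)
  expect_length(p, 1)
  expect_equal(p[[1]]$country, "A")
  expect_equal(polygon_area(p[[1]]$ring), 30 * 20)
  expect_equal(p[[1]]$kind, "bcu_country_portion")
})

test_that("a straddling BCU partitions into portions whose areas sum", {
  eez <- list(rp_zone("eez_A", "eez", rect_ring(0, 50, 0, 50), country = "A"),
              rp_zone("eez_B", "eez", rect_ring(50, 100, 0, 50), country = "B"))
  bcu <- list(rp_zone("bcu_1", "bcu", rect_ring(30, 80, 10, 30), bcuid = 1L))
  p <- clip_bcus(bcu, eez)
  expect_length(p, 2)
  expect_equal(sum(vapply(p, function(z) polygon_area(z$ring), numeric(1))),
               50 * 20, tolerance = 1e-9)
})

test_that("portion count equals the generator's membership table row count", {
  g <- generate_geometry(world_config(seed = 7))
  p <- clip_bcus(g$bcus, g$eez)
  expect_length(p, nrow(g$membership))
  got <- unique(data.frame(
    country = vapply(p, `[[`, "", "country"),
    bcuid = vapply(p, `[[`, 0L, "bcuid")))
  want <- g$membership[order(g$membership$bcuid, g$membership$country), ]
  got <- got[order(got$bcuid, got$country), ]
  expect_equal(got$bcuid, want$bcuid)
  expect_equal(got$country, want$country)
})

test_that("portion areas per BCU sum to the 200-nm-clipped BCU area", {
  g <- generate_geometry(world_config(seed = 13))
  p <- clip_bcus(g$bcus, g$eez)
  for (b in g$bcus) {
    mine <- p[vapply(p, `[[`, 0L, "bcuid") == b$bcuid]
    clipped <- clip_polygon_convex(
      b$ring, rect_ring(0, max(g$strips), g$limit_y, g$shore_y))
    expect_equal(sum(vapply(mine, function(z) polygon_area(z$ring),
                            numeric(1))),
                 polygon_area(clipped), tolerance = 1e-6,
                 label = b$zone_id)
  }
})

test_that("zonal means follow the cell-center rule", {
  # constant raster -> the constant
  r <- make_raster(matrix(3.7, 6, 6), cellsize = 1)
  z <- rp_zone("z", "bcu", rect_ring(0.2, 4.9, 1.1, 5.3), bcuid = 1L)
  expect_equal(zonal_mean(r, z), 3.7)
  # 4x4 with known values; zone covers exactly the 4 center cells
  vals <- matrix(1:16, 4, 4)           # column-major: cell (r,c) = r + 4(c-1)
  r2 <- make_raster(vals, cellsize = 1)
  z2 <- rp_zone("z2", "bcu", rect_ring(1, 3, 1, 3), bcuid = 2L)
  # centers inside (1,3)x(1,3): rows 2-3, cols 2-3 -> values 6,7,10,11
  expect_equal(zonal_mean(r2, z2), mean(c(6, 7, 10, 11)))
  # zone outside the raster extent -> NA with a warning
  z3 <- rp_zone("z3", "bcu", rect_ring(100, 110, 100, 110), bcuid = 3L)
  expect_warning(out <- zonal_mean(r2, z3), "no cell centers")
  expect_true(is.na(out))
  # bounded by the raster's range over the zone
  set.seed(1)
  r4 <- make_raster(matrix(runif(64), 8, 8), cellsize = 1)
  z4 <- rp_zone("z4", "bcu", rect_ring(1, 6, 2, 7), bcuid = 4L)
  idx <- zone_cells(r4, z4)
  m <- zonal_mean(r4, z4)
  expect_gte(m, min(r4$values[idx])); expect_lte(m, max(r4$values[idx]))
})

test_that("BCU summaries pool cells across portions and match a brute force", {
  res <- run_small_change_analysis(seed = 6)
  st <- res$stacks$`2013`
  smry <- res$summary
  for (i in seq_len(nrow(smry))) {
    b <- smry$bcuid[i]
    mine <- res$portions[vapply(res$portions, `[[`, 0L, "bcuid") == b]
    idx <- unique(unlist(lapply(mine, zone_cells, raster = st$total)))
    expect_equal(smry$mean_chi[i], mean(st$total$values[idx]),
                 tolerance = 1e-12)
    # percent contributions sum to one and category means sum to the total
    expect_equal(smry$pct_climate[i] + smry$pct_land[i] + smry$pct_marine[i],
                 1, tolerance = 1e-9)
    expect_equal(smry$mean_climate[i] + smry$mean_land[i] + smry$mean_marine[i],
                 smry$mean_chi[i], tolerance = 1e-9)
  }
})

test_that("an all-climate world attributes 100% of CHI to climate", {
  s <- list(make_stressor("s1", "climate", matrix(0.5, 10, 10), cellsize = 10))
  h <- list(make_habitat("h1", matrix(1, 10, 10), cellsize = 10))
  mu <- matrix(1, 1, 1, dimnames = list("h1", "s1"))
  st <- compute_impact(s, h, mu)
  z <- rp_zone("p", "bcu_country_portion", rect_ring(10, 60, 10, 60),
               bcuid = 1L, country = "A")
  smry <- summarize_bcu(list(z), st)
  expect_equal(smry$pct_climate, 1)
  expect_equal(smry$pct_land, 0)
})

test_that("country summaries average portion means by default, pool on request", {
  v <- matrix(0, 10, 10)
  v[, 1:5] <- 2; v[, 6:10] <- 4
  st <- constant_stack(v, cellsize = 1)
  p1 <- rp_zone("b1_A", "bcu_country_portion", rect_ring(0, 5, 2, 8),
                bcuid = 1L, country = "A")   # 30 cells of 2
  p2 <- rp_zone("b2_A", "bcu_country_portion", rect_ring(5, 10, 4, 6),
                bcuid = 2L, country = "A")   # 10 cells of 4
  s_mean <- summarize_country(list(p1, p2), st)
  expect_equal(s_mean$mean_chi, 3)  # (2 + 4) / 2, portions equally weighted
  s_pool <- summarize_country(list(p1, p2), st, method = "pooled")
  expect_equal(s_pool$mean_chi, (30 * 2 + 10 * 4) / 40)
  # permutation invariance in portion order
  s_rev <- summarize_country(list(p2, p1), st)
  expect_equal(s_rev$mean_chi, s_mean$mean_chi)
  # single portion reduces to that portion's mean
  s_one <- summarize_country(list(p1), st)
  expect_equal(s_one$mean_chi, 2)
})

test_that("membership counts are exact on the packaged table and on toys", {
  tab <- load_membership_fixture()
  mc <- membership_counts(tab)
  expect_equal(mc$n_bcus, 50)
  expect_equal(mc$n_countries, 28)
  expect_equal(as.integer(mc$countries_per_bcu[c("1", "2", "3")]),
               c(38L, 8L, 4L))
  one <- data.frame(country = "AUS", bcuid = 1L)
  mc1 <- membership_counts(one)
  expect_equal(mc1$n_countries, 1)
  expect_equal(mc1$n_bcus, 1)
  dup <- rbind(one, one)
  expect_error(membership_counts(dup), "duplicate")
})
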