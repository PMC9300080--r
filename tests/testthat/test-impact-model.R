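test_that("rescaling log-transforms, clips and divides as specified", {
  # 3x3 ramp 0..8, clip at the maximum: each cell log(x+1)/log(9)
  r <- make_raster(matrix(0:8, 3, 3))
  out <- rescale_stressor(r, clip_quantile = 1)
  expect_equal(out$values, log(matrix(0:8, 3, 3) + 1) / log(9),
               tolerance = 1e-12)
  expect_equal(max(out$values), 1)  # max equals clip value -> exactly 1
  # constant zero raster: clip value 0 -> all zeros with a warning
  expect_warning(z <- rescale_stressor(make_raster(matrix(0, 2, 2))),
                 "clip value 0")
  expect_true(all(z$values == 0))
  # all-missing raster rejected
  expect_error(rescale_stressor(make_raster(matrix(NA_real_, 2, 2))),
               "all-missing")
})

test_that("joint two-period rescaling pools the clip value across periods", {
  a <- make_raster(matrix(seq(0, 1, length.out = 9), 3, 3))
  b <- make_raster(matrix(seq(0, 3, length.out = 9), 3, 3))
  rs <- rescale_periods(a, b, clip_quantile = 1)
  # pooled clip = log(4): period one's max maps to log(2)/log(4), not 1
  expect_equal(max(rs$`2008`$values), log(2) / log(4), tolerance = 1e-12)
  expect_equal(max(rs$`2013`$values), 1, tolerance = 1e-12)
  # within-period rescale of the same layer would reach 1 instead
  expect_equal(max(rescale_stressor(a, 1)$values), 1, tolerance = 1e-12)
})

test_that("unit intensity, one habitat, unit vulnerability give unit impact", {
  st <- constant_stack(matrix(1, 3, 3))
  expect_equal(st$total$values, matrix(1, 3, 3))
  expect_equal(st$per_category$climate$values, matrix(1, 3, 3))
})

test_that("cells with no habitat anywhere yield an all-zero stack", {
  s <- make_stressor("s1", "marine", matrix(runif(9), 3, 3))
  h <- make_habitat("h1", matrix(0, 3, 3))
  mu <- matrix(1, 1, 1, dimnames = list("h1", "s1"))
  st <- compute_impact(list(s), list(h), mu)
  expect_equal(st$total$values, matrix(0, 3, 3))
})

test_that("impact stack matches the naive triple-loop oracle on random worlds", {
  for (seed in 1:20) {
    mw <- random_micro_world(seed)
    for (agg in c("mean", "sum")) {
      got <- compute_impact(mw$stressors, mw$habitats, mw$vuln,
                            habitat_agg = agg)
      want <- oracle_impact(mw$stressors, mw$habitats, mw$vuln,
                            habitat_agg = agg)
      expect_equal(got$total$values, want$total, tolerance = 1e-9)
      for (cat in names(want$per_category))
        expect_equal(got$per_category[[cat]]$values, want$per_category[[cat]],
                     tolerance = 1e-9)
    }
  }
})

test_that("category rasters sum to total CHI at every cell", {
  for (seed in c(3, 17)) {
    mw <- random_micro_world(seed, nr = 8, nc = 8, n_s = 6)
    st <- compute_impact(mw$stressors, mw$habitats, mw$vuln)
    cat_sum <- st$per_category$climate$values + st$per_category$land$values +
      st$per_category$marine$values
    expect_equal(cat_sum, st$total$values, tolerance = 1e-12)
    per_s <- Reduce(`+`, lapply(st$per_stressor, `[[`, "values"))
    expect_equal(per_s, st$total$values, tolerance = 1e-12)
  }
})

test_that("raising one stressor's intensity never decreases total CHI", {
  mw <- random_micro_world(23)
  st0 <- compute_impact(mw$stressors, mw$habitats, mw$vuln)
  bumped <- mw$stressors
  bumped[[2]]$raster$values[3, 3] <- min(1, bumped[[2]]$raster$values[3, 3] + 0.4)
  st1 <- compute_impact(bumped, mw$habitats, mw$vuln)
  expect_true(all(st1$total$values - st0$total$values >= -1e-12))
})

test_that("with intensities and weights in [0,1] impacts respect scale bounds", {
  for (seed in 4:8) {
    mw <- random_micro_world(seed, n_s = 5)
    st <- compute_impact(mw$stressors, mw$habitats, mw$vuln)
    for (ps in st$per_stressor)
      expect_true(all(ps$values <= 1 + 1e-12))
    expect_true(all(st$total$values <= 5 + 1e-12))
  }
})

test_that("grid and vulnerability mismatches fail fast with names", {
  mw <- random_micro_world(1)
  bad <- mw$stressors
  bad[[2]]$raster <- make_raster(matrix(0, 4, 4))
  expect_error(compute_impact(bad, mw$habitats, mw$vuln), "s2")
  expect_error(compute_impact(mw$stressors, mw$habitats,
                              mw$vuln[, -2, drop = FALSE]), "s2")
  vneg <- mw$vuln; vneg[1, 1] <- -0.1
  expect_error(compute_impact(mw$stressors, mw$habitats, vneg), "negative")
})

test_that("missing intensities contribute zero unless all layers are missing", {
  s1 <- make_stressor("s1", "climate", matrix(c(NA, 1, 1, 1), 2, 2))
  s2 <- make_stressor("s2", "marine", matrix(c(NA, NA, 0.5, 0.5), 2, 2))
  h <- make_habitat("h1", matrix(1, 2, 2))
  mu <- matrix(1, 1, 2, dimnames = list("h1", c("s1", "s2")))
  expect_message(st <- compute_impact(list(s1, s2), list(h), mu),
                 "missing intensity")
  expect_true(is.na(st$total$values[1, 1]))      # all stressors missing there
  expect_equal(st$total$values[2, 1], 1)          # s2 missing -> contributes 0
  expect_equal(st$total$values[1, 2], 1.5)
})

test_that("change analysis nulls out ineligible stressors exactly", {
  base <- matrix(runif(16), 4, 4)
  h <- make_habitat("h1", matrix(1, 4, 4))
  mu <- matrix(1, 1, 2, dimnames = list("h1", c("keep", "drop")))
  mk <- function(keep_v, drop_v) list(
    make_stressor("keep", "climate", keep_v, eligible = TRUE),
    make_stressor("drop", "marine", drop_v, eligible = FALSE))
  st08 <- compute_impact(mk(base, base), list(h), mu)
  # identical periods -> zero everywhere
  d0 <- change_in_impact(st08, st08, c(keep = TRUE, drop = FALSE))
  expect_equal(d0$total$values, matrix(0, 4, 4))
  # only the ineligible stressor changes -> still identically zero
  st13 <- compute_impact(mk(base, pmin(base + 0.3, 1)), list(h), mu)
  d1 <- change_in_impact(st08, st13, c(keep = TRUE, drop = FALSE))
  expect_equal(d1$total$values, matrix(0, 4, 4))
  expect_equal(d1$per_category$marine$values, matrix(0, 4, 4))
  # missing eligibility flag is an error naming the stressor
  expect_error(change_in_impact(st08, st13, c(keep = TRUE)), "drop")
})

test_that("a flat +0.2 intensity rise in one eligible stressor moves CHI by +0.2", {
  h <- make_habitat("h1", matrix(1, 3, 3))
  mu <- matrix(1, 1, 1, dimnames = list("h1", "s1"))
  st08 <- compute_impact(list(make_stressor("s1", "climate",
                                            matrix(0.3, 3, 3))), list(h), mu)
  st13 <- compute_impact(list(make_stressor("s1", "climate",
                                            matrix(0.5, 3, 3))), list(h), mu)
  d <- change_in_impact(st08, st13, c(s1 = TRUE))
  expect_equal(d$total$values, matrix(0.2, 3, 3), tolerance = 1e-12)
  expect_equal(d$per_category$climate$values, matrix(0.2, 3, 3),
               tolerance = 1e-12)
})
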