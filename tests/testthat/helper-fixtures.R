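# Shared constructors and independent oracles used across the suite.

make_raster <- function(values, nr = NULL, nc = NULL, cellsize = 1) {
  if (!is.matrix(values)) values <- matrix(values, nr, nc)
  rp_raster(values, cellsize = cellsize)
}

make_stressor <- function(name, category, values, period = "2013",
                          eligible = TRUE, cellsize = 1) {
  list(name = name, category = category, period = period,
       raster = make_raster(values, cellsize = cellsize),
       change_eligible = eligible)
}

make_habitat <- function(name, presence, cellsize = 1) {
  list(name = name, presence = make_raster(presence, cellsize = cellsize))
}

# single-stressor stack with constant unit vulnerability everywhere; handy for
# closed-form zonal checks
constant_stack <- function(total_values, cellsize = 1) {
  s <- make_stressor("s1", "climate", total_values, cellsize = cellsize)
  h <- make_habitat("h1", matrix(1, nrow(s$raster$values),
                                 ncol(s$raster$values)), cellsize = cellsize)
  mu <- matrix(1, 1, 1, dimnames = list("h1", "s1"))
  compute_impact(list(s), list(h), mu)
}

small_world_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(grid_shape = c(32, 32), n_countries = 4, n_bcus = 5, seed = seed),
    list(...))
  do.call(world_config, args)
}

# independent naive oracle: explicit loops over cells x stressors x habitats
oracle_impact <- function(stressors, habitats, vuln,
                          habitat_agg = "mean") {
  dims <- dim(stressors[[1]]$raster$values)
  total <- matrix(0, dims[1], dims[2])
  per_cat <- list(climate = total, land = total, marine = total)
  for (r in seq_len(dims[1])) {
    for (cl in seq_len(dims[2])) {
      n_present <- 0
      for (h in habitats)
        if (h$presence$values[r, cl] == 1) n_present <- n_present + 1
      denom <- if (habitat_agg == "mean") max(1, n_present) else 1
      for (s in stressors) {
        wsum <- 0
        for (h in habitats)
          if (h$presence$values[r, cl] == 1)
            wsum <- wsum + vuln[h$name, s$name]
        val <- s$raster$values[r, cl] * wsum / denom
        per_cat[[s$category]][r, cl] <- per_cat[[s$category]][r, cl] + val
        total[r, cl] <- total[r, cl] + val
      }
    }
  }
  list(total = total, per_category = per_cat)
}

# seeded random micro-world for oracle comparisons
random_micro_world <- function(seed, nr = 5, nc = 5, n_s = 4, n_h = 3) {
  set.seed(seed)
  cats <- sample(c("climate", "land", "marine"), n_s, replace = TRUE)
  stressors <- lapply(seq_len(n_s), function(i) {
    make_stressor(paste0("s", i), cats[i], matrix(runif(nr * nc), nr, nc))
  })
  habitats <- lapply(seq_len(n_h), function(i) {
    make_habitat(paste0("h", i), matrix(rbinom(nr * nc, 1, 0.6), nr, nc))
  })
  vuln <- matrix(runif(n_h * n_s), n_h, n_s,
                 dimnames = list(paste0("h", seq_len(n_h)),
                                 paste0("s", seq_len(n_s))))
  list(stressors = stressors, habitats = habitats, vuln = vuln)
}

country_codes_for_test <- function(n) sprintf("C%02d", seq_len(n))

# end-to-end change analysis on a small world; returns mean per-category
# delta across BCU cells (used for trend-recovery properties)
run_small_change_analysis <- function(seed) {
  w <- generate_world(small_world_config(seed = seed))
  per <- vapply(w$stressors, `[[`, "", "period")
  s08 <- w$stressors[per == "2008"]; s13 <- w$stressors[per == "2013"]
  for (i in seq_along(s08)) {
    rs <- rescale_periods(s08[[i]]$raster, s13[[i]]$raster)
    s08[[i]]$raster <- rs$`2008`; s13[[i]]$raster <- rs$`2013`
  }
  st08 <- compute_impact(s08, w$habitats, w$vulnerability)
  st13 <- compute_impact(s13, w$habitats, w$vulnerability)
  elig <- stats::setNames(vapply(s13, `[[`, TRUE, "change_eligible"),
                          vapply(s13, `[[`, "", "name"))
  delta <- change_in_impact(st08, st13, elig)
  portions <- clip_bcus(w$geometry$bcus, w$geometry$eez)
  smry <- summarize_bcu(portions, st13, delta)
  list(climate = mean(smry$delta_climate), marine = mean(smry$delta_marine),
       land = mean(smry$delta_land), summary = smry, world = w,
       stacks = list(`2008` = st08, `2013` = st13), delta = delta,
       portions = portions)
}

# independent quadrant comparator: straight-line logic, no shared code path
oracle_quadrants <- function(x, y) {
  mx <- stats::median(x); my <- stats::median(y)
  out <- character(length(x))
  for (i in seq_along(x)) {
    if (x[i] >= mx) {
      out[i] <- if (y[i] >= my) "high_x_high_y" else "high_x_low_y"
    } else {
      out[i] <- if (y[i] >= my) "low_x_high_y" else "low_x_low_y"
    }
  }
  out
}
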