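# Stage 3: zonal summaries.
# Clips BCUs to the 200-nm EEZ limits, splits them by country, and reduces
# the impact rasters to per-BCU and per-country tables (means, percent
# contributions by category, changes). Also reports the same counts on the
# packaged real-world membership table for comparison.
source("analysis/00_config.R")

res <- local({
  # recompute the stacks deterministically rather than reading stage-2 output
  world <- if (dir.exists(WORLD_DIR)) load_world(WORLD_DIR)
  else generate_world(study_config(), out_dir = WORLD_DIR)
  per <- vapply(world$stressors, `[[`, "", "period")
  s08 <- world$stressors[per == "2008"]; s13 <- world$stressors[per == "2013"]
  snap13 <- lapply(s13, function(s) { s$raster <- rescale_stressor(s$raster); s })
  stack13 <- compute_impact(snap13, world$habitats, world$vulnerability)
  for (i in seq_along(s08)) {
    rs <- rescale_periods(s08[[i]]$raster, s13[[i]]$raster)
    s08[[i]]$raster <- rs$`2008`; s13[[i]]$raster <- rs$`2013`
  }
  elig <- setNames(vapply(s13, `[[`, TRUE, "change_eligible"),
                   vapply(s13, `[[`, "", "name"))
  delta <- change_in_impact(
    compute_impact(s08, world$habitats, world$vulnerability),
    compute_impact(s13, world$habitats, world$vulnerability), elig)
  portions <- clip_bcus(world$geometry$bcus, world$geometry$eez)
  list(world = world, stack13 = stack13, delta = delta, portions = portions)
})

bcu <- summarize_bcu(res$portions, res$stack13, res$delta)
country <- summarize_country(res$portions, res$stack13, res$delta)
write.csv(bcu, file.path(RESULTS_DIR, "bcu_summary.csv"), row.names = FALSE)
write.csv(country, file.path(RESULTS_DIR, "country_summary.csv"),
          row.names = FALSE)

cat("Per-BCU CHI: ", round(min(bcu$mean_chi), 2), "-",
    round(max(bcu$mean_chi), 2), " (mean ", round(mean(bcu$mean_chi), 2),
    ")\n", sep = "")
cat("Mean contribution climate/land/marine: ",
    paste(round(100 * colMeans(bcu[c("pct_climate", "pct_land",
                                     "pct_marine")])), collapse = "/"),
    "%\n", sep = "")
cat("BCUs with rising CHI 2008-2013: ", sum(bcu$delta_chi > 0), "/",
    nrow(bcu), "\n", sep = "")

tab <- load_membership_fixture()
mc <- membership_counts(tab)
cat("Packaged real membership table: ", mc$n_bcus, " BCUs, ",
    mc$n_countries, " countries; 1/2/3-country BCUs: ",
    paste(as.integer(mc$countries_per_bcu), collapse = "/"), "\n", sep = "")
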