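# Stage 2: cumulative human impact rasters.
# 2013 snapshot uses within-period rescaling of each stressor; the 2008-2013
# change uses joint two-period rescaling and drops the seven stressors
# without comparable data in both periods. Writes total and per-category
# CHI and delta-CHI rasters.
source("analysis/00_config.R")

if (!dir.exists(WORLD_DIR)) {
  world <- generate_world(study_config(), out_dir = WORLD_DIR)
} else {
  world <- load_world(WORLD_DIR)
}

per <- vapply(world$stressors, `[[`, "", "period")
s08 <- world$stressors[per == "2008"]
s13 <- world$stressors[per == "2013"]

snap13 <- lapply(s13, function(s) {
  s$raster <- rescale_stressor(s$raster); s
})
stack13 <- compute_impact(snap13, world$habitats, world$vulnerability)

for (i in seq_along(s08)) {
  rs <- rescale_periods(s08[[i]]$raster, s13[[i]]$raster)
  s08[[i]]$raster <- rs$`2008`; s13[[i]]$raster <- rs$`2013`
}
j08 <- compute_impact(s08, world$habitats, world$vulnerability)
j13 <- compute_impact(s13, world$habitats, world$vulnerability)
elig <- setNames(vapply(s13, `[[`, TRUE, "change_eligible"),
                 vapply(s13, `[[`, "", "name"))
delta <- change_in_impact(j08, j13, elig)

out <- file.path(RESULTS_DIR, "impact")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
write_ascii_grid(stack13$total, file.path(out, "chi_2013_total.asc"))
for (cat in names(stack13$per_category))
  write_ascii_grid(stack13$per_category[[cat]],
                   file.path(out, sprintf("chi_2013_%s.asc", cat)))
write_ascii_grid(delta$total, file.path(out, "delta_chi_total.asc"))
for (cat in names(delta$per_category))
  write_ascii_grid(delta$per_category[[cat]],
                   file.path(out, sprintf("delta_chi_%s.asc", cat)))

sea <- !is.na(stack13$total$values)
cat("2013 CHI over the grid: mean ", round(mean(stack13$total$values[sea]), 3),
    ", max ", round(max(stack13$total$values[sea]), 3), "\n", sep = "")
cat("Change analysis excluded ", sum(!elig), " of ", length(elig),
    " stressors: ", paste(names(elig)[!elig], collapse = ", "), "\n", sep = "")
cat("Mean delta-CHI: ", round(mean(delta$total$values), 4), "\n", sep = "")
cat("Rasters written under ", out, "\n", sep = "")
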