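# Stage 1: generate the synthetic study system and serialize it.
# Writes GeoJSON polygon layers (countries' land, EEZs to the 200-nm limit,
# BCUs), ASCII-grid stressor/habitat rasters for 2008 and 2013, the
# vulnerability matrix, and the management-metric table with latent truth.
source("analysis/00_config.R")

world <- generate_world(study_config(), out_dir = WORLD_DIR)

mc <- membership_counts(world$geometry$membership)
cat("Simulated world (seed ", SEED, "):\n", sep = "")
cat("  ", mc$n_bcus, " BCUs across ", mc$n_countries, " countries; ",
    mc$n_rows, " membership rows\n", sep = "")
cat("  BCUs spanning 1/2/3 countries: ",
    paste(as.integer(mc$countries_per_bcu), collapse = "/"), "\n", sep = "")
cat("  ", length(world$stressors) / 2, " stressors x 2 periods, ",
    length(world$habitats), " habitats\n", sep = "")
cat("Serialized under ", WORLD_DIR, "\n", sep = "")
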