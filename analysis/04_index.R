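# Stage 4: per-country management indices.
# Directional min-max normalization of each management metric across the
# analyzed countries, regional imputation of missing scores, equal-weight
# averaging into one index per impact category, and collinearity diagnostics.
source("analysis/00_config.R")

world <- if (dir.exists(WORLD_DIR)) load_world(WORLD_DIR) else
  generate_world(study_config(), out_dir = WORLD_DIR)

idx <- build_management_index(world$metrics$table)
write.csv(idx$index, file.path(RESULTS_DIR, "management_index.csv"),
          row.names = FALSE)
write.csv(idx$components, file.path(RESULTS_DIR, "index_components.csv"),
          row.names = FALSE)
write.csv(idx$collinearity, file.path(RESULTS_DIR, "collinearity.csv"),
          row.names = FALSE)

for (cat_ in c("climate", "marine", "land")) {
  sc <- idx$index[idx$index$category == cat_, ]
  top <- sc[which.max(sc$score), ]; bot <- sc[which.min(sc$score), ]
  cat(sprintf("%-8s index: best %s (%.2f), worst %s (%.2f)\n", cat_,
              top$country, top$score, bot$country, bot$score))
}
cat(sum(idx$components$imputed), "component scores imputed from regions\n")
flg <- idx$collinearity[which(idx$collinearity$flagged), ]
if (nrow(flg)) {
  cat("Collinear component pairs (kept with equal weights):\n")
  print(flg[, c("category", "metric_a", "metric_b", "r", "p_value")],
        row.names = FALSE)
} else cat("No collinear component pairs flagged\n")
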