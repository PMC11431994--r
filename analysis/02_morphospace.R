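#!/usr/bin/env Rscript
# Stage 2: build the per-caste morphospace.
#
# Standardize the 8 traits within each caste, extract principal components
# of the correlation matrix, retain the first 4 and varimax-rotate them;
# workers' rotated scores are the coordinates used by every later stage.

library(antmorph)

traits <- read_trait_table(file.path("results", "data", "traits.csv"))

for (caste in c("major", "minor")) {
  model <- build_morphospace(traits, caste, n_pcs = 4L)
  print(model)
  morphospace_to_json(model,
                      file.path("results",
                                paste0("morphospace_", caste, ".json")))
  write_scores_csv(model,
                   file.path("results", paste0("scores_", caste, ".csv")))
  loadings <- data.frame(trait = rownames(model$loadings_rotated),
                         round(model$loadings_rotated, 4),
                         check.names = FALSE)
  write.csv(loadings,
            file.path("results", paste0("loadings_", caste, ".csv")),
            row.names = FALSE, quote = FALSE)
}
cat("Scores and loadings written under results/\n")
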