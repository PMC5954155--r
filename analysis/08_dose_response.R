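#!/usr/bin/env Rscript
# Cross-strain comparison: per-seed mean fitness effects in the
# high-dCas9 screen (x) against the low-dCas9 screen (y). The regression
# slope measures how much seed-specific toxicity is attenuated when dCas9
# expression is reduced ~2.5-fold.

library(crispritox)

per_seed <- function(name) {
  dir <- file.path("results", name)
  guides <- read_guides_tsv(file.path(dir, "guides.tsv"))
  fitness <- read_fitness_tsv(file.path(dir, "fitness.tsv"))
  tree <- fit_region_tree(fitness, guides)
  neutral <- classify_neutral_guides(tree, guides)
  seed_summary(fitness, guides, restriction = "neutral", neutral = neutral)
}

hi <- per_seed("screen_high")
lo <- per_seed("screen_low")
fit <- cross_strain_regression(hi, lo)
message(sprintf("cross-strain regression over %d seeds: slope %.2f, R^2 %.2f",
                fit$n_seeds, fit$slope, fit$r_squared))
m <- merge(hi, lo, by = "seed", suffixes = c("_high", "_low"))
write.table(m, "results/cross_strain_seed_means.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
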