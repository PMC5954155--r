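#!/usr/bin/env Rscript
# In-silico mutagenesis of the trained model: per-position standard
# deviation of single-mutation effects over 1000 random sequences, and the
# pairwise interaction matrix (mean Euclidean distance between
# double-mutation effects and summed singles) over 100 random sequences.

library(crispritox)

dir <- "results/screen_high"
model <- readRDS(file.path(dir, "seed_model.rds"))

prof <- single_mutation_effects(model, n_sequences = 1000L, seed = 1L)
v <- positional_variability(prof)
out <- data.frame(spacer_position = seq_along(v),   # 20 = PAM-proximal
                  window_position = 20L + seq_along(v),
                  std_mutation_effect = v)
write.table(out, file.path(dir, "positional_variability.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("top-5 positions by mutation-effect std: ",
        paste(sort(order(v, decreasing = TRUE)[1:5]), collapse = ", "))

im <- pairwise_interactions(model, n_sequences = 100L, seed = 1L)
write.table(round(im, 6), file.path(dir, "interaction_matrix.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("interaction concentration in the 5x5 seed block: %.1fx",
                seed_block_concentration(im)))
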