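#!/usr/bin/env Rscript
# Train the locally connected sequence-to-fitness model on neutral-region
# guides of the high-dCas9 screen (20-nt spacer input, seed-stratified
# 80/10/10 split) and evaluate it on the held-out test set.

library(crispritox)

dir <- "results/screen_high"
guides <- read_guides_tsv(file.path(dir, "guides.tsv"))
fitness <- read_fitness_tsv(file.path(dir, "fitness.tsv"))
neutral <- read.table(file.path(dir, "neutral_guides.tsv"), header = TRUE,
                      sep = "\t")$neutral

d <- merge(guides, fitness[, c("guide_id", "log2fc", "discarded")],
           by = "guide_id", sort = FALSE)
d <- d[match(guides$guide_id, d$guide_id), ]
keep <- neutral & !d$discarded & !is.na(d$log2fc)
d <- d[keep, ]
message(sprintf("training pool: %d neutral-region guides", nrow(d)))

spec <- model_spec(input_len = 20L, rng_seed = 1L)
split <- make_split(d$seed5, seed = 1L)
model <- train_model(spec, d$spacer, d$log2fc, split)
ev <- evaluate_model(model, d$spacer[split$test], d$log2fc[split$test])
message(sprintf("held-out test: Pearson r = %.3f, RMSE = %.3f (n = %d)",
                ev$pearson, ev$rmse, length(split$test)))

write.table(model$history, file.path(dir, "model_history.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
pred <- data.frame(guide_id = d$guide_id[split$test],
                   observed = d$log2fc[split$test],
                   predicted = predict(model, d$spacer[split$test]))
write.table(pred, file.path(dir, "model_test_predictions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(model, file.path(dir, "seed_model.rds"))   # scratch artifact
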