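#!/usr/bin/env Rscript
# Normalized per-guide log2 fold changes for both screens: median-of-ratios
# size factors, per-replicate log ratios, control-guide anchoring,
# <20-read discard rule.

library(crispritox)

for (name in c("screen_high", "screen_low")) {
  dir <- file.path("results", name)
  counts <- read_counts_tsv(file.path(dir, "counts.tsv"))
  guides <- read_guides_tsv(file.path(dir, "guides.tsv"))
  ft <- compute_log2fc(counts, guides = guides)
  write_fitness_tsv(ft, file.path(dir, "fitness.tsv"))
  message(sprintf("%s: %d guides, %d discarded (<20 reads), mean log2FC %.2f",
                  name, nrow(ft), sum(ft$discarded),
                  mean(ft$log2fc, na.rm = TRUE)))
}
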