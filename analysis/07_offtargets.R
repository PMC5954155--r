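#!/usr/bin/env Rscript
# Seed-match off-target analysis on the high-dCas9 screen: split
# template-strand guides in neutral genes into unexpected-defect and
# no-defect sets, sweep the minimum PAM-proximal identity k = 6..15, and
# test the enrichment of important-region off-targets among defect guides.

library(crispritox)

dir <- "results/screen_high"
guides <- read_guides_tsv(file.path(dir, "guides.tsv"))
fitness <- read_fitness_tsv(file.path(dir, "fitness.tsv"))
ann <- read_annotation(file.path(dir, "annotation.tsv"))
genome <- read_genome(file.path(dir, "genome.fasta"))

sets <- defect_sets(fitness, guides, ann, threshold = -3.5)
message(sprintf("template-strand guides in neutral genes: %d defect, %d no-defect",
                nrow(sets$defect), nrow(sets$no_defect)))

index <- index_genome_seeds(genome, k = 6L)
curve <- detection_rate_curve(sets$defect, sets$no_defect, index, ann)
write.table(curve$curve, file.path(dir, "detection_rate_curve.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(curve$curve)
message("argmax of the difference curve: k = ", curve$argmax_k)

ht <- offtarget_fisher_test(curve$defect_maxk, curve$no_defect_maxk, k = 9L)
message(sprintf("Fisher exact test at k = 9: odds ratio %.1f, p = %.3g",
                ht$estimate, ht$p.value))
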