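#!/usr/bin/env Rscript
# Positional analyses on the high-dCas9 screen: the orientation-stratified
# regression tree over PAM position, the important/neutral partition,
# rolling averages of the fitness effect, and the reverse-polar window test
# downstream of isolated essential/fitness gene ends.

library(crispritox)

dir <- "results/screen_high"
guides <- read_guides_tsv(file.path(dir, "guides.tsv"))
fitness <- read_fitness_tsv(file.path(dir, "fitness.tsv"))
ann <- read_annotation(file.path(dir, "annotation.tsv"))

tree <- fit_region_tree(fitness, guides)
neutral <- classify_neutral_guides(tree, guides)
message(sprintf("tree: %d leaves; %d/%d guides classified neutral",
                nrow(tree$leaves), sum(neutral), nrow(guides)))

write.table(tree$leaves, file.path(dir, "region_tree_leaves.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
important <- tree$leaves[tree$leaves$pred < -3.5, ]
write.table(important, file.path(dir, "important_regions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(guide_id = guides$guide_id, neutral = neutral),
            file.path(dir, "neutral_guides.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# rolling fitness along the genome for coding-strand guides (50 bp window)
d <- merge(guides, fitness[, c("guide_id", "log2fc", "discarded")],
           by = "guide_id")
d <- d[!d$discarded & !is.na(d$log2fc), ]
roll <- rolling_average(d$pam_pos[d$orientation == "coding"],
                        d$log2fc[d$orientation == "coding"], window = 50)
write.table(roll, file.path(dir, "rolling_coding_50bp.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# strong-defect (important) regions are masked out of the windows so the
# weak reverse-polar signal is not confounded by polar conduits into
# downstream operons
polar <- polar_effect_test(fitness, guides, ann, include = neutral)
write.table(polar, file.path(dir, "polar_effect_test.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("reverse-polar windows:")
print(polar)
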