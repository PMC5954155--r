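test_that("genome generation is deterministic and respects the config", {
  cfg <- tiny_config()
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genome$sequence, g2$genome$sequence)
  expect_identical(g1$annotation, g2$annotation)
  expect_identical(g1$planted$bad_seeds, g2$planted$bad_seeds)

  expect_equal(nrow(g1$annotation), cfg$n_genes)
  expect_true(all(g1$annotation$end <= cfg$genome_length))
  # genes do not overlap
  a <- g1$annotation[order(g1$annotation$start), ]
  expect_true(all(utils::head(a$end, -1) <= utils::tail(a$start, -1)))

  # gene-free genome
  g0 <- generate_genome(sim_config(genome_length = 2000L, n_genes = 0L,
                                   n_bad_seeds = 0L, n_offtarget_guides = 0L,
                                   rng_seed = 3L))
  expect_equal(nrow(g0$annotation), 0L)
})

test_that("essentiality classes follow the configured fractions", {
  counts <- vapply(1:5, function(s) {
    g <- generate_genome(sim_config(n_genes = 40L, frac_essential = 0.3,
                                    n_bad_seeds = 0L, n_offtarget_guides = 0L,
                                    rng_seed = s))
    sum(g$annotation$essentiality == "essential")
  }, numeric(1))
  # Binomial(40, 0.3): mean 12, sd 2.9; the mean of 5 draws has sd ~1.3
  expect_gt(mean(counts), 12 - 4)
  expect_lt(mean(counts), 12 + 4)
})

test_that("planted structures are present in the extracted library", {
  sim <- tiny_sim()
  key <- paste(sim$guides$pam_pos, sim$guides$strand)

  bs <- sim$planted$bad_seed_sites
  m <- match(paste(bs$pam_pos, bs$strand), key)
  expect_false(anyNA(m))
  expect_equal(sim$guides$seed5[m], bs$seed)

  expect_true(sim$config$control_spacer %in% sim$guides$spacer)

  ot <- sim$planted$offtargets
  expect_equal(nrow(ot), sim$config$n_offtarget_guides)
  dm <- match(paste(ot$donor_pam_pos, ot$donor_strand), key)
  expect_false(anyNA(dm))
  # donor guides sit on the template strand of neutral genes
  expect_true(all(sim$guides$orientation[dm] == "template"))
  ess <- sim$annotation$essentiality[match(sim$guides$target_gene[dm],
                                           sim$annotation$gene)]
  expect_true(all(ess == "neutral"))
})

test_that("planted off-target sites match the donor seed for exactly k bases", {
  sim <- tiny_sim()
  k <- sim$config$offtarget_k
  idx <- index_genome_seeds(sim$genome, k = 6L)
  key <- paste(sim$guides$pam_pos, sim$guides$strand)
  ot <- sim$planted$offtargets
  for (i in seq_len(nrow(ot))) {
    donor <- sim$guides[match(paste(ot$donor_pam_pos[i], ot$donor_strand[i]),
                              key), ]
    hits <- find_offtargets(donor, idx, min_k = k)
    planted_hit <- hits[hits$pam_pos == ot$site_pam_pos[i] &
                          hits$strand == ot$site_strand[i], ]
    expect_equal(nrow(planted_hit), 1L)
    expect_equal(planted_hit$match_len, k)   # mismatch forced at k+1
  }
})

test_that("true fitness decomposition fires the right components", {
  sim <- tiny_sim()
  tr <- sim$truth
  g <- sim$guides

  # total is the component sum everywhere
  expect_equal(tr$effect_total,
               tr$effect_on_target + tr$effect_polar + tr$effect_offtarget +
                 tr$effect_badseed)

  # template guides in neutral genes with no planted features: all zeros
  ann <- sim$annotation
  neutral_genes <- ann$gene[ann$essentiality == "neutral"]
  donor_key <- paste(sim$planted$offtargets$donor_pam_pos,
                     sim$planted$offtargets$donor_strand)
  sel <- g$orientation == "template" & g$target_gene %in% neutral_genes &
    !(g$seed5 %in% sim$planted$bad_seeds$seed) &
    !(paste(g$pam_pos, g$strand) %in% donor_key)
  expect_true(any(sel))
  expect_true(all(tr$effect_total[sel] == 0 |
                    tr$effect_polar[sel] == sim$config$weak_polar_effect))

  # coding guides in essential genes carry the on-target effect
  ess_genes <- ann$gene[ann$essentiality == "essential"]
  sel2 <- g$orientation == "coding" & g$target_gene %in% ess_genes
  expect_true(all(tr$effect_on_target[sel2] == sim$config$on_target_essential))

  # template guides never get on-target or (forward) operon polar
  sel3 <- g$orientation == "template"
  expect_true(all(tr$effect_on_target[sel3] == 0))
})

test_that("bad-seed effect scales linearly with dCas9 level and vanishes at 0", {
  cfg0 <- tiny_config(dcas9_level = 0)
  gen <- generate_genome(cfg0)
  sites <- scan_pams(gen$genome)
  guides <- annotate_guides(extract_guides(gen$genome, sites, quiet = TRUE),
                            gen$annotation)
  tr0 <- simulate_true_fitness(guides, gen$annotation, gen$planted, cfg0)
  expect_true(all(tr0$effect_badseed == 0))

  cfg_half <- tiny_config(dcas9_level = 0.5)
  tr_h <- simulate_true_fitness(guides, gen$annotation, gen$planted, cfg_half)
  cfg_full <- tiny_config(dcas9_level = 1)
  tr_f <- simulate_true_fitness(guides, gen$annotation, gen$planted, cfg_full)
  expect_equal(tr_h$effect_badseed, tr_f$effect_badseed * 0.5)
})

test_that("count simulation matches closed-form expectations", {
  # null screen, near-zero dispersion: end/start ratios ~ 1
  set.seed(5)
  truth0 <- data.frame(guide_id = paste0("g", 1:200),
                       effect_total = rep(0, 200))
  cfg <- sim_config(replicates = 2L, depth_per_guide = 5000,
                    nb_dispersion = 0, rng_seed = 5L)
  ct <- simulate_counts(truth0, cfg)
  ratios <- ct$counts[, "end_1"] / ct$counts[, "start_1"]
  expect_lt(abs(mean(ratios) - 1), 0.05)

  # a single -5 guide among nulls: depleted ~2^-5 relative to start
  truth1 <- data.frame(guide_id = paste0("g", 1:200),
                       effect_total = c(-5, rep(0, 199)))
  set.seed(6)
  ct1 <- simulate_counts(truth1, cfg)
  r1 <- (ct1$counts[1, "end_1"] / sum(ct1$counts[, "end_1"])) /
    (ct1$counts[1, "start_1"] / sum(ct1$counts[, "start_1"]))
  expect_lt(abs(log2(r1) - (-5)), 0.5)

  # column sums close to configured depth
  depth <- cfg$depth_per_guide * 200
  expect_true(all(abs(colSums(ct$counts) / depth - 1) < 0.05))
})

test_that("library subsetting keeps all planted guides", {
  cfg <- tiny_config(library_size = 800L)
  sim <- simulate_screen(cfg)
  expect_lte(nrow(sim$guides), 800L + 5L)
  key <- paste(sim$guides$pam_pos, sim$guides$strand)
  bs <- sim$planted$bad_seed_sites
  expect_true(all(paste(bs$pam_pos, bs$strand) %in% key))
  expect_true(sim$config$control_spacer %in% sim$guides$spacer)
})
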