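#' Run the full analysis on a (simulated or loaded) screen
#'
#' Chains the analysis stages on a screen object as produced by
#' [simulate_screen()] (or assembled from files): log2 fold changes,
#' region tree and neutral-guide classification, per-seed statistics and
#' bad-seed calls, the off-target detection-rate sweep, and optionally the
#' locally connected sequence model with mutagenesis attribution.
#'
#' @param sim list with `guides, annotation, counts, genome, config` (and
#'   `truth`, `planted` when simulated).
#' @param min_leaf,max_depth region-tree hyperparameters.
#' @param threshold strong-defect threshold (log2FC).
#' @param alpha significance level for bad-seed calls (Bonferroni-corrected).
#' @param fit_model train the sequence model and run the mutagenesis scans?
#' @param model_rng_seed seed for model init/batching and the mutagenesis
#'   sequence sets (defaults to the simulation seed).
#' @param n_mut_sequences,n_pair_sequences sizes of the random-sequence
#'   sets for the single- and pairwise-mutation scans.
#' @return list with elements `fitness, tree, neutral, seed_stats,
#'   seed_calls, reference_mean, sets, curve, fisher` and, when
#'   `fit_model`, `model, model_eval, variability, interactions`.
#' @export
analyze_screen <- function(sim, min_leaf = 10L, max_depth = 14L,
                           threshold = -3.5, alpha = 0.01,
                           fit_model = TRUE, model_rng_seed = NULL,
                           n_mut_sequences = 1000L, n_pair_sequences = 100L) {
  if (is.null(model_rng_seed)) model_rng_seed <- sim$config$rng_seed
  fitness <- compute_log2fc(sim$counts, guides = sim$guides,
                            control_spacer = sim$config$control_spacer)
  tree <- fit_region_tree(fitness, sim$guides, min_leaf = min_leaf,
                          max_depth = max_depth)
  neutral <- classify_neutral_guides(tree, sim$guides, threshold = threshold)

  ref_mean <- template_reference_mean(fitness, sim$guides)
  stats <- seed_summary(fitness, sim$guides, restriction = "neutral",
                        neutral = neutral)
  calls <- bad_seed_test(stats, ref_mean, alpha = alpha)

  sets <- defect_sets(fitness, sim$guides, sim$annotation,
                      threshold = threshold)
  index <- index_genome_seeds(sim$genome, k = 6L)
  curve <- detection_rate_curve(sets$defect, sets$no_defect, index,
                                sim$annotation)
  fisher <- offtarget_fisher_test(curve$defect_maxk, curve$no_defect_maxk,
                                  k = sim$config$offtarget_k)

  out <- list(fitness = fitness, tree = tree, neutral = neutral,
              seed_stats = stats, seed_calls = calls,
              reference_mean = ref_mean, sets = sets, curve = curve,
              fisher = fisher)

  if (fit_model) {
    d <- merge(sim$guides, fitness[, c("guide_id", "log2fc", "discarded")],
               by = "guide_id", sort = FALSE)
    # pin row order to the guide table: merge order is locale-dependent,
    # and row order feeds the (seeded) split and minibatch shuffles
    d <- d[match(sim$guides$guide_id, d$guide_id), , drop = FALSE]
    keep <- neutral & !d$discarded & !is.na(d$log2fc)
    d <- d[keep, , drop = FALSE]
    spec <- model_spec(input_len = 20L, rng_seed = model_rng_seed)
    split <- make_split(d$seed5, seed = model_rng_seed)
    model <- train_model(spec, d$spacer, d$log2fc, split)
    ev <- evaluate_model(model, d$spacer[split$test], d$log2fc[split$test])
    prof <- single_mutation_effects(model, n_sequences = n_mut_sequences,
                                    seed = model_rng_seed)
    out$model <- model
    out$model_eval <- ev
    out$model_data <- d
    out$model_split <- split
    out$variability <- positional_variability(prof)
    out$interactions <- pairwise_interactions(model,
                                              n_sequences = n_pair_sequences,
                                              seed = model_rng_seed)
  }
  out
}

#' Compare recovered bad seeds against the planted truth
#'
#' @param calls output of [bad_seed_test()].
#' @param planted the `planted` element of a simulation.
#' @return list: `recall` (fraction of planted seeds called significant),
#'   `false_positive_rate` (fraction of non-planted tested seeds called
#'   significant), `n_significant`, and `pearson` between recovered
#'   per-seed means and planted tau over the planted seeds.
#' @export
bad_seed_recovery <- function(calls, planted) {
  truth <- planted$bad_seeds
  tested <- calls[calls$call != "insufficient", , drop = FALSE]
  is_planted <- tested$seed %in% truth$seed
  sig <- tested$call == "significant"
  rec <- calls[match(truth$seed, calls$seed), , drop = FALSE]
  list(recall = mean(truth$seed %in% tested$seed[sig]),
       false_positive_rate = if (any(!is_planted)) mean(sig[!is_planted]) else 0,
       n_significant = sum(sig),
       pearson = stats::cor(rec$mean, truth$tau, use = "complete.obs"))
}

#' Interaction concentration in the PAM-proximal seed block
#'
#' Ratio of the mean interaction-matrix entry within the 5x5 PAM-proximal
#' block (positions 16-20 of the spacer) to the mean entry outside it.
#'
#' @param interactions matrix from [pairwise_interactions()].
#' @param seed_positions positions forming the seed block.
#' @return scalar ratio.
#' @export
seed_block_concentration <- function(interactions, seed_positions = 16:20) {
  len <- nrow(interactions)
  in_block <- matrix(FALSE, len, len)
  in_block[seed_positions, seed_positions] <- TRUE
  diag(in_block) <- FALSE
  off_diag <- upper.tri(interactions) | lower.tri(interactions)
  mean(interactions[in_block]) / mean(interactions[off_diag & !in_block])
}

#' Headline numbers of an analysed screen
#'
#' @param res output of [analyze_screen()].
#' @param sim the screen that produced it.
#' @return named list of scalar summaries (counts, rates, model metrics).
#' @export
screen_report <- function(res, sim) {
  rep_ <- list(
    n_guides = nrow(sim$guides),
    n_discarded = sum(res$fitness$discarded),
    n_neutral_guides = sum(res$neutral),
    n_significant_seeds = sum(res$seed_calls$call == "significant"),
    offtarget_argmax_k = res$curve$argmax_k,
    fisher_p = res$fisher$p.value,
    frac_template_neutral_defect =
      nrow(res$sets$defect) / (nrow(res$sets$defect) + nrow(res$sets$no_defect))
  )
  if (!is.null(res$model_eval)) {
    rep_$model_test_pearson <- res$model_eval$pearson
    rep_$model_test_rmse <- res$model_eval$rmse
    rep_$seed_block_interaction_ratio <-
      seed_block_concentration(res$interactions)
  }
  if (!is.null(sim$planted)) {
    rec <- bad_seed_recovery(res$seed_calls, sim$planted)
    rep_$bad_seed_recall <- rec$recall
    rep_$bad_seed_false_positive_rate <- rec$false_positive_rate
    rep_$per_seed_effect_pearson <- rec$pearson
  }
  rep_
}
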