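#' Per-seed (5-mer) fitness summaries
#'
#' Groups guides by their 5 PAM-proximal bases and summarises log2FC per
#' group. The default restriction keeps neutral-region guides (pass the
#' logical vector from [classify_neutral_guides()]); `"template"` keeps
#' template-strand guides in gene bodies; `"all"` keeps everything.
#' Discarded guides are always excluded; multi-mapping guides are kept
#' (seed identity does not depend on the mapped position).
#'
#' @param fitness fitness table.
#' @param guides annotated guide table.
#' @param restriction `"neutral"`, `"template"` or `"all"`.
#' @param neutral logical vector over guides (required for
#'   `restriction = "neutral"`).
#' @return data.frame `seed, n, mean, sd` (`sd` is `NA` for n = 1).
#' @export
seed_summary <- function(fitness, guides,
                         restriction = c("neutral", "template", "all"),
                         neutral = NULL) {
  restriction <- match.arg(restriction)
  d <- merge(guides, fitness[, c("guide_id", "log2fc", "discarded")],
             by = "guide_id", sort = FALSE)
  keep <- switch(restriction,
                 neutral = {
                   if (is.null(neutral)) stop("supply the neutral classification")
                   neutral[match(d$guide_id, guides$guide_id)]
                 },
                 template = d$orientation == "template",
                 all = rep(TRUE, nrow(d)))
  d <- d[keep & !d$discarded & !is.na(d$log2fc), , drop = FALSE]
  grp <- split(d$log2fc, d$seed5)
  grp <- grp[sort(names(grp), method = "radix")]   # locale-independent order
  data.frame(seed = names(grp),
             n = lengths(grp),
             mean = vapply(grp, mean, numeric(1)),
             sd = vapply(grp, function(v) if (length(v) > 1L) stats::sd(v)
                         else NA_real_, numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Reference mean for seed testing
#'
#' Mean log2FC of guides targeting the template strand of genes — the
#' population expected to show no fitness effect.
#'
#' @param fitness fitness table.
#' @param guides annotated guide table.
#' @return scalar mean log2FC.
#' @export
template_reference_mean <- function(fitness, guides) {
  d <- merge(guides, fitness[, c("guide_id", "log2fc", "discarded")],
             by = "guide_id", sort = FALSE)
  d <- d[!d$discarded & !is.na(d$log2fc) & d$orientation == "template", ,
         drop = FALSE]
  mean(d$log2fc)
}

#' Call bad seeds
#'
#' One-sided (lower) one-sample t-test of each seed group's mean against
#' the reference mean, Bonferroni-corrected over all 4^5 = 1024 possible
#' seeds. A seed is called significant when the corrected p is below
#' `alpha` and its mean is below the reference. Groups with fewer than 3
#' guides are reported as `insufficient`.
#'
#' @param stats per-seed summary from [seed_summary()].
#' @param reference_mean scalar reference (see
#'   [template_reference_mean()]).
#' @param alpha significance level on the corrected p.
#' @param n_tests Bonferroni multiplier (all possible 5-mers).
#' @param two_sided use a two-sided test instead.
#' @return `stats` with `t, p, p_bonferroni, call` columns added; `call`
#'   is `significant`, `not` or `insufficient`.
#' @export
bad_seed_test <- function(stats, reference_mean, alpha = 0.01,
                          n_tests = 1024L, two_sided = FALSE) {
  t_stat <- (stats$mean - reference_mean) / (stats$sd / sqrt(stats$n))
  df <- stats$n - 1L
  p <- if (two_sided) 2 * stats::pt(-abs(t_stat), df) else stats::pt(t_stat, df)
  p[stats$n < 3L] <- NA_real_
  t_stat[stats$n < 3L] <- NA_real_
  p_bonf <- pmin(1, p * n_tests)
  call <- ifelse(stats$n < 3L, "insufficient",
                 ifelse(!is.na(p_bonf) & p_bonf < alpha &
                          stats$mean < reference_mean, "significant", "not"))
  cbind(stats, data.frame(t = t_stat, p = p, p_bonferroni = p_bonf,
                          call = call, stringsAsFactors = FALSE))
}

#' Cross-strain regression of per-seed effects
#'
#' Ordinary least squares of per-seed mean log2FC in strain B on strain A
#' over the seeds present in both tables; the slope measures how much the
#' seed-specific toxicity is attenuated in strain B (e.g. at lower dCas9
#' concentration).
#'
#' @param stats_a,stats_b per-seed summaries ([seed_summary()]) for the
#'   two strains.
#' @param min_n keep seeds with at least this many guides in each strain.
#' @return list with `slope, intercept, r_squared, n_seeds` and the fitted
#'   `lm` object.
#' @export
cross_strain_regression <- function(stats_a, stats_b, min_n = 3L) {
  m <- merge(stats_a, stats_b, by = "seed", suffixes = c("_a", "_b"))
  m <- m[m$n_a >= min_n & m$n_b >= min_n, , drop = FALSE]
  if (nrow(m) < 3L) stop("fewer than 3 shared seeds; cannot regress")
  fit <- stats::lm(mean_b ~ mean_a, data = m)
  # R^2 from residuals directly (summary.lm warns on perfect fits)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((m$mean_b - mean(m$mean_b))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n_seeds = nrow(m), fit = fit)
}
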