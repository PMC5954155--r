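fake_guides <- function(pos, orientation = "coding", log2fc = 0,
                        strand = "+", gene = NA_character_) {
  n <- length(pos)
  data.frame(guide_id = paste0("f", seq_len(n)),
             spacer = random_dna(n, 20), pam_pos = as.integer(pos),
             strand = rep_len(strand, n), seed5 = substr(random_dna(n, 5), 1, 5),
             target_gene = rep_len(gene, n),
             orientation = rep_len(orientation, n),
             dist_from_start = NA_integer_, dist_from_end = NA_integer_,
             rel_pos = NA_real_, multi_mapping = FALSE,
             stringsAsFactors = FALSE)
}

fake_fitness <- function(guides, log2fc) {
  data.frame(guide_id = guides$guide_id, log2fc = log2fc,
             discarded = FALSE, stringsAsFactors = FALSE)
}

test_that("a zero-variance input yields a single leaf per orientation", {
  set.seed(51)
  g <- rbind(fake_guides(seq(0, 990, 10), "coding"),
             fake_guides(seq(5, 995, 10), "template"))
  ft <- fake_fitness(g, 0)
  tree <- fit_region_tree(ft, g, min_leaf = 5, max_depth = 5)
  expect_equal(nrow(tree$leaves), 2L)
  expect_equal(tree$leaves$pred, c(0, 0))
})

test_that("a planted depleted block is recovered with tight boundaries", {
  set.seed(52)
  pos <- sort(sample(0:49999, 4000))
  y <- ifelse(pos >= 10000 & pos < 12000, -5, 0) + rnorm(4000, 0, 0.2)
  g <- fake_guides(pos, "coding")
  ft <- fake_fitness(g, y)
  tree <- fit_region_tree(ft, g, min_leaf = 10, max_depth = 14)
  lv <- tree$leaves
  bad <- lv[lv$pred < -3.5, ]
  # the strong-defect leaves (the block may be subdivided internally)
  # form one contiguous run covering the planted block
  bad <- bad[order(bad$start), ]
  expect_true(all(utils::head(bad$end, -1) == utils::tail(bad$start, -1)))
  # union boundaries within min_leaf guides of the true block edges
  lo_rank <- sum(pos < min(bad$start))
  hi_rank <- sum(pos < max(bad$end))
  true_lo <- sum(pos < 10000); true_hi <- sum(pos < 12000)
  expect_lte(abs(lo_rank - true_lo), 10)
  expect_lte(abs(hi_rank - true_hi), 10)

  # neutral classification matches the construction >= 95%
  neutral <- classify_neutral_guides(tree, g)
  truth_neutral <- !(pos >= 10000 & pos < 12000)
  expect_gte(mean(neutral == truth_neutral), 0.95)
})

test_that("leaf predictions equal member means", {
  set.seed(53)
  pos <- sort(sample(0:9999, 500))
  y <- rnorm(500, 0, 1) + ifelse(pos < 5000, -2, 0)
  g <- fake_guides(pos, "coding")
  ft <- fake_fitness(g, y)
  tree <- fit_region_tree(ft, g, min_leaf = 20, max_depth = 3)
  pred <- predict_region_tree(tree, g)
  for (i in seq_len(nrow(tree$leaves))) {
    lv <- tree$leaves[i, ]
    sel <- pos > lv$start & pos <= lv$end
    if (lv$start == -Inf) sel <- pos <= lv$end
    expect_equal(unique(round(pred[sel], 10)), round(lv$pred, 10))
    expect_equal(lv$pred, mean(y[sel]))
    expect_equal(lv$n, sum(sel))
  }
})

test_that("splits equal exhaustive variance-minimizing search (depth <= 2)", {
  set.seed(54)
  for (i in 1:20) {
    n <- sample(20:50, 1)
    x <- sort(sample(0:999, n))
    y <- rnorm(n) + ifelse(x > sample(x, 1), rnorm(1, 0, 2), 0)
    g <- fake_guides(x, "coding")
    tree <- fit_region_tree(fake_fitness(g, y), g, min_leaf = 5, max_depth = 1)
    want <- split_oracle(x, y, 5)
    got <- tree$trees$coding$split
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got, want)
    }
  }
})

test_that("the first split agrees with rpart's anova split", {
  set.seed(55)
  x <- sort(sample(0:9999, 300))
  y <- ifelse(x > 4000, -3, 0) + rnorm(300, 0, 0.5)
  g <- fake_guides(x, "coding")
  tree <- fit_region_tree(fake_fitness(g, y), g, min_leaf = 10, max_depth = 1)
  rp <- rpart::rpart(y ~ x, minbucket = 10, minsplit = 20, maxdepth = 1,
                     cp = 0, xval = 0)
  expect_equal(tree$trees$coding$split, unname(rp$splits[1, "index"]))
})

test_that("rolling averages match definition and a brute-force oracle", {
  cst <- rolling_average(seq(0, 90, 10), rep(3, 10), window = 25)
  expect_true(all(cst$mean == 3))
  expect_true(all(cst$sd == 0))

  r <- rolling_average(c(0, 10, 20), c(1, 2, 3), window = 21)
  expect_equal(r$mean[r$position == 10], 2)
  expect_equal(r$n[r$position == 10], 3L)

  set.seed(56)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    pos <- sort(sample(0:500, n))
    v <- rnorm(n)
    w <- sample(5:100, 1)
    got <- rolling_average(pos, v, w)
    for (j in sample(seq_len(n), min(5, n))) {
      cc <- pos[j]
      member <- abs(pos - cc) <= w / 2
      expect_equal(got$mean[got$position == cc], mean(v[member]))
    }
  }
})

test_that("the reverse-polar window test finds a weak planted effect", {
  set.seed(57)
  # one isolated essential gene [1000,2000)+ followed by open space,
  # plus a reference template population centred at 0
  ann <- data.frame(gene = c("ess1", "neu1"),
                    start = c(1000L, 5000L), end = c(2000L, 6000L),
                    strand = "+", essentiality = c("essential", "neutral"),
                    operon = c("op1", "op2"),
                    promoter_start = NA_integer_, promoter_end = NA_integer_)
  near_pos <- sample(2001:2100, 220, replace = TRUE)
  far_pos <- sample(2101:2200, 220, replace = TRUE)
  tmpl_pos <- sample(5000:5999, 400, replace = TRUE)
  g <- rbind(fake_guides(near_pos + 1L, "intergenic", strand = "+"),
             fake_guides(far_pos + 1L, "intergenic", strand = "+"),
             fake_guides(tmpl_pos, "template", strand = "-", gene = "neu1"))
  g$guide_id <- paste0("pg", seq_len(nrow(g)))
  y <- c(rnorm(220, -0.5, 0.5), rnorm(220, 0, 0.5), rnorm(400, 0, 0.5))
  ft <- fake_fitness(g, y)
  res <- polar_effect_test(ft, g, ann)
  expect_equal(isolated_important_genes(ann), "ess1")
  near <- res[res$window == "near", ]
  far <- res[res$window == "far", ]
  expect_gte(near$n, 200)
  expect_lt(near$p, 0.01)
  expect_gt(far$p, 0.05)
})

test_that("the polar t statistic matches the closed form on a toy set", {
  ann <- data.frame(gene = "ess1", start = 100L, end = 200L, strand = "+",
                    essentiality = "essential", operon = "op1",
                    promoter_start = NA_integer_, promoter_end = NA_integer_)
  vals <- c(-0.8, -0.2, -0.5, -0.1, -0.9)
  g <- rbind(fake_guides(210:214, "intergenic", strand = "+"),
             fake_guides(c(150, 160, 170), "template", strand = "-", gene = "ess1"))
  g$guide_id <- paste0("tg", seq_len(nrow(g)))
  ref_vals <- c(0.1, -0.1, 0)
  ft <- fake_fitness(g, c(vals, ref_vals))
  res <- polar_effect_test(ft, g, ann, gene_list = "ess1")
  mu <- mean(ref_vals)
  t_manual <- (mean(vals) - mu) / (sd(vals) / sqrt(length(vals)))
  near <- res[res$window == "near", ]
  expect_equal(near$t, t_manual, tolerance = 1e-12)
  expect_equal(near$n, 5L)
  # degenerate window: identical to reference mean gives t = 0, p = 1
  ft2 <- fake_fitness(g, c(rep(mu, 5) + c(-0.1, 0.1, 0, -0.1, 0.1), ref_vals))
  res2 <- polar_effect_test(ft2, g, ann, gene_list = "ess1")
  expect_equal(res2$t[res2$window == "near"], 0, tolerance = 1e-9)
  # n < 3 in a window reports NA
  expect_true(is.na(res$p[res$window == "far"]))
})
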