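test_that("a toy genome with one NGG indexes a single site", {
  g <- genome_record("AAAATAAAAATTTTCGGTTTTTAAAT")
  idx <- index_genome_seeds(g, k = 6L)
  expect_equal(nrow(idx$sites), 1L)
  expect_equal(idx$sites$strand, "+")
  expect_equal(length(idx$map), 1L)
})

test_that("off-target hits equal a regex-based naive scan on random genomes", {
  set.seed(91)
  for (i in 1:50) {
    g <- random_genome(sample(300:800, 1))
    idx <- index_genome_seeds(g, k = 6L)
    guides <- extract_guides(g, scan_pams(g), quiet = TRUE)
    if (nrow(guides) == 0L) next
    gd <- guides[sample(nrow(guides), min(2, nrow(guides))), , drop = FALSE]
    for (j in seq_len(nrow(gd))) {
      k <- sample(6:9, 1)
      hits <- find_offtargets(gd[j, ], idx, min_k = k)
      want <- offtarget_oracle(g, gd$spacer[j], k,
                               own_pam = gd$pam_pos[j], own_strand = gd$strand[j])
      # the oracle sees matches whose PAM flank leaves the genome; restrict
      want <- want[want$pam_pos %in% idx$sites$pam_pos[idx$sites$avail >= 6], ,
                   drop = FALSE]
      got <- hits[order(hits$pam_pos, hits$strand), c("pam_pos", "strand")]
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want, info = paste("genome", i, "guide", j, "k", k))
    }
  }
})

test_that("match lengths are maximal PAM-proximal extensions", {
  # hand-built: guide seed ACGTACGTA planted with 7 matching bases elsewhere
  spacer <- paste0(strrep("T", 11), "ACGTACGTA")
  site <- paste0(spacer, "AGG")                       # own target
  other <- paste0(strrep("C", 9), "G", "GTACGTA", "TGG")  # 7-nt proximal match
  g <- genome_record(paste0("AAAA", site, "AAAA", other, "AAAA"))
  idx <- index_genome_seeds(g, k = 6L)
  guides <- extract_guides(g, scan_pams(g), quiet = TRUE)
  me <- guides[guides$spacer == spacer, ]
  hits <- find_offtargets(me, idx, min_k = 6L)
  hits <- hits[hits$strand == "+", ]
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$match_len, 7L)
})

test_that("hit sets are nested as k grows", {
  set.seed(92)
  g <- random_genome(2000)
  idx <- index_genome_seeds(g, k = 6L)
  guides <- extract_guides(g, scan_pams(g), quiet = TRUE)
  for (j in sample(nrow(guides), 10)) {
    prev <- NULL
    for (k in 6:12) {
      h <- find_offtargets(guides[j, ], idx, min_k = k)
      key <- paste(h$pam_pos, h$strand)
      if (!is.null(prev)) expect_true(all(key %in% prev))
      prev <- key
    }
  }
})

test_that("k-mer site counts match the uniform-composition expectation", {
  set.seed(93)
  g <- random_genome(2e6)
  idx <- index_genome_seeds(g, k = 5L)
  # NGG sites occur at rate ~1/8 per nt (both strands); 4^5 5-mers
  expected <- 2e6 / 8 / 1024
  observed <- mean(lengths(idx$map))
  expect_gt(observed, expected / 2)
  expect_lt(observed, expected * 2)
})

test_that("importance follows orientation and polarity rules", {
  ann <- data.frame(
    gene = c("essA", "neuB", "neuC", "essD"),
    start = c(100L, 400L, 700L, 1000L), end = c(300L, 600L, 900L, 1200L),
    strand = c("+", "+", "-", "+"),
    essentiality = c("essential", "neutral", "neutral", "essential"),
    operon = c("op1", "op2", "op3", "op2"),
    promoter_start = c(50L, 350L, NA, NA), promoter_end = c(100L, 400L, NA, NA))
  sites <- data.frame(pam_pos = c(150L, 150L, 450L, 450L, 750L, 60L, 370L, 950L),
                      strand = c("+", "-", "+", "-", "-", "-", "+", "+"),
                      prox = strrep("A", 20), avail = 20L)
  imp <- site_importance(sites, ann)
  expect_equal(imp, c(TRUE,   # essA body, coding orientation
                      FALSE,  # essA body, template orientation
                      TRUE,   # neuB body coding: essD downstream in op2 (polarity)
                      FALSE,  # neuB body, template
                      FALSE,  # neuC coding, but neutral with no important downstream
                      TRUE,   # promoter of essA operon, either strand
                      TRUE,   # promoter of op2, which contains essD
                      FALSE)) # intergenic
  # orientation-blind mode drops the strand requirement on gene bodies
  imp_blind <- site_importance(sites, ann, orientation_blind = TRUE)
  expect_equal(imp_blind[2], TRUE)
  expect_equal(imp_blind[4], TRUE)
})

test_that("a planted off-target in an essential promoter is found and flagged", {
  # guide at an intergenic site; its 9 proximal bases + TGG planted inside
  # the promoter of an essential gene
  seed9 <- "ACGTTGCAC"
  guide_site <- paste0(strrep("A", 11), seed9, "TGG")
  planted <- paste0(seed9, "CGG")
  filler1 <- strrep("T", 40)
  genome_seq <- paste0(filler1, guide_site, strrep("T", 30), planted,
                       strrep("T", 60))
  g <- genome_record(genome_seq)
  prom_start <- 40L + 34L + 30L - 3L
  ann <- data.frame(gene = "essX",
                    start = prom_start + 20L, end = prom_start + 60L,
                    strand = "+", essentiality = "essential", operon = "opX",
                    promoter_start = prom_start, promoter_end = prom_start + 20L)
  idx <- index_genome_seeds(g, k = 6L)
  guides <- extract_guides(g, scan_pams(g), quiet = TRUE)
  me <- guides[guides$seed5 == substr(seed9, 5, 9) & guides$strand == "+", ]
  me <- me[1, ]
  imp <- site_importance(idx$sites, ann)
  hits <- find_offtargets(me, idx, min_k = 9L, importance = imp)
  expect_equal(nrow(hits), 1L)
  expect_true(hits$in_important_region)
  expect_gte(hits$match_len, 9L)
})

test_that("detection curves separate planted defect guides from controls", {
  # covered end-to-end in the acceptance suite; here: degenerate identity
  sim <- tiny_sim()
  ft <- tiny_fitness()
  sets <- defect_sets(ft, sim$guides, sim$annotation)
  idx <- index_genome_seeds(sim$genome, k = 6L)
  same <- detection_rate_curve(sets$defect, sets$defect, idx, sim$annotation)
  expect_true(all(same$curve$difference == 0))
  # rates are monotonically non-increasing in k
  curve <- detection_rate_curve(sets$defect, sets$no_defect, idx,
                                sim$annotation)$curve
  expect_true(all(diff(curve$positive_rate) <= 0))
  expect_true(all(diff(curve$false_positive_rate) <= 0))
  expect_error(detection_rate_curve(sets$defect[0, ], sets$no_defect, idx,
                                    sim$annotation), "non-empty")
})

test_that("the Fisher table counts hits correctly", {
  d <- c(9, 9, 10, 3, 0)
  nd <- c(0, 0, 10, 9, 2, 0, 0)
  ht <- offtarget_fisher_test(d, nd, k = 9)
  # defect: 3 of 5 with >= 9; no-defect: 2 of 7
  expect_equal(unname(ht$estimate) > 1, TRUE)
  tab <- matrix(c(3, 2, 2, 5), 2, byrow = TRUE)
  expect_equal(ht$p.value, fisher.test(tab)$p.value)
})
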