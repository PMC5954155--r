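test_that("genome and annotation loading validates its inputs", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">g", "ACGT"), fa)
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tstart\tend\tstrand\tessentiality\toperon\tpromoter",
               "gA\t0\t4\t+\tneutral\topA\t."), tsv)
  gl <- load_genome(fa, tsv)
  expect_equal(nchar(gl$genome$sequence), 4L)
  expect_equal(nrow(gl$annotation), 1L)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tstart\tend\tstrand\tessentiality\toperon\tpromoter",
               "gA\t0\t9\t+\tneutral\topA\t."), bad)
  expect_error(load_genome(fa, bad), "beyond genome length")

  fan <- tempfile(fileext = ".fa")
  writeLines(c(">g", "ACGN"), fan)
  expect_error(read_genome(fan), "non-ACGT")

  ess <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tstart\tend\tstrand\tessentiality\toperon\tpromoter",
               "gA\t0\t4\t+\tmaybe\topA\t."), ess)
  expect_error(read_annotation(ess), "essentiality")
})

test_that("GFF3 parsing converts coordinates and requires essentiality", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "g\tx\tgene\t11\t40\t.\t+\t.\tID=gY;essentiality=essential;operon=op1;promoter=0-10",
               "g\tx\tgene\t51\t90\t.\t-\t.\tID=gZ;essentiality=neutral;operon=op2"), gff)
  ann <- read_annotation(gff)
  expect_equal(ann$start, c(10L, 50L))   # 1-based closed -> 0-based half-open
  expect_equal(ann$end, c(40L, 90L))
  expect_equal(ann$promoter_start[1], 0L)

  gff_bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "g\tx\tgene\t1\t4\t.\t+\t.\tID=gX;operon=op1"), gff_bad)
  expect_error(read_annotation(gff_bad), "gX")
})

test_that("scan_pams handles boundary cases", {
  expect_equal(nrow(scan_pams(genome_record("AAAAAA"))), 0L)
  p <- scan_pams(genome_record("ACGGTT"))
  expect_equal(nrow(p), 1L)
  expect_equal(p$pam_pos, 1L)       # "CGG", N at 0-based position 1
  expect_equal(p$strand, "+")
})

test_that("scan_pams matches a brute-force regex oracle on random genomes", {
  set.seed(101)
  for (i in 1:100) {
    len <- sample(50:5000, 1)
    circ <- i %% 2 == 0
    g <- random_genome(len, circular = circ)
    got <- scan_pams(g)
    want <- pam_oracle(g$sequence, circular = circ)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = sprintf("len=%d circular=%s", len, circ))
  }
})

test_that("reverse-complementing a linear genome mirrors the PAM set", {
  set.seed(11)
  g <- random_genome(800)
  L <- nchar(g$sequence)
  p1 <- scan_pams(g)
  p2 <- scan_pams(genome_record(revcomp(g$sequence)))
  # site (q, +) maps to (L-1-q, -) and vice versa
  mirrored <- data.frame(pam_pos = L - 1L - p1$pam_pos,
                         strand = ifelse(p1$strand == "+", "-", "+"))
  mirrored <- mirrored[order(mirrored$pam_pos, mirrored$strand), ]
  rownames(mirrored) <- rownames(p2) <- NULL
  expect_equal(p2, mirrored)
})

test_that("extract_guides takes the 20 nt 5' of the PAM and the seed is PAM-proximal", {
  # exact flank: 23-nt genome, PAM occupies [20,23)
  spacer <- "TGAGACCAGTCTAGGTCTCG"
  g <- genome_record(paste0(spacer, "TGG"))
  sites <- data.frame(pam_pos = 20L, strand = "+")
  gd <- extract_guides(g, sites)
  expect_equal(gd$spacer, spacer)
  expect_equal(gd$seed5, "TCTCG")

  # insufficient flank on a linear genome is skipped with a message
  expect_message(
    out <- extract_guides(g, data.frame(pam_pos = 5L, strand = "+")),
    "skipped")
  expect_equal(nrow(out), 0L)

  # minus-strand extraction: plant a known protospacer on the minus strand
  sp <- "ACGTACGTACGTACGTACGT"
  gseq <- paste0("CCT", revcomp(sp), "AAAA")   # CC then N at 0-based 2
  gm <- genome_record(gseq)
  gdm <- extract_guides(gm, data.frame(pam_pos = 2L, strand = "-"))
  expect_equal(gdm$spacer, sp)
})

test_that("extracted spacers re-locate exactly in the genome", {
  set.seed(12)
  g <- random_genome(3000)
  guides <- extract_guides(g, scan_pams(g), quiet = TRUE)
  idx <- sample(nrow(guides), 40)
  for (i in idx) {
    q <- guides$pam_pos[i]
    if (guides$strand[i] == "+") {
      expect_equal(substr(g$sequence, q - 19L, q), guides$spacer[i])
      expect_equal(substr(g$sequence, q + 2L, q + 3L), "GG")
    } else {
      expect_equal(revcomp(substr(g$sequence, q + 2L, q + 21L)), guides$spacer[i])
      expect_equal(substr(g$sequence, q - 1L, q), "CC")
    }
  }
})

test_that("annotate_guides assigns orientation per convention on a hand-built locus", {
  # layout: promoter [0,20) of geneA [20,120)+; geneB [150,250)-; rest intergenic
  ann <- data.frame(gene = c("geneA", "geneB"),
                    start = c(20L, 150L), end = c(120L, 250L),
                    strand = c("+", "-"),
                    essentiality = c("essential", "neutral"),
                    operon = c("op1", "op2"),
                    promoter_start = c(0L, NA), promoter_end = c(20L, NA))
  guides <- data.frame(
    guide_id = paste0("t", 1:6),
    spacer = c(strrep("A", 20), strrep("C", 20), strrep("G", 20),
               strrep("T", 20), paste0(strrep("A", 15), "CCCCC"),
               paste0(strrep("A", 15), "GGGGG")),
    pam_pos = c(50L, 60L, 200L, 210L, 10L, 300L),
    strand = c("+", "-", "-", "+", "+", "-"),
    seed5 = strrep("A", 5), stringsAsFactors = FALSE)
  out <- annotate_guides(guides, ann)
  expect_equal(out$orientation,
               c("coding", "template",   # geneA +: same strand = coding
                 "coding", "template",   # geneB -: minus-strand guide = coding
                 "promoter", "intergenic"))
  expect_equal(out$target_gene[1:5], c("geneA", "geneA", "geneB", "geneB", "geneA"))
  # distances from the PAM-proximal spacer base (pos-1 for +, pos+1 for -)
  expect_equal(out$dist_from_start[1], 49L - 20L)
  expect_equal(out$dist_from_end[1], 119L - 49L)
  expect_equal(out$dist_from_start[3], 249L - 201L)
  expect_false(any(out$multi_mapping[3:6]))
})

test_that("duplicated spacers are flagged multi-mapping", {
  guides <- data.frame(guide_id = c("a", "b", "c"),
                       spacer = c(strrep("A", 20), strrep("A", 20), strrep("C", 20)),
                       pam_pos = c(30L, 70L, 110L), strand = "+",
                       seed5 = strrep("A", 5), stringsAsFactors = FALSE)
  ann <- data.frame(gene = character(0), start = integer(0), end = integer(0),
                    strand = character(0), essentiality = character(0),
                    operon = character(0), promoter_start = integer(0),
                    promoter_end = integer(0))
  out <- annotate_guides(guides, ann)
  expect_equal(out$multi_mapping, c(TRUE, TRUE, FALSE))
})
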