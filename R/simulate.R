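#' Configuration for a synthetic CRISPRi screen
#'
#' Defaults emulate a desk-scale version of a genome-wide bacterial dCas9
#' knockdown screen: a 50 kb random genome organised in operons, a library
#' of guides at every NGG site, strand-dependent depletion in essential and
#' fitness genes, operon polar effects, a weak short-range reverse-polar
#' effect, planted seed-match off-targets, 5-mer seed toxicity scaled by
#' dCas9 level, and negative-binomial sequencing counts over a 17-generation
#' growth competition (effects are expressed directly on the end-vs-start
#' log2 scale).
#'
#' @param genome_length genome size in nt.
#' @param n_genes number of genes to place (in operons).
#' @param operon_size_probs probabilities of operon sizes 1..k.
#' @param gene_length_range uniform range of gene lengths, nt.
#' @param promoter_len promoter interval length, nt.
#' @param intra_operon_gap gap between genes within an operon, nt.
#' @param inter_operon_gap_range uniform range of intergenic gaps, nt.
#' @param frac_essential,frac_fitness per-gene class probabilities
#'   (remainder neutral).
#' @param library_size target library size; `NULL` keeps every extractable
#'   PAM site (planted sites and the control guide are always kept).
#' @param dcas9_level relative dCas9 concentration; 1.0 is the reference
#'   high-expression strain, ~0.4 a strain expressing ~2.6-fold less. The
#'   bad-seed effect scales linearly with this level.
#' @param n_bad_seeds number of toxic 5-mer seeds to plant.
#' @param guides_per_bad_seed planted guides per toxic seed.
#' @param bad_seed_tau_mean,bad_seed_tau_sd toxicity magnitude is drawn as
#'   `-max(3, abs(rnorm(mean, sd)))` log2FC units.
#' @param offtarget_k seed-identity length of planted off-targets, nt.
#' @param n_offtarget_guides number of guides given a planted off-target in
#'   an important region.
#' @param offtarget_effect log2FC effect of a planted off-target.
#' @param offtarget_dose_exponent off-target effects scale as
#'   `dcas9_level^exponent`: attenuated at low dCas9 like the bad-seed
#'   effect, but less strongly (exponent < 1).
#' @param on_target_essential,on_target_fitness log2FC of silencing an
#'   essential / fitness gene.
#' @param weak_polar_effect log2FC of the reverse-polar effect applied to
#'   coding-strand guides 0-100 nt past the end of an essential/fitness gene.
#' @param weak_polar_range nt window after the gene end where the
#'   reverse-polar effect applies.
#' @param generations growth duration (metadata; effects are end-vs-start).
#' @param replicates number of replicates.
#' @param depth_per_guide mean sequencing reads per guide per sample.
#' @param nb_dispersion negative-binomial dispersion (0 gives Poisson).
#' @param control_spacer spacer of the neutral control guide planted in an
#'   intergenic site and used to anchor fold changes.
#' @param rng_seed integer seed; the whole simulation is deterministic
#'   given it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 50000L,
                       n_genes = 40L,
                       operon_size_probs = c(0.45, 0.30, 0.15, 0.10),
                       gene_length_range = c(600L, 1000L),
                       promoter_len = 60L,
                       intra_operon_gap = 20L,
                       inter_operon_gap_range = c(150L, 600L),
                       frac_essential = 0.25,
                       frac_fitness = 0.15,
                       library_size = NULL,
                       dcas9_level = 1.0,
                       n_bad_seeds = 20L,
                       guides_per_bad_seed = 40L,
                       bad_seed_tau_mean = 4,
                       bad_seed_tau_sd = 1,
                       offtarget_k = 9L,
                       n_offtarget_guides = 60L,
                       offtarget_effect = -8,
                       offtarget_dose_exponent = 0.5,
                       on_target_essential = -8,
                       on_target_fitness = -4,
                       weak_polar_effect = -0.5,
                       weak_polar_range = c(0L, 100L),
                       generations = 17L,
                       replicates = 3L,
                       depth_per_guide = 500,
                       nb_dispersion = 0.05,
                       control_spacer = "TGAGACCAGTCTAGGTCTCG",
                       rng_seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$genome_length > 0, cfg$n_genes >= 0,
            cfg$frac_essential >= 0, cfg$frac_fitness >= 0,
            cfg$frac_essential + cfg$frac_fitness <= 1,
            cfg$generations > 0, cfg$replicates >= 1,
            cfg$depth_per_guide > 0, cfg$nb_dispersion >= 0,
            cfg$dcas9_level >= 0, nchar(cfg$control_spacer) == 20L)
  class(cfg) <- "sim_config"
  cfg
}

gene_effect_value <- function(essentiality, config) {
  ifelse(essentiality == "essential", config$on_target_essential,
         ifelse(essentiality == "fitness", config$on_target_fitness, 0))
}

#' Generate a synthetic genome with planted screen structure
#'
#' Builds an i.i.d.-uniform ACGT genome, places non-overlapping operons of
#' genes with promoters and assigns essentiality classes, then plants:
#' toxic-seed guide sites in neutral intergenic zones (each planted seed is
#' written immediately 5' of a created NGG PAM), the control guide, and
#' seed-match off-targets — for a subset of template-strand guides in
#' neutral genes, the guide's `offtarget_k` PAM-proximal bases plus an NGG
#' are copied into an essential/fitness gene body in coding orientation,
#' with the (k+1)-th base forced to mismatch so the planted identity is
#' exactly k.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (a `genome_record`), `annotation`, and
#'   `planted` (bad-seed taus and sites, control site, off-target pairs).
#' @export
generate_genome <- function(config) {
  set.seed(config$rng_seed)
  L <- config$genome_length
  ch <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  ann <- place_operons(config, L)
  if (config$n_genes > 0 && nrow(ann) < config$n_genes)
    stop("genome too short to place ", config$n_genes, " genes")

  claimed <- rep(FALSE, L)     # edited windows that must not be re-edited
  avail <- neutral_zone_mask(ann, config, L)

  ## --- plant bad seeds -------------------------------------------------
  seeds_pool <- setdiff(all_kmers(5L), substr(config$control_spacer, 16L, 20L))
  bad_seeds <- if (config$n_bad_seeds > 0) sample(seeds_pool, config$n_bad_seeds) else character(0)
  tau <- -pmax(3, abs(stats::rnorm(length(bad_seeds), config$bad_seed_tau_mean,
                                   config$bad_seed_tau_sd)))
  bs_sites <- NULL
  if (length(bad_seeds) > 0) {
    n_sites <- length(bad_seeds) * config$guides_per_bad_seed
    cand <- which(avail)
    cand <- cand[cand > 30L & cand < L - 30L]
    cand <- sample(cand)  # genome positions, 1-based index into ch
    got <- 0L; ptr <- 1L
    site_pos <- integer(n_sites); site_strand <- character(n_sites)
    while (got < n_sites && ptr <= length(cand)) {
      q <- cand[ptr] - 1L   # candidate pam_pos, 0-based
      ptr <- ptr + 1L
      strand <- sample(c("+", "-"), 1L)
      win <- if (strand == "+") (q - 5L):(q + 2L) else (q - 2L):(q + 5L)
      if (any(claimed[win + 1L]) || !all(avail[win + 1L])) next
      got <- got + 1L
      site_pos[got] <- q; site_strand[got] <- strand
      claimed[win + 1L] <- TRUE
    }
    if (got < n_sites)
      stop("could not place ", n_sites, " bad-seed guide sites; genome too crowded")
    seed_of_site <- rep(bad_seeds, each = config$guides_per_bad_seed)
    for (i in seq_len(n_sites)) {
      q <- site_pos[i]; s <- seed_of_site[i]
      if (site_strand[i] == "+") {
        ch[(q - 5L):(q - 1L) + 1L] <- strsplit(s, "")[[1]]
        ch[c(q + 1L, q + 2L) + 1L] <- "G"
      } else {
        # the 5 forward bases 3' of the PAM are the revcomp of the seed
        ch[(q + 1L):(q + 5L) + 1L] <- strsplit(revcomp(s), "")[[1]]
        ch[c(q - 2L, q - 1L) + 1L] <- "C"
      }
    }
    bs_sites <- data.frame(pam_pos = site_pos, strand = site_strand,
                           seed = seed_of_site, stringsAsFactors = FALSE)
  }

  ## --- plant the control guide ----------------------------------------
  cand <- which(avail & !claimed)
  cand <- cand[cand > 30L & cand < L - 30L]
  ctrl_pam <- NA_integer_
  for (p in sample(cand)) {
    q <- p - 1L
    win <- (q - 20L):(q + 2L)
    if (all(win >= 0L) && all(win < L) && !any(claimed[win + 1L]) && all(avail[win + 1L])) {
      ch[(q - 20L):(q - 1L) + 1L] <- strsplit(config$control_spacer, "")[[1]]
      ch[c(q + 1L, q + 2L) + 1L] <- "G"
      claimed[win + 1L] <- TRUE
      ctrl_pam <- q
      break
    }
  }
  if (is.na(ctrl_pam)) stop("could not place the control guide")

  ## --- plant off-targets ----------------------------------------------
  genome <- genome_record(paste(ch, collapse = ""), id = "sim_genome")
  offt <- NULL
  if (config$n_offtarget_guides > 0 && nrow(ann) > 0) {
    donors <- pick_offtarget_donors(genome, ann, bad_seeds, claimed, config)
    important <- ann[ann$essentiality %in% c("essential", "fitness"), , drop = FALSE]
    if (nrow(donors) > 0 && nrow(important) > 0) {
      # claim donor seed+PAM windows so later edits cannot touch them
      for (i in seq_len(nrow(donors))) {
        q <- donors$pam_pos[i]
        win <- if (donors$strand[i] == "+") (q - 10L):(q + 2L) else (q - 2L):(q + 10L)
        claimed[win + 1L] <- TRUE
      }
      placed <- place_offtarget_sites(donors, important, ch, claimed,
                                      config$offtarget_k)
      ch <- placed$ch; claimed <- placed$claimed
      offt <- placed$pairs
      genome <- genome_record(paste(ch, collapse = ""), id = "sim_genome")
    }
  }

  list(genome = genome, annotation = ann,
       planted = list(
         bad_seeds = data.frame(seed = bad_seeds, tau = tau, stringsAsFactors = FALSE),
         bad_seed_sites = bs_sites,
         control_pam_pos = ctrl_pam, control_strand = "+",
         offtargets = offt))
}

place_operons <- function(config, L) {
  if (config$n_genes == 0)
    return(data.frame(gene = character(0), start = integer(0), end = integer(0),
                      strand = character(0), essentiality = character(0),
                      operon = character(0), promoter_start = integer(0),
                      promoter_end = integer(0), stringsAsFactors = FALSE))
  rows <- list()
  pos <- as.integer(stats::runif(1, 100, 300))
  gi <- 0L; oi <- 0L
  while (gi < config$n_genes) {
    oi <- oi + 1L
    size <- sample(seq_along(config$operon_size_probs), 1L,
                   prob = config$operon_size_probs)
    size <- min(size, config$n_genes - gi)
    strand <- sample(c("+", "-"), 1L)
    lens <- as.integer(stats::runif(size, config$gene_length_range[1],
                                    config$gene_length_range[2]))
    block_len <- config$promoter_len + sum(lens) + (size - 1L) * config$intra_operon_gap
    if (pos + block_len > L - 100L) break
    op_id <- sprintf("op%03d", oi)
    # lay out in genome order; for '-' operons transcription runs right-to-left
    gene_order <- if (strand == "+") seq_len(size) else rev(seq_len(size))
    cur <- pos
    prom <- c(NA_integer_, NA_integer_)
    if (strand == "+") {
      prom <- c(cur, cur + config$promoter_len); cur <- cur + config$promoter_len
    }
    starts <- integer(size); ends <- integer(size)
    for (j in seq_len(size)) {
      idx <- gene_order[j]
      starts[idx] <- cur; ends[idx] <- cur + lens[idx]
      cur <- ends[idx] + if (j < size) config$intra_operon_gap else 0L
    }
    if (strand == "-") prom <- c(cur, cur + config$promoter_len)
    # promoter belongs to the transcription-first gene
    first_gene <- 1L
    for (j in seq_len(size)) {
      gi <- gi + 1L
      rows[[gi]] <- data.frame(
        gene = sprintf("gene%03d", gi), start = starts[j], end = ends[j],
        strand = strand,
        essentiality = sample(ESSENTIALITY_LEVELS, 1L,
                              prob = c(config$frac_essential, config$frac_fitness,
                                       1 - config$frac_essential - config$frac_fitness)),
        operon = op_id,
        promoter_start = if (j == first_gene) prom[1] else NA_integer_,
        promoter_end = if (j == first_gene) prom[2] else NA_integer_,
        stringsAsFactors = FALSE)
    }
    pos <- cur + if (strand == "-") config$promoter_len else 0L
    pos <- pos + as.integer(stats::runif(1, config$inter_operon_gap_range[1],
                                         config$inter_operon_gap_range[2]))
  }
  ann <- do.call(rbind, rows)
  validate_annotation(ann, L)
}

# positions (1-based mask) outside gene bodies, promoters, and the
# 0-200 nt window downstream of essential/fitness gene ends
neutral_zone_mask <- function(ann, config, L) {
  avail <- rep(TRUE, L)
  for (i in seq_len(nrow(ann))) {
    avail[(ann$start[i] + 1L):ann$end[i]] <- FALSE
    if (!is.na(ann$promoter_start[i]))
      avail[(ann$promoter_start[i] + 1L):ann$promoter_end[i]] <- FALSE
    if (ann$essentiality[i] %in% c("essential", "fitness")) {
      if (ann$strand[i] == "+") {
        w <- ann$end[i]:min(L - 1L, ann$end[i] + 200L)
      } else {
        w <- max(0L, ann$start[i] - 201L):(ann$start[i] - 1L)
      }
      avail[w + 1L] <- FALSE
    }
  }
  avail
}

all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE)[, k:1, drop = FALSE])
}

# Donor guides for planted off-targets: template-strand guides in neutral
# gene bodies, unedited so far, not carrying a planted bad seed.
pick_offtarget_donors <- function(genome, ann, bad_seeds, claimed, config) {
  L <- nchar(genome$sequence)
  sites <- scan_pams(genome)
  ok_flank <- ifelse(sites$strand == "+", sites$pam_pos >= 20L,
                     sites$pam_pos + 21L <= L)
  sites <- sites[ok_flank, , drop = FALSE]
  guides <- extract_guides(genome, sites, quiet = TRUE)
  neutral <- ann[ann$essentiality == "neutral", , drop = FALSE]
  keep <- logical(nrow(guides))
  for (i in seq_len(nrow(guides))) {
    p <- guides$pam_pos[i]
    hit <- which(neutral$start <= p & p < neutral$end)
    if (length(hit) == 0L) next
    if (guides$strand[i] == neutral$strand[hit[1L]]) next   # want template
    q <- guides$pam_pos[i]
    win <- if (guides$strand[i] == "+") (q - 10L):(q + 2L) else (q - 2L):(q + 10L)
    if (any(win < 0L) || any(win >= L) || any(claimed[win + 1L])) next
    if (guides$seed5[i] %in% bad_seeds) next
    keep[i] <- TRUE
  }
  cand <- guides[keep, , drop = FALSE]
  n <- min(config$n_offtarget_guides, nrow(cand))
  if (n < config$n_offtarget_guides)
    warning("only ", n, " off-target donor guides available")
  cand[sample(nrow(cand), n), , drop = FALSE]
}

# Copy each donor's k PAM-proximal spacer bases (+NGG, mismatch at k+1)
# into an essential/fitness gene body in coding orientation.
place_offtarget_sites <- function(donors, important, ch, claimed, k) {
  bases <- c("A", "C", "G", "T")
  pairs <- list()
  for (i in seq_len(nrow(donors))) {
    spc <- strsplit(donors$spacer[i], "")[[1]]   # spc[20] is PAM-proximal
    match_chars <- spc[(21L - k):20L]            # k proximal bases, distal->proximal
    mm_ref <- spc[20L - k]                       # the (k+1)-th proximal base
    mm <- sample(setdiff(bases, mm_ref), 1L)
    placed <- FALSE
    for (try in seq_len(300L)) {
      g <- important[sample(nrow(important), 1L,
                            prob = important$end - important$start), , drop = FALSE]
      strand <- g$strand
      if (strand == "+") {
        lo <- g$start + k + 1L; hi <- g$end - 3L
        if (hi < lo) next
        q <- sample(lo:hi, 1L)
        win <- (q - k - 1L):(q + 2L)
        if (any(claimed[win + 1L])) next
        # spacer char j sits at forward position q - 21 + j
        ch[(q - k):(q - 1L) + 1L] <- match_chars
        ch[q - k - 1L + 1L] <- mm
        ch[c(q + 1L, q + 2L) + 1L] <- "G"
      } else {
        lo <- g$start + 2L; hi <- g$end - k - 2L
        if (hi < lo) next
        q <- sample(lo:hi, 1L)
        win <- (q - 2L):(q + k + 1L)
        if (any(claimed[win + 1L])) next
        # spacer char j sits at forward position q + 21 - j, complemented
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        ch[(q + 1L):(q + k) + 1L] <- comp[rev(match_chars)]
        ch[q + k + 1L + 1L] <- comp[[mm]]
        ch[c(q - 2L, q - 1L) + 1L] <- "C"
      }
      claimed[win + 1L] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        donor_pam_pos = donors$pam_pos[i], donor_strand = donors$strand[i],
        site_pam_pos = q, site_strand = strand, gene = g$gene,
        stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) warning("could not place off-target for donor ", donors$guide_id[i])
  }
  list(ch = ch, claimed = claimed, pairs = do.call(rbind, pairs))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$genome_length, "nt genome,", x$n_genes, "genes,",
      x$n_bad_seeds, "bad seeds, dcas9_level", x$dcas9_level, "\n")
  invisible(x)
}

#' Planted per-guide fitness decomposition
#'
#' Computes, for every guide, the planted effect components on the
#' end-vs-start log2 abundance scale:
#' \itemize{
#'   \item on-target: coding-strand guides in essential/fitness genes get the
#'     gene's silencing effect; promoter guides (either orientation) get the
#'     strongest effect in the operon the promoter drives;
#'   \item polar: coding-strand guides also silence every gene downstream in
#'     the same operon; a weak reverse-polar effect applies to guides on the
#'     coding strand 0-100 nt past the end of an essential/fitness gene;
#'   \item off-target: planted seed-match off-targets in important regions;
#'   \item bad seed: guides whose 5 PAM-proximal bases equal a planted toxic
#'     seed get tau_s scaled linearly by the dCas9 level.
#' }
#' `effect_total` is the sum of the four components.
#'
#' @param guides annotated guide table ([annotate_guides()]).
#' @param annotation gene annotation.
#' @param planted the `planted` element of [generate_genome()] output.
#' @param config the [sim_config()].
#' @return data.frame with one row per guide: `guide_id`, the four effect
#'   components and `effect_total`.
#' @export
simulate_true_fitness <- function(guides, annotation, planted, config) {
  n <- nrow(guides)
  eff_on <- numeric(n); eff_polar <- numeric(n)
  eff_off <- numeric(n); eff_bad <- numeric(n)

  gval <- gene_effect_value(annotation$essentiality, config)
  names(gval) <- annotation$gene

  # transcription order within operons
  operon_members <- split(seq_len(nrow(annotation)), annotation$operon)

  operon_downstream_min <- function(gene) {
    i <- match(gene, annotation$gene)
    mem <- operon_members[[annotation$operon[i]]]
    if (annotation$strand[i] == "+") {
      ds <- mem[annotation$start[mem] > annotation$start[i]]
    } else {
      ds <- mem[annotation$start[mem] < annotation$start[i]]
    }
    if (length(ds) == 0L) 0 else min(gval[annotation$gene[ds]], 0)
  }
  operon_min <- function(gene) {
    i <- match(gene, annotation$gene)
    mem <- operon_members[[annotation$operon[i]]]
    min(gval[annotation$gene[mem]], 0)
  }

  loc <- ifelse(guides$strand == "+", guides$pam_pos - 1L, guides$pam_pos + 1L)
  imp <- annotation[annotation$essentiality %in% c("essential", "fitness"), , drop = FALSE]

  for (i in seq_len(n)) {
    ori <- guides$orientation[i]
    if (ori == "coding") {
      eff_on[i] <- gval[[guides$target_gene[i]]]
      eff_polar[i] <- operon_downstream_min(guides$target_gene[i])
    } else if (ori == "promoter") {
      eff_on[i] <- operon_min(guides$target_gene[i])
    }
    # reverse-polar: coding strand, 0-100 nt past an essential/fitness gene end
    if (nrow(imp) > 0) {
      same <- imp$strand == guides$strand[i]
      if (any(same)) {
        d <- ifelse(imp$strand[same] == "+",
                    loc[i] - (imp$end[same] - 1L),
                    imp$start[same] - loc[i])
        if (any(d > config$weak_polar_range[1] & d <= config$weak_polar_range[2]))
          eff_polar[i] <- eff_polar[i] + config$weak_polar_effect
      }
    }
  }

  if (!is.null(planted$offtargets) && nrow(planted$offtargets) > 0) {
    key <- paste(guides$pam_pos, guides$strand)
    donor_key <- paste(planted$offtargets$donor_pam_pos,
                       planted$offtargets$donor_strand)
    eff_off[key %in% donor_key] <- config$offtarget_effect *
      config$dcas9_level^config$offtarget_dose_exponent
  }

  if (nrow(planted$bad_seeds) > 0) {
    idx <- match(guides$seed5, planted$bad_seeds$seed)
    hit <- !is.na(idx)
    eff_bad[hit] <- planted$bad_seeds$tau[idx[hit]] * config$dcas9_level
  }

  data.frame(guide_id = guides$guide_id,
             effect_on_target = eff_on, effect_polar = eff_polar,
             effect_offtarget = eff_off, effect_badseed = eff_bad,
             effect_total = eff_on + eff_polar + eff_off + eff_bad,
             stringsAsFactors = FALSE)
}

#' Build a count table container
#'
#' @param counts integer matrix, guides x samples; rownames are guide ids.
#' @param samples data.frame with `sample`, `replicate`, `timepoint`
#'   (`start`/`end`) matching the columns of `counts`.
#' @return a `count_table`.
#' @export
count_table <- function(counts, samples) {
  stopifnot(ncol(counts) == nrow(samples),
            all(samples$timepoint %in% c("start", "end")),
            !is.null(rownames(counts)), !anyDuplicated(rownames(counts)))
  reps <- split(samples$timepoint, samples$replicate)
  if (!all(vapply(reps, function(tp) all(c("start", "end") %in% tp), logical(1))))
    stop("every replicate needs both a start and an end sample")
  structure(list(counts = counts, samples = samples), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d guides x %d samples (%d replicates)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$samples$replicate))))
  invisible(x)
}

#' Simulate sequencing counts for a screen
#'
#' Start abundances are Dirichlet-uniform; end abundances are proportional
#' to start x 2^effect_total (renormalised, as in a competitive pool).
#' Counts are negative-binomial around depth-scaled abundances,
#' independently per replicate and timepoint.
#'
#' @param truth output of [simulate_true_fitness()].
#' @param config the [sim_config()].
#' @param control_id optional guide id of the control guide; the control
#'   is a designed spike-in, so it enters at exactly average abundance
#'   instead of a random clone share (anchoring then does not inherit
#'   clone-sampling noise).
#' @return a [count_table()].
#' @export
simulate_counts <- function(truth, config, control_id = NULL) {
  n <- nrow(truth)
  depth <- config$depth_per_guide * n
  share_start <- stats::rgamma(n, 1, 1)
  if (!is.null(control_id)) {
    i <- match(control_id, truth$guide_id)
    if (!is.na(i)) share_start[i] <- 1
  }
  share_start <- share_start / sum(share_start)
  w_end <- share_start * 2^truth$effect_total
  share_end <- w_end / sum(w_end)

  draw <- function(mu) {
    if (config$nb_dispersion <= 0) stats::rpois(n, mu)
    else stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
  }
  R <- config$replicates
  cols <- list(); info <- list()
  for (r in seq_len(R)) {
    cols[[paste0("start_", r)]] <- draw(share_start * depth)
    cols[[paste0("end_", r)]] <- draw(share_end * depth)
    info[[r]] <- data.frame(sample = paste0(c("start_", "end_"), r),
                            replicate = r, timepoint = c("start", "end"),
                            stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- truth$guide_id
  count_table(counts, do.call(rbind, info))
}

#' Run the full screen simulation
#'
#' Generates the genome with planted structure, extracts and annotates the
#' guide library, computes the ground-truth effect ledger and draws read
#' counts. Everything is deterministic given `config$rng_seed`.
#'
#' @param config a [sim_config()].
#' @return list with `config, genome, annotation, guides, truth, counts,
#'   planted`. The control guide id is in `control_guide`.
#' @export
simulate_screen <- function(config = sim_config()) {
  gen <- generate_genome(config)
  sites <- scan_pams(gen$genome)
  guides <- extract_guides(gen$genome, sites, quiet = TRUE)
  guides <- annotate_guides(guides, gen$annotation)

  keep_key <- paste(c(gen$planted$bad_seed_sites$pam_pos,
                      gen$planted$control_pam_pos,
                      gen$planted$offtargets$donor_pam_pos),
                    c(gen$planted$bad_seed_sites$strand,
                      gen$planted$control_strand,
                      gen$planted$offtargets$donor_strand))
  key <- paste(guides$pam_pos, guides$strand)
  if (!is.null(config$library_size) && config$library_size < nrow(guides)) {
    must <- key %in% keep_key
    free <- which(!must)
    n_extra <- max(0L, config$library_size - sum(must))
    keep <- sort(c(which(must), sample(free, min(n_extra, length(free)))))
    guides <- guides[keep, , drop = FALSE]
    key <- key[keep]
  }

  truth <- simulate_true_fitness(guides, gen$annotation, gen$planted, config)
  # screens of the same library (same rng_seed) at different dCas9 levels
  # are independent experiments: decorrelate their sequencing noise
  set.seed((config$rng_seed + 7919L * as.integer(round(1000 * config$dcas9_level))) %% .Machine$integer.max)
  control_guide <- guides$guide_id[match(paste(gen$planted$control_pam_pos,
                                               gen$planted$control_strand), key)]
  counts <- simulate_counts(truth, config, control_id = control_guide)
  list(config = config, genome = gen$genome, annotation = gen$annotation,
       guides = guides, truth = truth, counts = counts,
       planted = gen$planted, control_guide = control_guide)
}

#' Write a simulated screen to a run directory
#'
#' Emits genome FASTA, annotation TSV, guides TSV, counts TSV, the truth
#' ledger JSON and the echoed config JSON.
#'
#' @param sim output of [simulate_screen()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ss <- Biostrings::DNAStringSet(sim$genome$sequence)
  names(ss) <- sim$genome$id
  Biostrings::writeXStringSet(ss, file.path(dir, "genome.fasta"))
  ann <- sim$annotation
  ann$promoter <- ifelse(is.na(ann$promoter_start), ".",
                         paste0(ann$promoter_start, "-", ann$promoter_end))
  utils::write.table(ann[, c("gene", "start", "end", "strand", "essentiality",
                             "operon", "promoter")],
                     file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_guides_tsv(sim$guides, file.path(dir, "guides.tsv"))
  cnt <- data.frame(guide_id = rownames(sim$counts$counts), sim$counts$counts,
                    stringsAsFactors = FALSE)
  utils::write.table(cnt, file.path(dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"), digits = NA)
  jsonlite::write_json(sim$planted, file.path(dir, "planted.json"),
                       digits = NA, auto_unbox = TRUE)
  cfg <- sim$config; class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a count table written by [write_simulation()]
#'
#' Expects a TSV with a `guide_id` column and `start_<r>` / `end_<r>`
#' count columns.
#'
#' @param path counts TSV.
#' @return a [count_table()].
#' @export
read_counts_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, setdiff(names(tab), "guide_id"), drop = FALSE])
  rownames(mat) <- tab$guide_id
  cols <- colnames(mat)
  info <- data.frame(sample = cols,
                     replicate = as.integer(sub("^(start|end)_", "", cols)),
                     timepoint = sub("_.*$", "", cols),
                     stringsAsFactors = FALSE)
  count_table(mat, info)
}
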