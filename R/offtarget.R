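# PAM-proximal-first strings for every NGG site: element i is the target
# sequence read from the PAM outwards (up to 20 nt; shorter at linear
# genome edges).
pam_site_table <- function(genome) {
  sites <- scan_pams(genome)
  seq <- genome$sequence
  L <- nchar(seq)
  q <- sites$pam_pos
  plus <- sites$strand == "+"
  avail <- integer(nrow(sites))
  prox <- character(nrow(sites))
  if (genome$circular) {
    avail[] <- pmin(20L, L)
  } else {
    avail[plus] <- pmin(20L, q[plus])
    avail[!plus] <- pmin(20L, L - q[!plus] - 1L)
  }
  # plus strand: reverse of the upstream flank; minus: complement of the
  # downstream flank in forward order
  p_idx <- which(plus & avail > 0L)
  if (length(p_idx)) {
    fl <- substring(seq, q[p_idx] - avail[p_idx] + 1L, q[p_idx])
    prox[p_idx] <- as.character(Biostrings::reverse(Biostrings::DNAStringSet(fl)))
  }
  m_idx <- which(!plus & avail > 0L)
  if (length(m_idx)) {
    fl <- substring(seq, q[m_idx] + 2L, q[m_idx] + 1L + avail[m_idx])
    prox[m_idx] <- as.character(Biostrings::complement(Biostrings::DNAStringSet(fl)))
  }
  sites$prox <- prox
  sites$avail <- avail
  sites
}

#' Index all NGG sites of a genome by their PAM-proximal k-mer
#'
#' @param genome a `genome_record`.
#' @param k lookup k-mer width (the index supports match lengths >= k).
#' @return a `seed_index`: site table (with PAM-proximal strings) and a
#'   hash from k-mer to site row indices.
#' @export
index_genome_seeds <- function(genome, k = 6L) {
  stopifnot(k >= 1L, k <= 20L)
  sites <- pam_site_table(genome)
  ok <- sites$avail >= k
  map <- split(which(ok), substr(sites$prox[ok], 1L, k))
  structure(list(k = as.integer(k), sites = sites, map = map,
                 genome_id = genome$id), class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> %d NGG sites, k=%d, genome %s\n",
              nrow(x$sites), x$k, x$genome_id))
  invisible(x)
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(a, "", fixed = TRUE)[[1]][seq_len(n)]
  bv <- strsplit(b, "", fixed = TRUE)[[1]][seq_len(n)]
  mis <- which(av != bv)
  if (length(mis) == 0L) n else mis[1L] - 1L
}

#' Importance of every NGG site under the screen's repression rules
#'
#' A site can silence an important region if it lies (a) in a gene body in
#' coding orientation (protospacer strand = gene sense strand) where the
#' gene or any gene downstream of it in the same operon is
#' essential/fitness (elongation block + polarity), or (b) in the promoter
#' of an operon containing an essential/fitness gene, in either
#' orientation (initiation block). `orientation_blind = TRUE` drops the
#' strand requirement on gene bodies.
#'
#' @param sites site table (from a `seed_index`).
#' @param annotation gene annotation.
#' @param orientation_blind ignore hit orientation in gene bodies.
#' @return logical vector over sites.
#' @export
site_importance <- function(sites, annotation, orientation_blind = FALSE) {
  n_ann <- nrow(annotation)
  gval <- annotation$essentiality %in% c("essential", "fitness")
  # per gene: is it or anything downstream in its operon important?
  downstream_imp <- logical(n_ann)
  for (i in seq_len(n_ann)) {
    mem <- which(annotation$operon == annotation$operon[i])
    ds <- if (annotation$strand[i] == "+")
      mem[annotation$start[mem] >= annotation$start[i]]
    else mem[annotation$start[mem] <= annotation$start[i]]
    downstream_imp[i] <- any(gval[ds])
  }
  operon_imp <- vapply(annotation$operon, function(op)
    any(gval[annotation$operon == op]), logical(1))

  out <- logical(nrow(sites))
  for (s in seq_len(nrow(sites))) {
    p <- sites$pam_pos[s]
    hit <- which(annotation$start <= p & p < annotation$end)
    if (length(hit)) {
      g <- hit[1L]
      ok_orient <- orientation_blind || sites$strand[s] == annotation$strand[g]
      if (ok_orient && downstream_imp[g]) out[s] <- TRUE
    } else {
      prom <- which(!is.na(annotation$promoter_start) &
                      annotation$promoter_start <= p & p < annotation$promoter_end)
      if (length(prom) && any(operon_imp[prom])) out[s] <- TRUE
    }
  }
  out
}

#' Seed-match off-targets of a guide
#'
#' Finds every NGG site whose PAM-proximal bases are identical to the
#' guide's over at least `min_k` nt (maximal base-by-base extension from
#' the PAM; no gaps), excluding the guide's own target site.
#'
#' @param guide one-row guide data.frame (`spacer, pam_pos, strand`).
#' @param index a `seed_index` with `index$k <= min_k`.
#' @param min_k minimum seed identity in nt (>= 6).
#' @param importance optional logical vector from [site_importance()];
#'   adds an `in_important_region` column.
#' @return data.frame of hits: `pam_pos, strand, match_len` (and
#'   `in_important_region`), possibly empty.
#' @export
find_offtargets <- function(guide, index, min_k = 9L, importance = NULL) {
  stopifnot(min_k >= 6L, index$k <= min_k)
  prox <- as.character(Biostrings::reverse(Biostrings::DNAStringSet(guide$spacer)))
  key <- substr(prox, 1L, index$k)
  cand <- index$map[[key]]
  if (is.null(cand)) cand <- integer(0)
  own <- index$sites$pam_pos[cand] == guide$pam_pos &
    index$sites$strand[cand] == guide$strand
  cand <- cand[!own]
  if (length(cand) == 0L)
    return(data.frame(pam_pos = integer(0), strand = character(0),
                      match_len = integer(0)))
  ml <- vapply(cand, function(s) common_prefix_len(prox, index$sites$prox[s]),
               integer(1))
  keep <- ml >= min_k
  out <- data.frame(pam_pos = index$sites$pam_pos[cand[keep]],
                    strand = index$sites$strand[cand[keep]],
                    match_len = ml[keep], stringsAsFactors = FALSE)
  if (!is.null(importance)) out$in_important_region <- importance[cand[keep]]
  out
}

# For a set of guides, the maximal seed-match length to any important
# off-target site (0 when none at >= index$k).
max_important_match <- function(guides, index, importance) {
  prox_all <- as.character(Biostrings::reverse(Biostrings::DNAStringSet(guides$spacer)))
  keys <- substr(prox_all, 1L, index$k)
  vapply(seq_len(nrow(guides)), function(i) {
    cand <- index$map[[keys[i]]]
    if (is.null(cand)) return(0L)
    cand <- cand[importance[cand]]
    cand <- cand[!(index$sites$pam_pos[cand] == guides$pam_pos[i] &
                     index$sites$strand[cand] == guides$strand[i])]
    if (length(cand) == 0L) return(0L)
    max(vapply(cand, function(s)
      common_prefix_len(prox_all[i], index$sites$prox[s]), integer(1)))
  }, integer(1))
}

#' Defect / no-defect guide sets for off-target analysis
#'
#' Splits guides targeting the template strand of neutral genes into those
#' with an unexpected strong fitness defect (log2FC < threshold) and the
#' remainder.
#'
#' @param fitness fitness table.
#' @param guides annotated guide table.
#' @param annotation gene annotation.
#' @param threshold strong-defect threshold.
#' @return list of two guide data.frames: `defect`, `no_defect`.
#' @export
defect_sets <- function(fitness, guides, annotation, threshold = -3.5) {
  d <- merge(guides, fitness[, c("guide_id", "log2fc", "discarded")],
             by = "guide_id", sort = FALSE)
  neutral_genes <- annotation$gene[annotation$essentiality == "neutral"]
  d <- d[!d$discarded & !is.na(d$log2fc) &
           d$orientation == "template" &
           d$target_gene %in% neutral_genes, , drop = FALSE]
  list(defect = d[d$log2fc < threshold, , drop = FALSE],
       no_defect = d[d$log2fc >= threshold, , drop = FALSE])
}

#' Off-target detection-rate curve over seed-match lengths
#'
#' For each k, the fraction of defect guides (positive rate) and of
#' no-defect guides (false-positive rate) with at least one important-
#' region off-target of seed identity >= k, plus their difference — an
#' estimate of the fraction of unexpected defects explained by
#' off-targets. Both rates are non-increasing in k by construction.
#'
#' @param defect,no_defect guide data.frames ([defect_sets()]).
#' @param index a `seed_index` built at `k = min(k_range)`.
#' @param annotation gene annotation.
#' @param k_range seed-match lengths to sweep.
#' @param orientation_blind see [site_importance()].
#' @return list: `curve` data.frame (`k, positive_rate,
#'   false_positive_rate, difference`), `argmax_k`, and the per-guide
#'   maximal important match lengths (`defect_maxk`, `no_defect_maxk`).
#' @export
detection_rate_curve <- function(defect, no_defect, index, annotation,
                                 k_range = 6:15, orientation_blind = FALSE) {
  if (nrow(defect) == 0L || nrow(no_defect) == 0L)
    stop("both guide sets must be non-empty")
  stopifnot(index$k <= min(k_range))
  imp <- site_importance(index$sites, annotation,
                         orientation_blind = orientation_blind)
  mk_d <- max_important_match(defect, index, imp)
  mk_n <- max_important_match(no_defect, index, imp)
  curve <- data.frame(
    k = k_range,
    positive_rate = vapply(k_range, function(k) mean(mk_d >= k), numeric(1)),
    false_positive_rate = vapply(k_range, function(k) mean(mk_n >= k), numeric(1)))
  curve$difference <- curve$positive_rate - curve$false_positive_rate
  list(curve = curve, argmax_k = k_range[which.max(curve$difference)],
       defect_maxk = mk_d, no_defect_maxk = mk_n)
}

#' Fisher test for off-target enrichment among defect guides
#'
#' 2x2 Fisher exact test of (defect vs no-defect) x (has an important-
#' region off-target at seed identity >= k vs not).
#'
#' @param defect_maxk,no_defect_maxk per-guide maximal match lengths from
#'   [detection_rate_curve()].
#' @param k seed-match length at which to test.
#' @return the `htest` object from [stats::fisher.test()].
#' @export
offtarget_fisher_test <- function(defect_maxk, no_defect_maxk, k = 9L) {
  tab <- matrix(c(sum(defect_maxk >= k), sum(defect_maxk < k),
                  sum(no_defect_maxk >= k), sum(no_defect_maxk < k)),
                nrow = 2, byrow = TRUE,
                dimnames = list(set = c("defect", "no_defect"),
                                hit = c("hit", "no_hit")))
  stats::fisher.test(tab)
}
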