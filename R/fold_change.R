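#' Median-of-ratios size factors
#'
#' For each sample j, the factor is the median over guides of
#' count_gj / (geometric mean of guide g across samples); guides with a
#' zero count in any sample are excluded from the median.
#'
#' @param counts nonnegative integer matrix, guides x samples.
#' @return named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  all_nonzero <- rowSums(counts == 0) == 0
  if (!any(all_nonzero))
    stop("no guide has nonzero counts in every sample; sequencing depth ",
         "is likely too low to normalize")
  lg <- log(counts[all_nonzero, , drop = FALSE])
  loggeo <- rowMeans(lg)
  # median taken on the log scale (even-sized medians average
  # geometrically), matching the reference median-of-ratios estimator
  sf <- apply(lg, 2, function(lj) exp(stats::median(lj - loggeo)))
  stats::setNames(sf, colnames(counts))
}

#' Per-guide log2 fold changes, anchored to a control guide
#'
#' For each replicate,
#' `log2((end/sf_end + p) / (start/sf_start + p))` minus the same quantity
#' for the control guide; the reported `log2fc` is the mean over
#' replicates. Guides whose total read count across all samples is below
#' `min_total_reads` are flagged discarded and carry no fold change.
#'
#' @param counts a [count_table()].
#' @param control_guide guide id of the control guide, or `NULL` with
#'   `guides`+`control_spacer` to look it up by spacer.
#' @param guides optional guide table used to resolve `control_spacer`.
#' @param control_spacer spacer sequence of the control guide.
#' @param min_total_reads discard threshold on total reads across samples.
#' @param pseudocount added to normalized counts before the ratio.
#' @return data.frame (`fitness_table`): `guide_id`, `log2fc`, one
#'   `log2fc_rep<r>` column per replicate, `discarded`, `reason`.
#' @export
compute_log2fc <- function(counts, control_guide = NULL, guides = NULL,
                           control_spacer = "TGAGACCAGTCTAGGTCTCG",
                           min_total_reads = 20, pseudocount = 1) {
  stopifnot(inherits(counts, "count_table"))
  mat <- counts$counts
  info <- counts$samples
  if (is.null(control_guide)) {
    if (is.null(guides)) stop("provide control_guide or a guide table")
    hit <- guides$guide_id[guides$spacer == control_spacer]
    if (length(hit) == 0L) stop("control guide with spacer ", control_spacer,
                                " not found in the guide table")
    control_guide <- hit[1L]
  }
  if (!control_guide %in% rownames(mat))
    stop("control guide ", control_guide, " absent from the count table")

  sf <- size_factors(mat)
  norm <- sweep(mat, 2, sf, "/")

  total <- rowSums(mat)
  discarded <- total < min_total_reads
  if (discarded[control_guide])
    stop("control guide was discarded (<", min_total_reads, " total reads); ",
         "cannot anchor fold changes")

  reps <- sort(unique(info$replicate))
  rep_l2fc <- matrix(NA_real_, nrow(mat), length(reps),
                     dimnames = list(rownames(mat), paste0("log2fc_rep", reps)))
  for (ri in seq_along(reps)) {
    s_col <- info$sample[info$replicate == reps[ri] & info$timepoint == "start"]
    e_col <- info$sample[info$replicate == reps[ri] & info$timepoint == "end"]
    l <- log2((norm[, e_col] + pseudocount) / (norm[, s_col] + pseudocount))
    rep_l2fc[, ri] <- l - l[control_guide]
  }
  l2fc <- rowMeans(rep_l2fc)
  rep_l2fc[discarded, ] <- NA_real_
  l2fc[discarded] <- NA_real_

  out <- data.frame(guide_id = rownames(mat), log2fc = l2fc,
                    rep_l2fc, discarded = discarded,
                    reason = ifelse(discarded,
                                    sprintf("total reads %d < %d", total,
                                            as.integer(min_total_reads)), ""),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "control_guide") <- control_guide
  attr(out, "size_factors") <- sf
  out
}

#' Write / read a fitness table as TSV
#'
#' Values are written at two decimals; use the in-memory object for full
#' precision.
#'
#' @param fitness fitness table from [compute_log2fc()].
#' @param path file path.
#' @export
write_fitness_tsv <- function(fitness, path) {
  out <- fitness
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = 2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_fitness_tsv
#' @export
read_fitness_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
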