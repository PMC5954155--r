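#' Regression tree over genomic position, stratified by orientation
#'
#' Fits, separately for each guide orientation class (coding, template,
#' promoter, intergenic), a 1-D CART regression tree of log2FC on PAM
#' position: exhaustive variance-reduction splits, leaf prediction = mean
#' log2FC of member guides. The leaves partition the genome per
#' orientation into intervals of consistent fitness effect; leaves
#' predicting a strong defect define the "important regions".
#' Discarded and multi-mapping guides are excluded (positional attribution
#' is undefined for multi-mappers).
#'
#' @param fitness fitness table ([compute_log2fc()]).
#' @param guides annotated guide table.
#' @param min_leaf minimum guides per leaf.
#' @param max_depth maximum tree depth.
#' @return a `region_tree`: per-orientation trees plus a `leaves`
#'   data.frame (`orientation, start, end, pred, n`) whose intervals
#'   partition the position axis per orientation.
#' @export
fit_region_tree <- function(fitness, guides, min_leaf = 10L, max_depth = 14L) {
  d <- merge(guides, fitness[, c("guide_id", "log2fc", "discarded")],
             by = "guide_id")
  d <- d[!d$discarded & !d$multi_mapping & !is.na(d$log2fc), , drop = FALSE]
  if (nrow(d) == 0L) stop("no usable guides to fit the region tree")
  strata <- split(d, d$orientation)
  strata <- strata[sort(names(strata), method = "radix")]
  trees <- lapply(strata, function(s) {
    tree_1d(s$pam_pos, s$log2fc, min_leaf = min_leaf, max_depth = max_depth)
  })
  leaves <- do.call(rbind, lapply(names(trees), function(o) {
    lv <- tree_1d_leaves(trees[[o]])
    data.frame(orientation = o, lv, stringsAsFactors = FALSE)
  }))
  structure(list(trees = trees, leaves = leaves,
                 min_leaf = min_leaf, max_depth = max_depth),
            class = "region_tree")
}

# Exhaustive variance-minimizing 1-D regression tree. Split points are
# midpoints between adjacent distinct x values; a split is kept only if it
# strictly reduces the summed squared error and both children have at
# least min_leaf points.
tree_1d <- function(x, y, min_leaf = 10L, max_depth = 14L) {
  o <- order(x)
  grow <- function(x, y, depth) {
    n <- length(y)
    node <- list(n = n, pred = mean(y))
    if (depth >= max_depth || n < 2L * min_leaf) return(node)
    sp <- best_split_1d(x, y, min_leaf)
    if (is.null(sp)) return(node)
    left <- x <= sp$split
    node$split <- sp$split
    node$left <- grow(x[left], y[left], depth + 1L)
    node$right <- grow(x[!left], y[!left], depth + 1L)
    node
  }
  tree <- grow(x[o], y[o], 0L)
  tree
}

# Best SSE-reducing split for sorted-or-not x. Returns NULL if no valid
# strictly-improving split exists.
best_split_1d <- function(x, y, min_leaf) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  n <- length(y)
  csum <- cumsum(y)
  csum2 <- cumsum(y^2)
  tot <- csum[n]; tot2 <- csum2[n]
  i <- seq_len(n - 1L)
  # candidate boundaries after position i; require distinct x on both sides
  valid <- i >= min_leaf & (n - i) >= min_leaf & x[i] < x[i + 1L]
  if (!any(valid)) return(NULL)
  i <- i[valid]
  sse <- (csum2[i] - csum[i]^2 / i) +
    ((tot2 - csum2[i]) - (tot - csum[i])^2 / (n - i))
  sse0 <- tot2 - tot^2 / n
  best <- which.min(sse)
  if (sse[best] >= sse0 - 1e-12) return(NULL)
  list(split = (x[i[best]] + x[i[best] + 1L]) / 2, sse = sse[best])
}

tree_1d_leaves <- function(node, lo = -Inf, hi = Inf) {
  if (is.null(node$split)) {
    return(data.frame(start = lo, end = hi, pred = node$pred, n = node$n))
  }
  rbind(tree_1d_leaves(node$left, lo, node$split),
        tree_1d_leaves(node$right, node$split, hi))
}

tree_1d_predict <- function(node, x) {
  vapply(x, function(xi) {
    nd <- node
    while (!is.null(nd$split)) nd <- if (xi <= nd$split) nd$left else nd$right
    nd$pred
  }, numeric(1))
}

#' Predict leaf log2FC for guides from a region tree
#'
#' @param tree a `region_tree`.
#' @param guides guide table with `pam_pos` and `orientation`.
#' @return numeric vector of leaf predictions (`NA` for orientations not
#'   seen during fitting).
#' @export
predict_region_tree <- function(tree, guides) {
  out <- rep(NA_real_, nrow(guides))
  for (o in names(tree$trees)) {
    sel <- guides$orientation == o
    if (any(sel)) out[sel] <- tree_1d_predict(tree$trees[[o]], guides$pam_pos[sel])
  }
  out
}

#' @export
print.region_tree <- function(x, ...) {
  cat("<region_tree>", nrow(x$leaves), "leaves over",
      length(x$trees), "orientation strata\n")
  invisible(x)
}

#' Guides in neutral regions
#'
#' Neutral guides sit in tree leaves predicting log2FC above the
#' strong-defect threshold; the complement defines the important regions.
#'
#' @param tree a `region_tree`.
#' @param guides guide table.
#' @param threshold strong-defect threshold (log2FC).
#' @return logical vector: `TRUE` where the guide's leaf prediction is
#'   above the threshold.
#' @export
classify_neutral_guides <- function(tree, guides, threshold = -3.5) {
  pred <- predict_region_tree(tree, guides)
  !is.na(pred) & pred > threshold
}

#' Centered rolling average over genomic coordinates
#'
#' At each sorted distinct coordinate, averages all values whose
#' coordinate lies within a centered window of the given width.
#'
#' @param pos numeric coordinates.
#' @param values values keyed by `pos`.
#' @param window window width (same units as `pos`).
#' @return data.frame `position, mean, sd, n`.
#' @export
rolling_average <- function(pos, values, window) {
  stopifnot(window > 0, length(pos) == length(values))
  keep <- !is.na(values) & !is.na(pos)
  pos <- pos[keep]; values <- values[keep]
  o <- order(pos)
  pos <- pos[o]; values <- values[o]
  centers <- unique(pos)
  half <- window / 2
  res <- lapply(centers, function(cc) {
    lo <- findInterval(cc - half, pos, left.open = TRUE) + 1L
    hi <- findInterval(cc + half, pos)
    v <- values[lo:hi]
    data.frame(position = cc, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0, n = length(v))
  })
  do.call(rbind, res)
}

#' Genes not followed by another essential/fitness gene
#'
#' The predicate behind the reverse-polar analysis: essential/fitness
#' genes for which no other essential/fitness gene body intersects the
#' `max_dist` nt downstream of their end (in their own orientation).
#'
#' @param annotation gene annotation.
#' @param max_dist downstream window checked, nt.
#' @return character vector of gene names.
#' @export
isolated_important_genes <- function(annotation, max_dist = 200L) {
  imp <- annotation[annotation$essentiality %in% c("essential", "fitness"), ,
                    drop = FALSE]
  keep <- logical(nrow(imp))
  for (i in seq_len(nrow(imp))) {
    g <- imp[i, ]
    if (g$strand == "+") {
      win <- c(g$end, g$end + max_dist)
    } else {
      win <- c(g$start - max_dist, g$start)
    }
    others <- imp[imp$gene != g$gene, , drop = FALSE]
    overlap <- others$start < win[2] & others$end > win[1]
    keep[i] <- !any(overlap)
  }
  imp$gene[keep]
}

#' Reverse-polar effect test downstream of gene ends
#'
#' One-sample t-tests (two-sided) of coding-strand guides located in
#' windows downstream of the ends of isolated essential/fitness genes,
#' against the mean log2FC of template-strand guides in gene bodies (the
#' reference population for "no effect"). Guides inside annotated
#' promoters are excluded from the windows: binding there blocks
#' transcription initiation of the downstream operon, a distinct (and
#' typically strong) effect that is not reverse polarity.
#'
#' @param fitness fitness table.
#' @param guides annotated guide table.
#' @param annotation gene annotation.
#' @param gene_list genes to use; default [isolated_important_genes()].
#' @param windows list of `(from, to]` nt windows past the gene end.
#' @param include optional logical vector over `guides` restricting the
#'   populations (e.g. neutral-region guides from
#'   [classify_neutral_guides()], which masks strong-defect contexts such
#'   as polar conduits into downstream operons).
#' @return data.frame with one row per window: `from, to, n, mean,
#'   reference_mean, t, p` (`p = NA` when `n < 3`).
#' @export
polar_effect_test <- function(fitness, guides, annotation,
                              gene_list = NULL,
                              windows = list(near = c(0, 100), far = c(100, 200)),
                              include = NULL) {
  d <- merge(guides, fitness[, c("guide_id", "log2fc", "discarded")],
             by = "guide_id")
  if (!is.null(include)) {
    d <- d[include[match(d$guide_id, guides$guide_id)], , drop = FALSE]
  }
  d <- d[!d$discarded & !is.na(d$log2fc), , drop = FALSE]
  ref <- d$log2fc[d$orientation == "template"]
  ref_mean <- mean(ref)
  if (is.null(gene_list)) gene_list <- isolated_important_genes(annotation)
  genes <- annotation[annotation$gene %in% gene_list, , drop = FALSE]

  loc <- ifelse(d$strand == "+", d$pam_pos - 1L, d$pam_pos + 1L)
  res <- lapply(names(windows), function(w) {
    win <- windows[[w]]
    sel <- rep(FALSE, nrow(d))
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      same <- d$strand == g$strand
      dd <- if (g$strand == "+") loc - (g$end - 1L) else g$start - loc
      sel <- sel | (same & dd > win[1] & dd <= win[2])
    }
    sel <- sel & d$orientation != "promoter"
    v <- d$log2fc[sel]
    if (length(v) >= 3L) {
      tt <- stats::t.test(v, mu = ref_mean)
      data.frame(window = w, from = win[1], to = win[2], n = length(v),
                 mean = mean(v), reference_mean = ref_mean,
                 t = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(window = w, from = win[1], to = win[2], n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 reference_mean = ref_mean, t = NA_real_, p = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res)
}
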