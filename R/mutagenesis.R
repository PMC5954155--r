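# Accept either a trained seed_model or a plain prediction function
# (function(one_hot_matrix) -> numeric) with an explicit input length.
as_predictor <- function(model, input_len = NULL) {
  if (inherits(model, "seed_model")) {
    list(fn = function(X) predict(model, X), len = model$spec$input_len)
  } else if (is.function(model)) {
    if (is.null(input_len)) stop("input_len required for a bare predictor function")
    list(fn = model, len = as.integer(input_len))
  } else stop("model must be a seed_model or a function")
}

#' Single-mutation effect profile
#'
#' Generates random uniform ACGT sequences, mutates every position to each
#' of the 3 alternative bases in silico, and records the change in model
#' prediction. Mutating a base to itself has effect 0 by definition and is
#' excluded (stored as `NA`).
#'
#' @param model a `seed_model` or a prediction function on one-hot input.
#' @param n_sequences number of random sequences (1000 mirrors the scale
#'   used for this analysis).
#' @param seed RNG seed for the random sequence set.
#' @param input_len required when `model` is a bare function.
#' @return a `mutation_profile`: `effects` array
#'   (sequence x position x base, `NA` at the reference base),
#'   `ref` (reference base index per sequence/position), `input_len`.
#' @export
single_mutation_effects <- function(model, n_sequences = 1000L, seed = 1L,
                                    input_len = NULL) {
  pr <- as_predictor(model, input_len)
  set.seed(seed)
  seqs <- random_dna(n_sequences, pr$len)
  X <- one_hot_encode(seqs, pr$len)
  y0 <- pr$fn(X)
  n <- n_sequences; len <- pr$len
  ref <- matrix(0L, n, len)
  for (p in seq_len(len))
    ref[, p] <- max.col(X[, (p - 1L) * 4L + 1:4, drop = FALSE])
  eff <- array(NA_real_, dim = c(n, len, 4L),
               dimnames = list(NULL, NULL, BASES))
  for (p in seq_len(len)) {
    cols <- (p - 1L) * 4L + 1:4
    for (bi in 1:4) {
      Xm <- X
      Xm[, cols] <- 0
      Xm[, cols[bi]] <- 1
      d <- pr$fn(Xm) - y0
      d[ref[, p] == bi] <- NA_real_
      eff[, p, bi] <- d
    }
  }
  structure(list(effects = eff, ref = ref, input_len = len,
                 n_sequences = n), class = "mutation_profile")
}

#' Per-position standard deviation of mutation effects
#'
#' The positional-importance summary: at each position, the standard
#' deviation of the prediction changes over all (sequence, alternative
#' base) mutations.
#'
#' @param profile a `mutation_profile`.
#' @return numeric vector over positions (1 = PAM-distal end of the
#'   model's window; for the 20-nt spacer model position 20 is
#'   PAM-proximal).
#' @export
positional_variability <- function(profile) {
  vapply(seq_len(profile$input_len), function(p) {
    stats::sd(profile$effects[, p, ], na.rm = TRUE)
  }, numeric(1))
}

#' Embed spacer-model positions in a wider reporting window
#'
#' Reports a 20-nt spacer profile in 60-nt target-window coordinates
#' (spacer at positions 21-40, PAM at 41-43); positions the model never
#' sees are exactly 0.
#'
#' @param v per-position vector from [positional_variability()].
#' @param window_len reporting window length.
#' @param offset positions upstream of the spacer in the window.
#' @return numeric vector of length `window_len`.
#' @export
embed_spacer_in_window <- function(v, window_len = 60L, offset = 20L) {
  out <- numeric(window_len)
  out[offset + seq_along(v)] <- v
  out
}

#' Pairwise mutation-interaction matrix
#'
#' For each random sequence and each position pair (i, j), forms the
#' 9-vector of double-mutation effects Eij over the 3x3 alternative-base
#' combinations and the 9-vector of summed single effects Ei + Ej, and
#' records the Euclidean distance between the two; the matrix entry is the
#' mean distance over sequences. A model additive across positions gives a
#' matrix of exact zeros; nonzero entries flag epistatic interactions
#' between positions.
#'
#' @param model a `seed_model` or prediction function.
#' @param n_sequences number of random sequences (100 mirrors the scale
#'   used for this analysis).
#' @param seed RNG seed.
#' @param input_len required for a bare function.
#' @return symmetric nonnegative matrix (position x position, zero
#'   diagonal) with attribute `n_sequences`.
#' @export
pairwise_interactions <- function(model, n_sequences = 100L, seed = 1L,
                                  input_len = NULL) {
  pr <- as_predictor(model, input_len)
  set.seed(seed)
  len <- pr$len
  seqs <- random_dna(n_sequences, len)
  X <- one_hot_encode(seqs, len)
  y0 <- pr$fn(X)

  pairs <- utils::combn(len, 2L)
  n_pairs <- ncol(pairs)
  acc <- matrix(0, len, len)

  for (s in seq_len(n_sequences)) {
    x0 <- X[s, ]
    refidx <- vapply(seq_len(len), function(p)
      which.max(x0[(p - 1L) * 4L + 1:4]), integer(1))
    alts <- lapply(refidx, function(r) setdiff(1:4, r))

    # single effects for this sequence: len x 4 (NA at ref)
    Xs <- matrix(x0, 3L * len, length(x0), byrow = TRUE)
    srow <- 0L
    skey <- matrix(0L, 3L * len, 2L)
    for (p in seq_len(len)) for (b in alts[[p]]) {
      srow <- srow + 1L
      cols <- (p - 1L) * 4L + 1:4
      Xs[srow, cols] <- 0; Xs[srow, cols[b]] <- 1
      skey[srow, ] <- c(p, b)
    }
    dsing <- pr$fn(Xs) - y0[s]
    singles <- matrix(NA_real_, len, 4L)
    singles[skey] <- dsing

    # double mutants: 9 per pair
    nd <- 9L * n_pairs
    Xd <- matrix(x0, nd, length(x0), byrow = TRUE)
    drow <- 0L
    dkey <- matrix(0L, nd, 4L)   # i, bi, j, bj
    for (k in seq_len(n_pairs)) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      ci <- (i - 1L) * 4L + 1:4; cj <- (j - 1L) * 4L + 1:4
      for (bi in alts[[i]]) for (bj in alts[[j]]) {
        drow <- drow + 1L
        Xd[drow, ci] <- 0; Xd[drow, ci[bi]] <- 1
        Xd[drow, cj] <- 0; Xd[drow, cj[bj]] <- 1
        dkey[drow, ] <- c(i, bi, j, bj)
      }
    }
    ddbl <- pr$fn(Xd) - y0[s]
    ssum <- singles[dkey[, 1:2]] + singles[dkey[, 3:4]]
    diffsq <- (ddbl - ssum)^2
    pair_of_row <- rep(seq_len(n_pairs), each = 9L)
    dist_pair <- sqrt(rowsum(diffsq, pair_of_row)[, 1L])
    for (k in seq_len(n_pairs)) {
      acc[pairs[1L, k], pairs[2L, k]] <- acc[pairs[1L, k], pairs[2L, k]] + dist_pair[k]
    }
  }
  mat <- acc / n_sequences
  mat <- mat + t(mat)
  diag(mat) <- 0
  attr(mat, "n_sequences") <- n_sequences
  mat
}
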