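BASES <- c("A", "C", "G", "T")

#' One-hot encode DNA sequences
#'
#' Position-major layout with fixed channel order A, C, G, T: column
#' `4*(p-1)+b` is position p, base b. Exactly one 1 per position.
#'
#' @param sequences character vector of equal-length ACGT strings.
#' @param len expected sequence length (checked; default from the first
#'   sequence).
#' @return numeric matrix, `length(sequences)` x `4*len`.
#' @export
one_hot_encode <- function(sequences, len = NULL) {
  if (length(sequences) == 0L) stop("no sequences")
  if (is.null(len)) len <- nchar(sequences[1])
  if (any(nchar(sequences) != len))
    stop("all sequences must have length ", len)
  chars <- strsplit(sequences, "", fixed = TRUE)
  code <- match(unlist(chars), BASES)
  if (anyNA(code)) stop("sequences must be over A/C/G/T only")
  n <- length(sequences)
  X <- matrix(0, n, 4L * len)
  rows <- rep(seq_len(n), each = len)
  cols <- (rep.int(seq_len(len), n) - 1L) * 4L + code
  X[cbind(rows, cols)] <- 1
  X
}

#' @rdname one_hot_encode
#' @param X one-hot matrix as produced by [one_hot_encode()].
#' @export
one_hot_decode <- function(X) {
  len <- ncol(X) / 4L
  apply(X, 1, function(r) {
    paste(BASES[max.col(matrix(r, len, 4L, byrow = TRUE))], collapse = "")
  })
}

#' Specification of the locally connected fitness model
#'
#' A sparsely connected feedforward regressor on one-hot DNA: hidden
#' layers of 40, 20, 10 and 5 tanh units where unit i of a layer connects
#' only to the `conn_width` proximal units of the previous layer (anchored
#' proportionally, so locality follows sequence order on the
#' position-major input), followed by a dense linear scalar output.
#' Trained by Adam on mean squared error with L2 weight decay and
#' patience-based early stopping on a validation set.
#'
#' @param input_len input sequence length in nt (20 for the spacer-only
#'   model, 60 for the target-context model).
#' @param layers hidden layer sizes.
#' @param conn_width how many proximal units of the previous layer each
#'   unit sees.
#' @param lambda L2 regularization strength.
#' @param lr Adam learning rate (default selected by validation loss;
#'   smaller rates stall against the patience-based early stop).
#' @param batch_size minibatch size.
#' @param max_epochs training epoch cap.
#' @param patience early stop after this many epochs without validation
#'   improvement.
#' @param restarts number of independently initialized training runs; the
#'   run with the lowest validation MSE is kept. The patience-based early
#'   stop often halts a narrow sparse network on a noisy validation
#'   plateau, so single runs have a heavy right tail of validation losses;
#'   restarts select on validation loss only.
#' @param rng_seed seed controlling initialization and batch order
#'   (restart r uses rng_seed + r - 1).
#' @return a `model_spec` list.
#' @export
model_spec <- function(input_len = 20L, layers = c(40L, 20L, 10L, 5L),
                       conn_width = 5L, lambda = 1e-4, lr = 1e-2,
                       batch_size = 64L, max_epochs = 200L, patience = 2L,
                       restarts = 8L, rng_seed = 1L) {
  spec <- list(input_len = as.integer(input_len), layers = as.integer(layers),
               conn_width = as.integer(conn_width), lambda = lambda, lr = lr,
               batch_size = as.integer(batch_size),
               max_epochs = as.integer(max_epochs),
               patience = as.integer(patience), restarts = as.integer(restarts),
               rng_seed = as.integer(rng_seed))
  stopifnot(spec$lambda >= 0, spec$conn_width >= 1,
            all(spec$conn_width <= c(4L * spec$input_len, spec$layers)))
  class(spec) <- "model_spec"
  spec
}

# Connectivity masks: unit i of a layer with n units over a previous layer
# of m units connects to floor((i-1)*m/n)+1 + {-2..2} (clipped).
build_masks <- function(spec) {
  sizes <- c(4L * spec$input_len, spec$layers)
  half <- (spec$conn_width - 1L) %/% 2L
  masks <- vector("list", length(spec$layers))
  for (l in seq_along(spec$layers)) {
    m <- sizes[l]; n <- sizes[l + 1L]
    M <- matrix(0, n, m)
    for (i in seq_len(n)) {
      anchor <- floor((i - 1L) * m / n) + 1L
      cols <- max(1L, anchor - half):min(m, anchor + half)
      M[i, cols] <- 1
    }
    masks[[l]] <- M
  }
  masks
}

init_weights <- function(spec) {
  masks <- build_masks(spec)
  H <- length(spec$layers)
  W <- vector("list", H + 1L)
  b <- vector("list", H + 1L)
  for (l in seq_len(H)) {
    s <- sqrt(6 / (2 * spec$conn_width))
    W[[l]] <- matrix(stats::runif(length(masks[[l]]), -s, s),
                     nrow(masks[[l]]), ncol(masks[[l]])) * masks[[l]]
    b[[l]] <- numeric(nrow(masks[[l]]))
  }
  nH <- spec$layers[H]
  s <- sqrt(6 / (nH + 1))
  W[[H + 1L]] <- matrix(stats::runif(nH, -s, s), 1L, nH)
  b[[H + 1L]] <- 0
  list(W = W, b = b, masks = masks)
}

forward_pass <- function(W, b, X) {
  H <- length(W) - 1L
  A <- vector("list", H + 1L)
  A[[1L]] <- X
  for (l in seq_len(H)) {
    Z <- A[[l]] %*% t(W[[l]])
    Z <- sweep(Z, 2, b[[l]], "+")
    A[[l + 1L]] <- tanh(Z)
  }
  yhat <- drop(A[[H + 1L]] %*% t(W[[H + 1L]])) + b[[H + 1L]]
  list(A = A, yhat = yhat)
}

#' Train the locally connected fitness model
#'
#' @param spec a [model_spec()].
#' @param sequences character vector of ACGT strings of length
#'   `spec$input_len` (or an already one-hot matrix).
#' @param y observed log2 fold changes.
#' @param split list with integer index vectors `train`, `val`, `test`
#'   (disjoint); see [make_split()].
#' @return a `seed_model`: spec, weights, training `history` (of the kept
#'   restart), `best_epoch` and a `split_fingerprint`.
#' @export
train_model <- function(spec, sequences, y, split) {
  restarts <- if (is.null(spec$restarts)) 1L else spec$restarts
  if (restarts > 1L) {
    runs <- lapply(seq_len(restarts) - 1L, function(r) {
      sp <- spec; sp$restarts <- 1L; sp$rng_seed <- spec$rng_seed + r
      train_model(sp, sequences, y, split)
    })
    val <- vapply(runs, function(m) min(m$history$val_mse), numeric(1))
    best <- runs[[which.min(val)]]
    best$spec <- spec
    best$restart_val_mse <- val
    return(best)
  }
  X <- if (is.matrix(sequences)) sequences else one_hot_encode(sequences, spec$input_len)
  stopifnot(nrow(X) == length(y))
  for (s in c("train", "val", "test"))
    if (length(split[[s]]) == 0L) stop("empty ", s, " split")
  if (length(intersect(split$train, split$val)) ||
      length(intersect(split$train, split$test)) ||
      length(intersect(split$val, split$test)))
    stop("splits must be disjoint")

  set.seed(spec$rng_seed)
  par <- init_weights(spec)
  W <- par$W; b <- par$b; masks <- par$masks
  H <- length(spec$layers)
  adam <- list(mW = lapply(W, function(w) w * 0), vW = lapply(W, function(w) w * 0),
               mb = lapply(b, function(x) x * 0), vb = lapply(b, function(x) x * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0L

  Xtr <- X[split$train, , drop = FALSE]; ytr <- y[split$train]
  Xva <- X[split$val, , drop = FALSE]; yva <- y[split$val]
  ntr <- nrow(Xtr)

  best_val <- Inf; best <- list(W = W, b = b); best_epoch <- 0L
  history <- NULL

  for (epoch in seq_len(spec$max_epochs)) {
    ord <- sample.int(ntr)
    batch_losses <- c()
    for (start in seq(1L, ntr, by = spec$batch_size)) {
      idx <- ord[start:min(start + spec$batch_size - 1L, ntr)]
      Xb <- Xtr[idx, , drop = FALSE]; yb <- ytr[idx]
      B <- length(yb)
      fp <- forward_pass(W, b, Xb)
      resid <- fp$yhat - yb
      batch_losses <- c(batch_losses, mean(resid^2))

      # backward
      gW <- vector("list", H + 1L); gb <- vector("list", H + 1L)
      delta <- matrix(2 * resid / B, ncol = 1L)             # B x 1
      gW[[H + 1L]] <- t(delta) %*% fp$A[[H + 1L]] + 2 * spec$lambda * W[[H + 1L]]
      gb[[H + 1L]] <- sum(delta)
      up <- delta %*% W[[H + 1L]]                           # B x n_H
      for (l in rev(seq_len(H))) {
        dZ <- up * (1 - fp$A[[l + 1L]]^2)
        gW[[l]] <- (t(dZ) %*% fp$A[[l]] + 2 * spec$lambda * W[[l]]) * masks[[l]]
        gb[[l]] <- colSums(dZ)
        if (l > 1L) up <- dZ %*% W[[l]]
      }

      # Adam update
      t_step <- t_step + 1L
      c1 <- 1 - beta1^t_step; c2 <- 1 - beta2^t_step
      for (l in seq_len(H + 1L)) {
        adam$mW[[l]] <- beta1 * adam$mW[[l]] + (1 - beta1) * gW[[l]]
        adam$vW[[l]] <- beta2 * adam$vW[[l]] + (1 - beta2) * gW[[l]]^2
        W[[l]] <- W[[l]] - spec$lr * (adam$mW[[l]] / c1) /
          (sqrt(adam$vW[[l]] / c2) + eps)
        adam$mb[[l]] <- beta1 * adam$mb[[l]] + (1 - beta1) * gb[[l]]
        adam$vb[[l]] <- beta2 * adam$vb[[l]] + (1 - beta2) * gb[[l]]^2
        b[[l]] <- b[[l]] - spec$lr * (adam$mb[[l]] / c1) /
          (sqrt(adam$vb[[l]] / c2) + eps)
      }
      for (l in seq_len(H)) W[[l]] <- W[[l]] * masks[[l]]
    }
    val_mse <- mean((forward_pass(W, b, Xva)$yhat - yva)^2)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_mse = mean(batch_losses),
                                         val_mse = val_mse))
    if (val_mse < best_val - 1e-9) {
      best_val <- val_mse; best <- list(W = W, b = b); best_epoch <- epoch
    } else if (epoch - best_epoch > spec$patience) {
      break
    }
  }

  structure(list(spec = spec, W = best$W, b = best$b, masks = masks,
                 history = history, best_epoch = best_epoch,
                 split_fingerprint = vapply(split, function(ix)
                   sprintf("n=%d sum=%.0f", length(ix), sum(ix)), character(1))),
            class = "seed_model")
}

#' @export
print.seed_model <- function(x, ...) {
  cat(sprintf("<seed_model> input %d nt, layers %s, best epoch %d (val MSE %.4f)\n",
              x$spec$input_len, paste(x$spec$layers, collapse = "/"),
              x$best_epoch, min(x$history$val_mse)))
  invisible(x)
}

#' Predict fitness from sequence
#'
#' @param object a `seed_model`.
#' @param newdata character vector of sequences or a one-hot matrix.
#' @param ... unused.
#' @return numeric vector of predicted log2FC, order-preserving.
#' @export
predict.seed_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata
       else one_hot_encode(newdata, object$spec$input_len)
  if (ncol(X) != 4L * object$spec$input_len)
    stop("input has ", ncol(X) / 4, " nt but the model expects ",
         object$spec$input_len)
  unname(forward_pass(object$W, object$b, X)$yhat)
}

#' Evaluate a model on held-out data
#'
#' @param model a `seed_model`.
#' @param sequences test sequences (must be disjoint from training).
#' @param y observed log2FC.
#' @return list with `pearson` (NA if predictions have zero variance) and
#'   `rmse` in log2FC units.
#' @export
evaluate_model <- function(model, sequences, y) {
  pred <- predict(model, sequences)
  r <- if (stats::sd(pred) == 0) NA_real_ else stats::cor(pred, y)
  list(pearson = r, rmse = sqrt(mean((pred - y)^2)))
}

#' Stratified train/validation/test split
#'
#' Largest-remainder proportional allocation within each stratum (e.g.
#' seed5 groups), so every stratum is represented across splits in
#' proportion to `fracs`.
#'
#' @param groups stratum label per observation.
#' @param fracs train/val/test fractions (sum to 1).
#' @param seed RNG seed for shuffling.
#' @return list of disjoint index vectors `train`, `val`, `test`.
#' @export
make_split <- function(groups, fracs = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(abs(sum(fracs) - 1) < 1e-8)
  set.seed(seed)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    target <- fracs * n
    base <- floor(target)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(target - base, stats::runif(3), decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    cuts <- cumsum(base)
    out$train <- c(out$train, idx[seq_len(base[1])])
    if (base[2] > 0) out$val <- c(out$val, idx[(cuts[1] + 1L):cuts[2]])
    if (base[3] > 0) out$test <- c(out$test, idx[(cuts[2] + 1L):cuts[3]])
  }
  out
}
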