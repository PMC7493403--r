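# Mini-batch training with Adam on categorical cross-entropy. Gradients are
# exact: the max-pool gradient is routed to the argmax position of each
# filter, the average-pool gradient is spread as 1/L over the true (unpadded)
# length, so variable-length inputs need no padding at all -- each protein is
# convolved at its own length.

#' Training configuration
#'
#' @param epochs Number of passes over the training data (default 100).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Mini-batch size; gradients are averaged within a batch.
#' @param class_weights Weight the loss by inverse class frequency, which
#'   protects the minority compartments (the intermembrane space above all)
#'   under the skewed class sizes typical of curated mitochondrial sets.
#' @param loss Loss name; only `"cross_entropy"` is supported.
#' @param optimizer Optimizer name; only `"adam"` is supported.
#' @param seed Seed controlling shuffling (and the validation split).
#' @param validation_split Fraction of the data held out, stratified by
#'   class, to monitor validation loss for early stopping. 0 (the default)
#'   trains for the full epoch count.
#' @param patience Epochs without validation-loss improvement before early
#'   stopping (only when `validation_split > 0`).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100, learning_rate = 1e-3, batch_size = 16,
                         class_weights = TRUE, loss = "cross_entropy",
                         optimizer = "adam", seed = 1,
                         validation_split = 0, patience = 10) {
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1, patience >= 1,
            validation_split >= 0, validation_split < 1)
  loss <- match.arg(loss, "cross_entropy")
  optimizer <- match.arg(optimizer, "adam")
  structure(
    list(epochs = as.integer(epochs), learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         class_weights = isTRUE(class_weights), loss = loss,
         optimizer = optimizer, seed = as.integer(seed),
         validation_split = validation_split, patience = as.integer(patience)),
    class = "train_config"
  )
}

zero_like <- function(weights) {
  lapply(weights, function(w) if (is.matrix(w)) w * 0 else numeric(length(w)))
}

adam_init <- function(weights) {
  list(m = zero_like(weights), v = zero_like(weights), t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(weights = weights, state = state)
}

# Loss and gradients for one mini-batch. The proteins' im2col matrices are
# stacked row-wise so the convolution, its gradient and the dense layers run
# as single BLAS products; pooling and its gradient are applied per protein
# block at each protein's true length (no padding enters any statistic).
batch_backward <- function(weights, caches, lens, ys, ws) {
  B <- length(caches)
  nF <- ncol(weights$Wc)
  Cbig <- do.call(rbind, caches)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L

  Z <- Cbig %*% weights$Wc
  Z <- sweep(Z, 2, weights$bc, `+`)
  A <- Z * (Z > 0)

  P <- matrix(0, B, 2L * nF)
  mx_idx <- matrix(0L, B, nF)
  for (b in seq_len(B)) {
    Ab <- A[starts[b]:ends[b], , drop = FALSE]
    ix <- max.col(t(Ab), ties.method = "first")
    mx_idx[b, ] <- ix
    P[b, ] <- c(Ab[cbind(ix, seq_len(nF))], colMeans(Ab))
  }

  H_pre <- sweep(P %*% weights$W1, 2, weights$b1, `+`)
  H <- H_pre * (H_pre > 0)
  O <- sweep(H %*% weights$W2, 2, weights$b2, `+`)
  O <- O - apply(O, 1, max)
  E <- exp(O)
  probs <- E / rowSums(E)

  p_true <- pmax(probs[cbind(seq_len(B), ys)], 1e-12)
  losses <- -ws * log(p_true)
  correct <- max.col(probs, ties.method = "first") == ys

  dO <- probs
  dO[cbind(seq_len(B), ys)] <- dO[cbind(seq_len(B), ys)] - 1
  dO <- dO * ws
  dW2 <- crossprod(H, dO)
  db2 <- colSums(dO)
  dH <- (dO %*% t(weights$W2)) * (H_pre > 0)
  dW1 <- crossprod(P, dH)
  db1 <- colSums(dH)
  dP <- dH %*% t(weights$W1)                          # B x 2F

  dA <- matrix(0, nrow(A), nF)
  for (b in seq_len(B)) {
    rows <- starts[b]:ends[b]
    dA[rows, ] <- matrix(dP[b, nF + seq_len(nF)] / lens[b],
                         lens[b], nF, byrow = TRUE)
    hit <- cbind(starts[b] - 1L + mx_idx[b, ], seq_len(nF))
    dA[hit] <- dA[hit] + dP[b, seq_len(nF)]
  }
  dZ <- dA * (Z > 0)
  dWc <- crossprod(Cbig, dZ)
  dbc <- colSums(dZ)

  list(loss = sum(losses), n_correct = sum(correct),
       grads = list(Wc = dWc, bc = dbc, W1 = dW1, b1 = db1,
                    W2 = dW2, b2 = db2))
}

#' Train the compartment predictor
#'
#' Mini-batch Adam on (optionally class-weighted) categorical cross-entropy.
#' With a fixed seed the loss trace is reproducible run-to-run on the same
#' platform. When `validation_split > 0` a stratified slice is held out and
#' training stops early once validation loss has not improved for `patience`
#' epochs, restoring the best weights.
#'
#' @param model An untrained (or previously trained) `mito_cnn`.
#' @param x List of `encoded_protein` matrices.
#' @param labels Compartment labels aligned with `x`.
#' @param config A [train_config()].
#' @return The model with updated weights, `trained = TRUE` and a `history`
#'   tibble (`epoch`, `loss`, `accuracy`, and `val_loss` when validating).
#' @export
train <- function(model, x, labels, config = train_config()) {
  stopifnot(inherits(model, "mito_cnn"))
  if (length(x) == 0) stop("empty training data", call. = FALSE)
  labels <- as_compartment(labels)
  if (length(labels) != length(x)) {
    stop("'x' and 'labels' must have the same length", call. = FALSE)
  }
  if (dplyr::n_distinct(labels) < 2) {
    stop("training data must contain at least two classes", call. = FALSE)
  }
  purrr::walk(x, check_encoded, model = model)

  k <- model$config$kernel_width
  caches <- purrr::map(x, im2col, kernel_width = k)
  lens <- vapply(x, nrow, integer(1))
  y <- as.integer(labels)

  counts <- table(factor(y, levels = 1:4))
  w_class <- rep(1, 4)
  if (config$class_weights) {
    present <- counts > 0
    w_class[present] <- sum(counts) / (sum(present) * counts[present])
  }

  weights <- model$weights
  state <- adam_init(weights)
  history <- vector("list", config$epochs)

  withr::with_seed(config$seed, {
    n <- length(x)
    val_idx <- integer(0)
    if (config$validation_split > 0) {
      val_idx <- unlist(lapply(split(seq_len(n), y), function(ix) {
        nv <- max(1L, round(length(ix) * config$validation_split))
        sample(ix, nv)
      }), use.names = FALSE)
    }
    tr_idx <- setdiff(seq_len(n), val_idx)

    best_val <- Inf
    best_weights <- weights
    stall <- 0L
    n_epochs_run <- 0L

    for (epoch in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      ep_correct <- 0L
      for (batch in batches) {
        bp <- batch_backward(weights, caches[batch], lens[batch], y[batch],
                             w_class[y[batch]])
        ep_loss <- ep_loss + bp$loss
        ep_correct <- ep_correct + bp$n_correct
        grads <- lapply(bp$grads, `/`, length(batch))
        upd <- adam_step(weights, grads, state, config$learning_rate)
        weights <- upd$weights
        state <- upd$state
      }
      rec <- list(epoch = epoch, loss = ep_loss / length(tr_idx),
                  accuracy = ep_correct / length(tr_idx))
      if (length(val_idx) > 0) {
        vl <- mean(vapply(val_idx, function(i) {
          fw <- forward_pass(weights, caches[[i]], lens[i])
          -w_class[y[i]] * log(max(fw$probs[y[i]], 1e-12))
        }, numeric(1)))
        rec$val_loss <- vl
        if (vl < best_val - 1e-8) {
          best_val <- vl
          best_weights <- weights
          stall <- 0L
        } else {
          stall <- stall + 1L
        }
      }
      history[[epoch]] <- rec
      n_epochs_run <- epoch
      if (length(val_idx) > 0 && stall >= config$patience) break
    }
    if (length(val_idx) > 0) weights <- best_weights
  })

  model$weights <- weights
  model$trained <- TRUE
  model$train_config <- config
  model$history <- dplyr::bind_rows(history[seq_len(n_epochs_run)])
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint is self-describing: architecture config, weights, channel
#' order and class order travel together so encoder/model compatibility can
#' be checked on load.
#'
#' @param model A `mito_cnn`.
#' @param path Checkpoint file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mito_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mito_cnn") ||
      !identical(model$channels, encoding_channels())) {
    stop("not a compatible model checkpoint: ", path, call. = FALSE)
  }
  model
}
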