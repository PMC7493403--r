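# The four-compartment 1D-CNN: a length-preserving convolution (stride 1,
# symmetric zero padding) of 256 width-19 filters over the Lx30 encoding,
# parallel global max and global average pooling concatenated into a
# 512-vector, a 256-unit ReLU hidden layer, and a 4-way softmax. The forward
# and backward passes are written as BLAS matrix products over an im2col
# expansion of the input.

#' Network architecture configuration
#'
#' @param n_filters Number of convolutional filters (default 256).
#' @param kernel_width Filter width in residues; must be odd so that
#'   symmetric zero padding preserves the sequence length (default 19).
#' @param n_hidden Hidden units in the fully connected layer (default 256).
#' @param n_classes Output classes; fixed at 4, one per sub-mitochondrial
#'   compartment.
#' @param conv_activation Convolution activation; only `"relu"` is supported.
#' @param seed Seed for weight initialization.
#' @return A `model_config` list.
#' @export
model_config <- function(n_filters = 256, kernel_width = 19, n_hidden = 256,
                         n_classes = 4, conv_activation = "relu", seed = 1) {
  if (kernel_width %% 2 == 0) {
    stop("kernel_width must be odd (symmetric padding preserves length)",
         call. = FALSE)
  }
  if (n_classes != 4) {
    stop("n_classes is fixed at 4 (the four sub-mitochondrial compartments)",
         call. = FALSE)
  }
  stopifnot(n_filters >= 1, n_hidden >= 1, kernel_width >= 1)
  conv_activation <- match.arg(conv_activation, "relu")
  structure(
    list(n_filters = as.integer(n_filters),
         kernel_width = as.integer(kernel_width),
         n_hidden = as.integer(n_hidden),
         n_classes = 4L,
         conv_activation = conv_activation,
         n_channels = 30L,
         seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Build an untrained network
#'
#' Weights use He-normal initialization (variance 2/fan-in), biases start at
#' zero; initialization is reproducible through the config seed.
#'
#' @param config A [model_config()].
#' @return A `mito_cnn` model object.
#' @export
build_model <- function(config = model_config()) {
  d_in <- config$kernel_width * config$n_channels
  d_pool <- 2L * config$n_filters
  weights <- withr::with_seed(config$seed, list(
    Wc = matrix(rnorm(d_in * config$n_filters, 0, sqrt(2 / d_in)),
                d_in, config$n_filters),
    bc = numeric(config$n_filters),
    W1 = matrix(rnorm(d_pool * config$n_hidden, 0, sqrt(2 / d_pool)),
                d_pool, config$n_hidden),
    b1 = numeric(config$n_hidden),
    W2 = matrix(rnorm(config$n_hidden * config$n_classes, 0,
                      sqrt(2 / config$n_hidden)),
                config$n_hidden, config$n_classes),
    b2 = numeric(config$n_classes)
  ))
  structure(
    list(config = config, weights = weights, channels = encoding_channels(),
         classes = compartment_levels(), trained = FALSE, history = NULL),
    class = "mito_cnn"
  )
}

n_parameters <- function(model) {
  sum(vapply(model$weights, length, integer(1)))
}

#' @export
print.mito_cnn <- function(x, ...) {
  cfg <- x$config
  cat("<mito_cnn> 1D-CNN sub-mitochondrial compartment predictor\n")
  cat("  conv: ", cfg$n_filters, " filters x width ", cfg$kernel_width,
      " over 30 channels (length-preserving)\n", sep = "")
  cat("  pooling: global max + global average -> ", 2 * cfg$n_filters,
      " features\n", sep = "")
  cat("  dense: ", cfg$n_hidden, " hidden units -> softmax over ",
      cfg$n_classes, " compartments\n", sep = "")
  cat("  parameters: ", n_parameters(x),
      if (x$trained) "  (trained)" else "  (untrained)", "\n", sep = "")
  invisible(x)
}

# im2col: rows of the result are the kernel_width x n_channels receptive
# field around each position, flattened row-major, with zero padding of
# (k - 1) / 2 rows at both ends.
im2col <- function(x, kernel_width) {
  L <- nrow(x)
  nc <- ncol(x)
  pad <- (kernel_width - 1L) %/% 2L
  xp <- rbind(matrix(0, pad, nc), unclass(x), matrix(0, pad, nc))
  idx <- outer(seq_len(L) - 1L, seq_len(kernel_width), `+`)  # padded row ids
  a <- xp[as.vector(t(idx)), , drop = FALSE]                 # (L*k) x nc
  matrix(t(a), nrow = L, byrow = TRUE)                       # L x (k*nc)
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# Forward pass from a precomputed im2col matrix. Returns intermediates
# needed for the backward pass when cache = TRUE.
forward_pass <- function(weights, C, L, cache = FALSE) {
  Z <- C %*% weights$Wc
  Z <- sweep(Z, 2, weights$bc, `+`)
  A <- Z * (Z > 0)                                   # ReLU feature map L x F
  mx_idx <- max.col(t(A), ties.method = "first")     # argmax row per filter
  mx <- A[cbind(mx_idx, seq_len(ncol(A)))]
  av <- colMeans(A)
  p <- c(mx, av)                                     # pooled, length 2F
  h_pre <- drop(p %*% weights$W1) + weights$b1
  h <- h_pre * (h_pre > 0)
  o <- drop(h %*% weights$W2) + weights$b2
  probs <- softmax(o)
  if (!cache) return(list(probs = probs, feature_map = A, pooled = p, hidden = h))
  list(probs = probs, feature_map = A, pooled = p, hidden = h,
       A = A, mx_idx = mx_idx, h_pre = h_pre, L = L)
}

#' Inspect the network's intermediate representations
#'
#' Runs one forward pass and returns the convolutional feature map (L rows x
#' n_filters), the concatenated max/average pooled vector (length
#' 2 * n_filters), the hidden activations and the class probabilities.
#'
#' @param model A `mito_cnn`.
#' @param x An `encoded_protein` (L x 30 matrix).
#' @return List with `feature_map`, `pooled`, `hidden`, `probabilities`.
#' @export
cnn_features <- function(model, x) {
  check_encoded(model, x)
  C <- im2col(x, model$config$kernel_width)
  fw <- forward_pass(model$weights, C, nrow(x))
  list(feature_map = fw$feature_map, pooled = fw$pooled, hidden = fw$hidden,
       probabilities = setNames(fw$probs, model$classes))
}

check_encoded <- function(model, x) {
  if (!is.matrix(x) || ncol(x) != model$config$n_channels) {
    stop("input must be an encoded protein with ", model$config$n_channels,
         " channels, got ", if (is.matrix(x)) ncol(x) else "a non-matrix",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Predict sub-mitochondrial compartments
#'
#' Softmax probabilities over the four compartments; the predicted label is
#' the argmax, with ties broken by the lowest class index. Inference is
#' deterministic: repeated calls on the same weights and input are
#' bit-identical.
#'
#' @param object A `mito_cnn` model.
#' @param x An `encoded_protein` or a (named) list of them.
#' @param ... Unused.
#' @return Tibble with one row per protein: `protein_id`,
#'   `predicted_compartment`, `p_outer`, `p_inner`, `p_ims`, `p_matrix`.
#' @export
predict.mito_cnn <- function(object, x, ...) {
  if (is.matrix(x)) x <- list(x)
  rows <- purrr::map(x, function(e) {
    check_encoded(object, e)
    C <- im2col(e, object$config$kernel_width)
    probs <- forward_pass(object$weights, C, nrow(e))$probs
    stopifnot(abs(sum(probs) - 1) < 1e-6)
    tibble(
      protein_id = attr(e, "protein_id") %||% NA_character_,
      predicted_compartment = object$classes[which.max(probs)],
      p_outer = probs[1], p_inner = probs[2], p_ims = probs[3],
      p_matrix = probs[4]
    )
  })
  dplyr::bind_rows(rows)
}
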