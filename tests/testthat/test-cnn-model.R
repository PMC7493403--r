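test_that("architecture dimensions match the printed design", {
  model <- build_model(model_config())
  seqc <- paste(rep("A", 100), collapse = "")
  enc <- encode_protein(list(id = "x", sequence = seqc),
                        generate_pssm(list(id = "x", sequence = seqc),
                                      noise = 1, seed = 3))
  f <- cnn_features(model, enc)
  expect_equal(dim(f$feature_map), c(100, 256))   # Lx256 feature map
  expect_length(f$pooled, 512)                    # max + avg concatenated
  expect_length(f$hidden, 256)
  expect_length(f$probabilities, 4)
})

test_that("even kernel widths are rejected at configuration time", {
  expect_error(model_config(kernel_width = 18), "odd")
  expect_error(model_config(n_classes = 3), "fixed at 4")
})

test_that("the architecture is length-agnostic from kernel-width to 1000", {
  model <- build_model(small_model_config())
  for (L in c(19, 1, 1000)) {
    seqc <- paste(sample(c("A", "G", "L", "W"), L, replace = TRUE),
                  collapse = "")
    enc <- encode_protein(list(id = "x", sequence = seqc),
                          generate_pssm(list(id = "x", sequence = seqc),
                                        noise = 1, seed = L))
    f <- cnn_features(model, enc)
    expect_equal(nrow(f$feature_map), L)  # length-preserving convolution
    expect_equal(sum(f$probabilities), 1, tolerance = 1e-9)
  }
})

test_that("softmax normalization holds over random models", {
  seqc <- paste(rep(c("A", "W"), 15), collapse = "")
  enc <- encode_protein(list(id = "x", sequence = seqc),
                        generate_pssm(list(id = "x", sequence = seqc),
                                      noise = 1, seed = 1))
  tiny <- model_config(n_filters = 8, kernel_width = 5, n_hidden = 8)
  for (s in 1:100) {
    tiny$seed <- s
    p <- predict(build_model(tiny), enc)
    probs <- unlist(p[c("p_outer", "p_inner", "p_ims", "p_matrix")])
    expect_equal(sum(probs), 1, tolerance = 1e-6)
    expect_true(all(probs >= 0))
  }
})

test_that("zeroed final layer yields the uniform distribution", {
  model <- build_model(small_model_config())
  model$weights$W2[] <- 0
  model$weights$b2[] <- 0
  seqc <- paste(rep("K", 30), collapse = "")
  enc <- encode_protein(list(id = "x", sequence = seqc),
                        generate_pssm(list(id = "x", sequence = seqc),
                                      noise = 0, seed = 1))
  p <- predict(model, enc)
  expect_equal(unlist(p[c("p_outer", "p_inner", "p_ims", "p_matrix")]),
               c(p_outer = 0.25, p_inner = 0.25, p_ims = 0.25,
                 p_matrix = 0.25))
  expect_equal(p$predicted_compartment, "outer_membrane")  # tie -> lowest index
})

test_that("inference is deterministic and rejects wrong channel counts", {
  model <- build_model(small_model_config())
  seqc <- paste(rep(c("A", "C", "D"), 10), collapse = "")
  enc <- encode_protein(list(id = "x", sequence = seqc),
                        generate_pssm(list(id = "x", sequence = seqc),
                                      noise = 1, seed = 4))
  p1 <- predict(model, enc)
  p2 <- predict(model, enc)
  expect_identical(p1, p2)
  expect_error(predict(model, matrix(0, 10, 29)), "channels")
})

test_that("analytic gradients agree with finite differences", {
  cfg <- model_config(n_filters = 4, kernel_width = 5, n_hidden = 6, seed = 2)
  model <- build_model(cfg)
  seqc <- "MKTAYIAKQR"
  enc <- encode_protein(list(id = "x", sequence = seqc),
                        generate_pssm(list(id = "x", sequence = seqc),
                                      noise = 1, seed = 5))
  C <- submito:::im2col(enc, cfg$kernel_width)
  L <- nrow(enc)
  bp <- submito:::batch_backward(model$weights, list(C), L, 2L, 1)
  loss_at <- function(w) {
    fw <- submito:::forward_pass(w, C, L)
    -log(fw$probs[2])
  }
  eps <- 1e-5
  for (nm in c("Wc", "bc", "W1", "b1", "W2", "b2")) {
    w <- model$weights
    idx <- sample(length(w[[nm]]), 3)
    for (i in idx) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      expect_equal(bp$grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("training descends on separable motif data and is seed-stable", {
  set <- toy_training_set(n_per_class = 10, seed = 42)
  model <- build_model(small_model_config())
  cfg <- train_config(epochs = 30, seed = 7)
  fit1 <- train(model, set$encoded, set$labels, cfg)
  expect_lt(tail(fit1$history$loss, 1), fit1$history$loss[1])

  fit2 <- train(model, set$encoded, set$labels, cfg)
  expect_identical(fit1$history, fit2$history)        # same seed, same trace
  expect_identical(fit1$weights, fit2$weights)
})

test_that("the network reaches 100% training accuracy on trivially separable data", {
  # each class tagged by an invariant residue block: zero substitution rate
  spec <- synthetic_spec(n_per_class = 5, length_range = c(30, 40),
                         substitution_rate = 0, seed = 8)
  prot <- generate_proteome(spec)
  encoded <- withr::with_seed(9, {
    profs <- lapply(seq_len(nrow(prot)), function(i) {
      generate_pssm(prot[i, ], noise = 0, seed = NULL)
    })
    names(profs) <- prot$id
    encode_proteome(prot, profs)
  })
  fit <- train(build_model(small_model_config()), encoded, prot$label,
               train_config(epochs = 40, seed = 3))
  preds <- predict(fit, encoded)
  expect_equal(preds$predicted_compartment, prot$label)
})

test_that("degenerate training inputs are rejected", {
  set <- toy_training_set(n_per_class = 3, seed = 10)
  model <- build_model(small_model_config())
  one_class <- set$labels == "matrix"
  expect_error(train(model, set$encoded[one_class], set$labels[one_class]),
               "two classes")
  expect_error(train(model, list(), character(0)), "empty")
})

test_that("checkpoints round-trip through save and load", {
  set <- toy_training_set(n_per_class = 3, seed = 12)
  fit <- train(build_model(small_model_config()), set$encoded, set$labels,
               train_config(epochs = 2, seed = 1))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, path)
  back <- load_model(path)
  expect_identical(predict(back, set$encoded), predict(fit, set$encoded))
})
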