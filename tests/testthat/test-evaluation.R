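test_that("confusion counts partition the scored proteins", {
  ids <- sprintf("P%02d", 1:12)
  truth <- tibble::tibble(protein_id = ids,
                          label = rep(compartment_levels(), each = 3))
  perfect <- tibble::tibble(protein_id = ids,
                            predicted_compartment = truth$label)
  cm <- confusion(perfect, truth)
  expect_equal(diag(cm), setNames(rep(3L, 4), compartment_levels()))
  expect_equal(sum(cm), 12)

  one_mistake <- perfect
  one_mistake$predicted_compartment[1] <- "matrix"  # true outer -> pred matrix
  cm2 <- confusion(one_mistake, truth)
  expect_equal(cm2["outer_membrane", "matrix"], 1L)
  expect_equal(sum(cm2), 12)

  shuffled <- one_mistake[sample(12), ]
  expect_equal(confusion(shuffled, truth), cm2)  # alignment is by id

  bad <- perfect
  bad$protein_id[1] <- "unknown"
  expect_error(confusion(bad, truth), "do not match")
})

test_that("per-class MCC equals the closed-form value on hand counts", {
  # class 1 one-vs-rest with TP=8, FN=2, FP=1, TN=9
  cm <- matrix(0L, 4, 4,
               dimnames = list(compartment_levels(), compartment_levels()))
  cm[1, 1] <- 8L; cm[1, 2] <- 2L; cm[2, 1] <- 1L; cm[2, 2] <- 9L
  expected <- (8 * 9 - 1 * 2) / sqrt((8 + 1) * (8 + 2) * (9 + 1) * (9 + 2))
  expect_equal(per_class_mcc(cm, "outer_membrane"), expected)
  expect_equal(per_class_mcc(cm, 1), expected)

  diag_cm <- diag(c(5L, 6L, 7L, 8L))
  dimnames(diag_cm) <- dimnames(cm)
  expect_equal(mcc_by_class(diag_cm)$mcc, rep(1, 4))
})

test_that("MCC is near zero when predictions are independent of truth", {
  withr::with_seed(123, {
    n <- 4000
    truth <- sample(1:4, n, replace = TRUE)
    pred <- sample(1:4, n, replace = TRUE)
    cm <- unclass(table(factor(truth, levels = 1:4),
                        factor(pred, levels = 1:4)))
    dimnames(cm) <- list(compartment_levels(), compartment_levels())
    for (k in 1:4) expect_lt(abs(per_class_mcc(cm, k)), 0.1)
  })
})

test_that("MCC is symmetric under swapping the dichotomy and bounded in [-1,1]", {
  withr::with_seed(99, {
    for (i in 1:1000) {
      cm <- random_cm(40)
      v <- per_class_mcc(cm, 2)
      expect_gte(v, -1); expect_lte(v, 1)
    }
  })
  # swap symmetry on the binary counts directly
  expect_equal(submito:::mcc_from_counts(8, 9, 1, 2),
               submito:::mcc_from_counts(9, 8, 2, 1))
  expect_equal(submito:::mcc_from_counts(0, 0, 0, 0), 0)  # empty margins
})

test_that("per-class MCC equals the Pearson-of-indicators oracle", {
  withr::with_seed(7, {
    for (i in 1:200) {
      cm <- random_cm(30)
      for (k in 1:4) {
        expect_equal(per_class_mcc(cm, k), mcc_pearson_oracle(cm, k),
                     tolerance = 1e-10)
      }
    }
  })
})

test_that("stratified folds split each class as evenly as possible", {
  labels <- rep(compartment_levels(), each = 10)
  fold <- make_folds(labels, 5, seed = 21)
  expect_equal(as.vector(table(fold)), rep(8L, 5))        # 8 proteins per fold
  per_class <- table(labels, fold)
  expect_true(all(per_class == 2))                        # 2 per class per fold
  expect_identical(fold, make_folds(labels, 5, seed = 21))  # seed-stable
  expect_false(identical(fold, make_folds(labels, 5, seed = 22)))
  expect_error(make_folds(rep(compartment_levels(), each = 3), 5),
               "fewer")
})

test_that("cross-validation partitions the data and pools fold matrices", {
  set <- toy_training_set(n_per_class = 5, seed = 31, length_range = c(30, 40))
  cv <- cross_validate(set$encoded, set$labels, k_folds = 2,
                       model_config = small_model_config(),
                       train_config = train_config(epochs = 10, seed = 2),
                       seed = 5)
  expect_equal(sort(cv$folds$protein_id), sort(set$records$id))
  expect_equal(sum(cv$pooled), length(set$encoded))
  expect_equal(cv$pooled, Reduce(`+`, cv$confusions))
  expect_equal(tidy(cv), cv$mcc)
  g <- glance(cv)
  expect_equal(g$n, 20)
  expect_equal(g$k_folds, 2)
})
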