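test_that("soft dice loss reproduces worked arithmetic cases", {
  mask <- array(0, c(10, 10, 1)); mask[1:10, 1:10, 1][1:100 <= 100] <- 0
  mask[3:7, 3:7, 1] <- 1  # some foreground
  expect_equal(soft_dice_loss(mask, mask, smoothing = 0), 0)

  a <- array(0, c(4, 4, 1)); a[1:2, , 1] <- 1
  b <- array(0, c(4, 4, 1)); b[3:4, , 1] <- 1
  expect_equal(soft_dice_loss(a, b, smoothing = 0), 1)

  # all-0.5 predictions against 8 foreground pixels on a 4x4 grid:
  # soft dice = 2*4 / (8 + 8) = 0.5
  p <- array(0.5, c(4, 4, 1))
  t <- array(0, c(4, 4, 1)); t[, 1:2, 1] <- 1
  expect_equal(soft_dice_loss(p, t, smoothing = 0), 0.5)

  expect_error(soft_dice_loss(p, array(0, c(3, 3, 1))), "identical shape")
  expect_error(soft_dice_loss(p, t, smoothing = -1), "nonnegative")
})

test_that("soft dice loss is bounded, symmetric for binary inputs and consistent with the dice metric", {
  set.seed(55)
  for (rep in 1:10) {
    p <- array(runif(6 * 6 * 4), c(6, 6, 4))
    t <- array(rbinom(6 * 6 * 4, 1, 0.4), c(6, 6, 4))
    l <- soft_dice_loss(p, t)
    expect_gte(l, 0); expect_lte(l, 1)

    pb <- array(rbinom(6 * 6 * 4, 1, 0.4), c(6, 6, 4))
    expect_equal(soft_dice_loss(pb, t, 0), soft_dice_loss(t, pb, 0))

    # cross-module consistency with the evaluation metric at s = 0
    for (ch in 1:4) {
      expect_equal(soft_dice_loss(pb[, , ch, drop = FALSE], t[, , ch, drop = FALSE], 0),
                   1 - dice(pb[, , ch], t[, , ch]), tolerance = 1e-12)
    }
  }
})

test_that("the loss gradient matches finite differences", {
  set.seed(66)
  p <- array(runif(5 * 5 * 2 * 2, 0.05, 0.95), c(5, 5, 2, 2))
  t <- array(rbinom(5 * 5 * 2 * 2, 1, 0.3), c(5, 5, 2, 2))
  g <- soft_dice_loss_grad(p, t, 1)
  for (i in sample(length(p), 12)) {
    pp <- p; pp[i] <- p[i] + 1e-6
    pm <- p; pm[i] <- p[i] - 1e-6
    fd <- (soft_dice_loss(pp, t, 1) - soft_dice_loss(pm, t, 1)) / 2e-6
    expect_equal(g[i], fd, tolerance = 1e-5)
  }
})

test_that("patient-level folds are balanced, exhaustive and reproducible", {
  ids <- sprintf("pat%03d", 1:285)
  folds <- make_folds(ids, folds = 10, seed = 2)
  sizes <- vapply(folds, function(f) length(f$validation_ids), 1L)
  expect_true(all(sizes %in% c(28L, 29L)))
  expect_true(all(vapply(folds, function(f) length(f$train_ids), 1L) %in% c(256L, 257L)))
  # each patient validates exactly once; train/validation disjoint
  all_val <- unlist(lapply(folds, `[[`, "validation_ids"))
  expect_setequal(all_val, ids)
  expect_equal(anyDuplicated(all_val), 0)
  for (f in folds) {
    expect_length(intersect(f$train_ids, f$validation_ids), 0)
  }

  expect_identical(make_folds(ids, 10, seed = 2), folds)
  expect_false(identical(make_folds(ids, 10, seed = 3), folds))

  singletons <- make_folds(sprintf("p%d", 1:10), folds = 10, seed = 1)
  expect_setequal(unlist(lapply(singletons, `[[`, "validation_ids")),
                  sprintf("p%d", 1:10))
  expect_true(all(vapply(singletons, function(f) length(f$validation_ids), 1L) == 1L))

  expect_error(make_folds(c("a", "a", "b"), 2), "duplicate")
  expect_error(train_config(folds = 1), "folds")
})

test_that("a zero learning rate leaves parameters unchanged over an epoch", {
  cases <- tiny_cohort(2)
  ds <- make_slice_dataset(cases, input_size = 32)
  m <- build_model(tiny_model_config(), seed = 5)
  before <- m$params
  fold <- list(fold_index = 1, train_ids = vapply(cases, `[[`, "", "patient_id"),
               validation_ids = character())
  tr <- train_fold(m, fold, ds, train_config(learning_rate = 0, epochs = 1,
                                             batch_size = 4, folds = 2, seed = 1))
  expect_identical(tr$model$params, before)
  expect_equal(nrow(tr$history), 1)
})

test_that("training history has one row per epoch and the loss falls on a tiny overfit", {
  cases <- tiny_cohort(2)
  ds <- make_slice_dataset(cases, input_size = 32)
  ids <- vapply(cases, `[[`, "", "patient_id")
  fold <- list(fold_index = 1, train_ids = ids[1], validation_ids = ids[2])
  m <- build_model(tiny_model_config(), seed = 5)
  tc <- train_config(learning_rate = 5e-3, epochs = 6, batch_size = 4,
                     folds = 2, seed = 9)
  tr <- train_fold(m, fold, ds, tc)
  expect_equal(nrow(tr$history), 6)
  expect_identical(tr$history$epoch, 1:6)
  expect_true(all(is.finite(tr$history$val_dice)))
  expect_lt(tail(tr$history$train_loss, 1), tr$history$train_loss[1])
  expect_error(train_fold(m, list(fold_index = 1, train_ids = "nobody",
                                  validation_ids = character()),
                          ds, tc), "empty training set")
})

test_that("cross-validation evaluates every patient exactly once, by its held-out model", {
  cases <- tiny_cohort(6)
  report <- run_cross_validation(cases, tiny_model_config(),
                                 quick_train_config(epochs = 1))
  expect_s3_class(report, "cohort_report")
  expect_equal(nrow(report$per_case), 6 * 4)
  expect_setequal(unique(report$per_case$patient_id),
                  vapply(cases, `[[`, "", "patient_id"))
  expect_equal(max(table(report$per_case$patient_id)), 4)
  expect_length(attr(report, "histories"), 2)
})
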