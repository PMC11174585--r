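test_that("splits are stratified, disjoint, exhaustive and deterministic", {
  ds <- generate_dataset(gait_benchmark_specs()[1:2], 50, noise_spec(),
                         frames = 8, seed = 2)
  sp <- split_dataset(ds, c(8, 1, 1), seed = 5)
  expect_equal(nrow(sp$train), 80L)
  expect_equal(nrow(sp$val), 10L)
  expect_equal(nrow(sp$test), 10L)
  # stratification: 40/5/5 within each class
  expect_equal(as.integer(table(sp$train$class_id)), c(40L, 40L))
  expect_equal(as.integer(table(sp$val$class_id)), c(5L, 5L))
  ids <- c(sp$train$sequence_id, sp$val$sequence_id, sp$test$sequence_id)
  expect_setequal(ids, ds$sequence_id)
  expect_equal(length(ids), length(unique(ids)))
  sp2 <- split_dataset(ds, c(8, 1, 1), seed = 5)
  expect_identical(sp$train$sequence_id, sp2$train$sequence_id)
  sp3 <- split_dataset(ds, c(8, 1, 1), seed = 6)
  expect_false(identical(sp$train$sequence_id, sp3$train$sequence_id))
})

test_that("degenerate split ratios are rejected", {
  ds <- generate_dataset(gait_benchmark_specs()[1:2], 10, noise_spec(),
                         frames = 8, seed = 3)
  expect_error(split_dataset(ds, c(1, 0, 0)), class = "fpgait_validation_error")
  expect_error(split_dataset(ds, c(-1, 1, 1)), class = "fpgait_validation_error")
  tiny <- ds[1:4, ]
  expect_error(split_dataset(tiny, c(8, 1, 1)),
               class = "fpgait_validation_error")
})

test_that("confusion counts and accuracies follow the one-vs-rest form", {
  # 10 items engineered to give class 1: TP=3 FN=1 FP=1 TN=5
  labels <- c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2)
  preds <- c(1, 1, 1, 2, 1, 2, 2, 2, 2, 2)
  cm <- confusion_matrix(preds, labels, 2)
  expect_equal(unname(cm$tp[1]), 3L)
  expect_equal(unname(cm$fn[1]), 1L)
  expect_equal(unname(cm$fp[1]), 1L)
  expect_equal(unname(cm$tn[1]), 5L)
  expect_equal(sum(cm$tp[1], cm$fp[1], cm$tn[1], cm$fn[1]), cm$n_total)
  acc <- evaluate_accuracy(cm)
  expect_equal(acc$per_class$ovr_accuracy[1], 0.8)  # (3+5)/10
  expect_equal(acc$micro, 0.8)

  # all correct
  cm1 <- confusion_matrix(c(1, 2, 3), c(1, 2, 3), 3)
  expect_equal(evaluate_accuracy(cm1)$micro, 1)
  expect_equal(evaluate_accuracy(cm1)$macro, 1)

  expect_error(confusion_matrix(integer(0), integer(0), 2),
               class = "fpgait_validation_error")
  expect_error(confusion_matrix(c(1, 4), c(1, 2), 3),
               class = "fpgait_validation_error")
})

test_that("micro accuracy matches a counting oracle and survives relabelling", {
  withr::with_seed(7, {
    labels <- sample.int(4, 60, replace = TRUE)
    preds <- sample.int(4, 60, replace = TRUE)
  })
  cm <- confusion_matrix(preds, labels, 4)
  correct <- 0L
  for (i in seq_along(labels)) if (preds[i] == labels[i]) correct <- correct + 1L
  expect_equal(evaluate_accuracy(cm)$micro, correct / 60)
  # permuting class identities leaves micro accuracy unchanged
  perm <- c(3L, 1L, 4L, 2L)
  cm2 <- confusion_matrix(perm[preds], perm[labels], 4)
  expect_equal(evaluate_accuracy(cm2)$micro, evaluate_accuracy(cm)$micro)
  # per-class counts satisfy TP+FP+TN+FN = n for every class
  expect_equal(unname(cm$tp + cm$fp + cm$tn + cm$fn), rep(60L, 4))
})

test_that("zero learning rate leaves parameters unchanged", {
  ds <- make_tiny_dataset()
  sp <- split_dataset(ds, c(4, 1, 1), seed = 1)
  cfg <- tiny_model_config()
  tc <- train_config(learning_rate = 0, epochs = 2, batch_size = 4, seed = 3)
  m0 <- fpgcn_init(cfg, seed = 3)
  fit <- train_model(cfg, sp$train, tc, val_data = sp$val)
  expect_equal(fpgait:::param_vector(fit$model$params),
               fpgait:::param_vector(m0$params))
})

test_that("training is deterministic and learns a separable toy problem", {
  ds <- make_tiny_dataset(n_per_class = 8)
  sp <- split_dataset(ds, c(6, 1, 1), seed = 2)
  tc <- train_config(learning_rate = 0.3, epochs = 10, batch_size = 4,
                     seed = 4)
  fit1 <- train_model(tiny_model_config(), sp$train, tc, val_data = sp$val)
  final_train <- dplyr::filter(fit1$history, split == "train",
                               epoch == max(epoch))
  expect_equal(final_train$accuracy, 1)
  expect_true(all(c("epoch", "split", "loss", "accuracy") %in%
                    names(fit1$history)))
  # bit-identical repetition under the same seed
  fit2 <- train_model(tiny_model_config(), sp$train, tc, val_data = sp$val)
  expect_identical(fit1$history, fit2$history)
  expect_equal(fpgait:::param_vector(fit1$model$params),
               fpgait:::param_vector(fit2$model$params))
  # glance/tidy surfaces
  expect_identical(tidy(fit1), fit1$history)
  g <- glance(fit1)
  expect_equal(g$variant, "fpgcn")
  expect_equal(g$best_epoch, fit1$best_epoch)
  # prediction plumbing
  preds <- predict(fit1, sp$test, type = "class")
  expect_length(preds, nrow(sp$test))
  pr <- predict(fit1, sp$test, type = "prob")
  expect_equal(rowSums(pr), rep(1, nrow(sp$test)), tolerance = 1e-12)
  ev <- evaluate_model(fit1, sp$test)
  expect_true(ev$micro >= 0 && ev$micro <= 1)
})

test_that("training rejects single-class data and bad configs", {
  ds <- make_tiny_dataset()
  one <- ds[ds$class_id == 1, ]
  expect_error(train_model(tiny_model_config(), one, train_config()),
               class = "fpgait_validation_error")
  expect_error(train_config(label_smoothing = 1),
               class = "fpgait_validation_error")
  expect_error(train_config(momentum = 1), class = "fpgait_validation_error")
})

test_that("ablation variant flags map to the documented architectures", {
  cfg_f <- toy_config("fgcn_only")
  cfg_p <- toy_config("pgcn_only")
  cfg_fp <- toy_config("fpgcn")
  m_f <- fpgcn_init(cfg_f, seed = 1)
  m_p <- fpgcn_init(cfg_p, seed = 1)
  m_fp <- fpgcn_init(cfg_fp, seed = 1)
  # the spectral-only variant drops the half/limb pathways and fusion
  expect_equal(m_f$config$n_pathways, 1L)
  expect_false(m_f$config$fuse)
  expect_equal(length(m_f$params$pathways), 1L)
  # the pyramid-only variant keeps all pathways but freezes the masks
  expect_equal(m_p$config$n_pathways, 3L)
  expect_true(m_p$config$fuse)
  ds <- make_tiny_dataset(n_per_class = 4)
  sp <- split_dataset(ds, c(2, 1, 1), seed = 1)
  tc <- train_config(learning_rate = 0.3, epochs = 2, batch_size = 4, seed = 1,
                     split_ratio = c(2, 1, 1))
  cfgp24 <- model_config(layout = "kinect25", n_classes = 2, frames = 24,
                         widths = c(6, 5, 4), depth = 1,
                         variant = "pgcn_only")
  fit_p <- train_model(cfgp24, sp$train, tc, val_data = sp$val)
  for (p in 1:3) {
    lw <- fit_p$model$params$pathways[[p]]$layers[[1]]
    expect_equal(lw$W_A, rep(1, length(lw$W_A)))  # masks stayed frozen
    expect_equal(lw$W_F, rep(1, length(lw$W_F)))
  }
})
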