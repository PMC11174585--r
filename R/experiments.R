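# Desk-scale experiments on the shipped synthetic benchmark: end-to-end
# training, the three-variant ablation, and the speed-robustness comparison
# of the spectral layer against the fixed-window temporal-convolution
# baseline.

#' Study conditions of the shipped synthetic benchmark
#'
#' One place defining the desk-scale protocol used by the package's own
#' experiments: the four-class benchmark dataset (100 sequences per class,
#' 120 frames at 30 fps on the 25-joint layout, 1 cm jitter, 2% dropout),
#' the reduced model (widths 16/12/8, depth 2) and the training
#' configuration (momentum SGD, learning rate 0.2, 3 epochs, batch 32,
#' label smoothing 0.1, 8:1:1 split).
#'
#' @return Named list of protocol constants.
#' @export
benchmark_protocol <- function() {
  list(
    n_per_class = 100L,
    frames = 120L,
    fps = 30,
    layout = "kinect25",
    widths = c(16L, 12L, 8L),
    depth = 2L,
    n_classes = 4L,
    learning_rate = 0.2,
    momentum = 0.9,
    epochs = 3L,
    batch_size = 32L,
    label_smoothing = 0.1,
    split_ratio = c(8, 1, 1),
    tcn_stride = 5L
  )
}

#' Generate the shipped four-class benchmark dataset
#'
#' @param seed Integer seed.
#' @param n_per_class,frames Override the protocol's dataset size.
#' @return A `gait_dataset`.
#' @export
benchmark_dataset <- function(seed = 1L,
                              n_per_class = benchmark_protocol()$n_per_class,
                              frames = benchmark_protocol()$frames) {
  pr <- benchmark_protocol()
  generate_dataset(gait_benchmark_specs(), n_per_class, benchmark_noise(),
                   frames = frames, fps = pr$fps, layout = pr$layout,
                   seed = seed)
}

#' Model configuration of the reduced benchmark classifier
#'
#' @param variant Model variant (see [model_config()]).
#' @param frames Frame count.
#' @return An `fpgcn_config`.
#' @export
benchmark_model_config <- function(variant = "fpgcn",
                                   frames = benchmark_protocol()$frames) {
  pr <- benchmark_protocol()
  model_config(layout = pr$layout, n_classes = pr$n_classes, frames = frames,
               widths = pr$widths, depth = pr$depth, variant = variant,
               epsilon = pr$label_smoothing, tcn_stride = pr$tcn_stride)
}

#' Training configuration of the benchmark protocol
#'
#' @param seed Integer seed.
#' @param epochs Override the protocol's epoch count.
#' @return An `fpgait_train_config`.
#' @export
benchmark_train_config <- function(seed = 1L,
                                   epochs = benchmark_protocol()$epochs) {
  pr <- benchmark_protocol()
  train_config(learning_rate = pr$learning_rate, momentum = pr$momentum,
               epochs = epochs, batch_size = pr$batch_size,
               split_ratio = pr$split_ratio,
               label_smoothing = pr$label_smoothing, seed = seed)
}

#' Train and evaluate one benchmark variant
#'
#' Splits the data 8:1:1 (stratified, seeded), trains the requested variant
#' and reports test metrics.
#'
#' @param data A `gait_dataset` (e.g. [benchmark_dataset()]).
#' @param variant Model variant.
#' @param seed Seed for the split, initialisation and batching.
#' @param epochs Training epochs.
#' @param return_fit Keep the fitted model in the result.
#' @return List with `variant`, `seed`, `test_accuracy` (micro),
#'   `test_macro`, `best_epoch`, and optionally `fit` and the `splits`.
#' @export
run_benchmark_variant <- function(data, variant = "fpgcn", seed = 1L,
                                  epochs = benchmark_protocol()$epochs,
                                  return_fit = FALSE) {
  splits <- split_dataset(data, benchmark_protocol()$split_ratio, seed = seed)
  cfg <- benchmark_model_config(variant, frames = dim(data$seq[[1]]$values)[2])
  fit <- train_model(cfg, splits$train, benchmark_train_config(seed, epochs),
                     val_data = splits$val)
  ev <- evaluate_model(fit, splits$test)
  out <- list(variant = variant, seed = seed, test_accuracy = ev$micro,
              test_macro = ev$macro, best_epoch = fit$best_epoch)
  if (return_fit) {
    out$fit <- fit
    out$splits <- splits
  }
  out
}

#' Three-variant ablation experiment
#'
#' Trains the full pyramid (`fpgcn`), the spectral-only (`fgcn_only`) and
#' the pyramid-only (`pgcn_only`) variants under identical seeds and
#' splits, for each of several seeds, and tabulates test accuracies.
#'
#' @param data A `gait_dataset`.
#' @param seeds Integer vector of seeds.
#' @param variants Character vector of variants to compare.
#' @param epochs Training epochs per run.
#' @param return_fits Keep the fitted models (attribute `"fits"`).
#' @return An `fpgait_ablation` tibble with columns `variant`, `seed`,
#'   `test_accuracy`, `test_macro`, `best_epoch`.
#' @export
run_ablation <- function(data, seeds = 1:3,
                         variants = c("fpgcn", "fgcn_only", "pgcn_only"),
                         epochs = benchmark_protocol()$epochs,
                         return_fits = FALSE) {
  rows <- list()
  fits <- list()
  for (seed in seeds) {
    for (variant in variants) {
      res <- run_benchmark_variant(data, variant, seed, epochs,
                                   return_fit = return_fits)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variant = variant, seed = seed,
        test_accuracy = res$test_accuracy, test_macro = res$test_macro,
        best_epoch = res$best_epoch)
      if (return_fits) fits[[paste(variant, seed, sep = "_")]] <- res$fit
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fpgait_ablation", class(out))
  if (return_fits) attr(out, "fits") <- fits
  out
}

#' Summarise an ablation table
#'
#' @param x An [run_ablation()] result.
#' @param ... Unused.
#' @return Tibble with per-variant mean and standard deviation of the test
#'   accuracy across seeds.
#' @method glance fpgait_ablation
#' @export
glance.fpgait_ablation <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$variant),
    mean_accuracy = mean(.data$test_accuracy),
    sd_accuracy = stats::sd(.data$test_accuracy),
    n_seeds = dplyr::n(),
    .groups = "drop"
  )
}

#' Benchmark dataset with per-sequence cadence perturbation
#'
#' Clones the benchmark class specs but scales every sequence's cadence by
#' an independent factor drawn uniformly from `[1 - shift, 1 + shift]`,
#' emulating walking-speed variation unseen in training.
#'
#' @param seed Integer seed.
#' @param shift Maximal relative cadence perturbation (default 0.2).
#' @param n_per_class Sequences per class.
#' @param frames Frame count.
#' @return A `gait_dataset`.
#' @export
perturbed_benchmark_dataset <- function(seed = 1L, shift = 0.2,
                                        n_per_class = 25L,
                                        frames = benchmark_protocol()$frames) {
  pr <- benchmark_protocol()
  specs <- gait_benchmark_specs()
  rows <- list()
  idx <- 0L
  for (k in seq_along(specs)) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      sseed <- derive_seed(seed + 7777L, idx)
      spec_i <- specs[[k]]
      ph <- 0
      withr::with_seed(derive_seed(sseed, 0L), {
        spec_i$cadence_hz <- specs[[k]]$cadence_hz * runif(1, 1 - shift, 1 + shift)
        ph <- runif(1, 0, 2 * pi)
      })
      s <- generate_sequence(spec_i, benchmark_noise(), frames, pr$fps,
                             pr$layout, seed = sseed, phase = ph)
      s$subject_id <- sprintf("pert_%02d_%03d", k, i)
      rows[[idx]] <- tibble::tibble(
        sequence_id = idx, class_id = specs[[k]]$class_id,
        class_name = specs[[k]]$name, subject_id = s$subject_id,
        seed = sseed, seq = list(s))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "layout") <- pr$layout
  attr(out, "fps") <- pr$fps
  attr(out, "frames") <- as.integer(frames)
  class(out) <- c("gait_dataset", class(out))
  out
}

#' Speed-robustness comparison: spectral layer vs temporal convolution
#'
#' Trains the single-pathway spectral classifier (`fgcn_only`) and the
#' width/depth-matched fixed-window temporal-convolution baseline (`tcn`)
#' on the clean benchmark, then evaluates both on a cadence-perturbed test
#' set whose speed variation was never seen in training.
#'
#' @param data Clean training `gait_dataset` (e.g. [benchmark_dataset()]).
#' @param seeds Integer vector of seeds.
#' @param shift Maximal relative cadence perturbation of the test set.
#' @param epochs Training epochs per run.
#' @param n_test_per_class Perturbed test sequences per class.
#' @param fits Optional named list of already-trained fits (names
#'   `"<variant>_<seed>"`, as produced by [run_ablation()] with
#'   `return_fits = TRUE`); matching entries are reused instead of
#'   retraining.
#' @return Tibble with columns `variant`, `seed`, `perturbed_accuracy`,
#'   `clean_accuracy`.
#' @export
run_speed_robustness <- function(data, seeds = 1:3, shift = 0.2,
                                 epochs = benchmark_protocol()$epochs,
                                 n_test_per_class = 25L, fits = NULL) {
  rows <- list()
  for (seed in seeds) {
    pert <- perturbed_benchmark_dataset(seed, shift, n_test_per_class,
                                        frames = dim(data$seq[[1]]$values)[2])
    for (variant in c("fgcn_only", "tcn")) {
      key <- paste(variant, seed, sep = "_")
      if (!is.null(fits[[key]])) {
        fit <- fits[[key]]
        splits <- split_dataset(data, benchmark_protocol()$split_ratio,
                                seed = seed)
        clean <- evaluate_model(fit, splits$test)$micro
      } else {
        res <- run_benchmark_variant(data, variant, seed, epochs,
                                     return_fit = TRUE)
        fit <- res$fit
        clean <- res$test_accuracy
      }
      evp <- evaluate_model(fit, pert)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variant = variant, seed = seed,
        perturbed_accuracy = evp$micro,
        clean_accuracy = clean)
    }
  }
  dplyr::bind_rows(rows)
}
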