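# ggplot2 diagnostics for fits, ablation tables and sequences.

#' Plot training history of a fit
#'
#' Loss and accuracy per epoch for the training and validation splits.
#'
#' @param object An `fpgcn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fpgcn_fit
#' @export
autoplot.fpgcn_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("loss", "accuracy"),
                           names_to = "metric")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = "split",
                  title = sprintf("training history (%s)",
                                  object$model$config$variant)) +
    ggplot2::theme_minimal()
}

#' Plot an ablation table
#'
#' Per-seed test accuracies and per-variant means.
#'
#' @param object An [run_ablation()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fpgait_ablation
#' @export
autoplot.fpgait_ablation <- function(object, ...) {
  summ <- glance(object)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$variant, y = .data$test_accuracy)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$seed)), size = 2) +
    ggplot2::geom_crossbar(
      data = summ,
      ggplot2::aes(x = .data$variant, y = .data$mean_accuracy,
                   ymin = .data$mean_accuracy, ymax = .data$mean_accuracy),
      inherit.aes = FALSE, width = 0.4, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "test accuracy", colour = "seed",
                  title = "ablation: test accuracy by variant") +
    ggplot2::theme_minimal()
}

#' Plot joint trajectories of a skeleton sequence
#'
#' Walking-direction coordinate of selected joints over time.
#'
#' @param object A `skeleton_sequence`.
#' @param joints 0-based joint indices (default: the layout's ankles).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot skeleton_sequence
#' @export
autoplot.skeleton_sequence <- function(object, joints = NULL, ...) {
  layout <- skeleton_layout(object$layout)
  if (is.null(joints)) joints <- unlist(layout$measure_joints)
  fwd <- layout$forward_channel
  T <- dim(object$values)[2]
  dat <- dplyr::bind_rows(lapply(joints, function(v) {
    tibble::tibble(
      time = (seq_len(T) - 1) / object$fps,
      joint = layout$graph$joint_names[v + 1L],
      coordinate = object$values[fwd, , v + 1L])
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$coordinate,
                                    colour = .data$joint)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [s]", y = "walking-direction coordinate [m]",
                  title = object$class_name %||% "skeleton sequence") +
    ggplot2::theme_minimal()
}
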