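# The four skeleton-sequence augmentations: mirroring, channel flipping,
# additive noise, random cropping. All preserve the label, tensor rank and
# finiteness of the sequence.

#' Mirror a skeleton sequence left/right
#'
#' Negates the lateral coordinate channel and swaps every left joint with
#' its right counterpart according to the layout's mirror map. Applying the
#' operation twice restores the original sequence exactly.
#'
#' @param x A `skeleton_sequence`.
#' @param layout Layout name or object; defaults to the sequence's own.
#' @return The mirrored `skeleton_sequence` (same label).
#' @export
augment_mirror <- function(x, layout = NULL) {
  layout <- resolve_layout(x, layout)
  if (all(layout$mirror_perm == seq_along(layout$mirror_perm))) {
    abort_config("layout '%s' defines no left/right mirror map", layout$name)
  }
  v <- x$values
  v[layout$lateral_channel, , ] <- -v[layout$lateral_channel, , ]
  x$values <- v[, , layout$mirror_perm, drop = FALSE]
  x
}

#' Permute the coordinate channels of a sequence
#'
#' @param x A `skeleton_sequence`.
#' @param perm Channel permutation (default: reversed channel order).
#' @return The channel-flipped sequence (same label).
#' @export
augment_channel_flip <- function(x, perm = rev(seq_len(dim(x$values)[1]))) {
  C <- dim(x$values)[1]
  if (!identical(sort(as.integer(perm)), seq_len(C))) {
    abort_validation("perm must be a permutation of 1..%d", C)
  }
  x$values <- x$values[perm, , , drop = FALSE]
  x
}

#' Add Gaussian coordinate noise to a sequence
#'
#' @param x A `skeleton_sequence`.
#' @param sd Noise standard deviation (`sd = 0` is the identity).
#' @param seed Integer seed.
#' @return The jittered sequence (same label).
#' @export
augment_noise <- function(x, sd, seed = 1L) {
  if (sd < 0) abort_validation("sd must be >= 0")
  if (sd > 0) {
    withr::with_seed(seed, {
      x$values <- x$values + rnorm(length(x$values), sd = sd)
    })
  }
  x
}

#' Crop a contiguous window of frames at a seeded random offset
#'
#' @param x A `skeleton_sequence`.
#' @param frames_out Output length `T_out <= T`. When `T_out == T` the
#'   offset is forced to zero and the sequence is returned unchanged.
#' @param seed Integer seed for the offset draw.
#' @return The cropped sequence (same label).
#' @export
augment_crop <- function(x, frames_out, seed = 1L) {
  T <- dim(x$values)[2]
  if (!is_count(frames_out, min = 2)) {
    abort_validation("frames_out must be an integer >= 2")
  }
  if (frames_out > T) {
    abort_validation("frames_out (%d) exceeds sequence length (%d)",
                     frames_out, T)
  }
  offset <- 0L
  if (frames_out < T) {
    withr::with_seed(seed, {
      offset <- sample.int(T - frames_out + 1L, 1L) - 1L
    })
  }
  x$values <- x$values[, offset + seq_len(frames_out), , drop = FALSE]
  x
}

resolve_layout <- function(x, layout) {
  if (is.null(layout)) layout <- x$layout
  if (is.character(layout)) layout <- skeleton_layout(layout)
  layout
}
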