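# Explicit preprocessing: body-centred translation and torso-length scale
# normalisation, the standard skeleton-GCN preparation step. Coordinates are
# stored un-normalised on disk; normalisation is an explicit, documented
# operation applied (by default) in the training pipeline.

#' Normalise a skeleton sequence
#'
#' Centres every frame on the pelvis (the layout's centre joints) and
#' divides all coordinates by the mean torso length, making the features
#' invariant to camera translation and subject scale.
#'
#' @param x A `skeleton_sequence`.
#' @param layout Layout name or object; defaults to the sequence's own.
#' @return The normalised `skeleton_sequence`.
#' @export
normalize_sequence <- function(x, layout = NULL) {
  layout <- resolve_layout(x, layout)
  v <- x$values  # (C, T, V)
  centre <- apply(v[, , layout$center_joints + 1L, drop = FALSE], c(1, 2), mean)
  v <- v - as.vector(centre)  # recycles over joints: (C,T) blocks
  lo <- apply(v[, , layout$torso_from + 1L, drop = FALSE], c(1, 2), mean)
  hi <- apply(v[, , layout$torso_to + 1L, drop = FALSE], c(1, 2), mean)
  torso <- mean(sqrt(colSums((hi - lo)^2)))
  if (!is.finite(torso) || torso <= 0) {
    abort_validation("degenerate torso length; cannot normalise")
  }
  x$values <- v / torso
  x
}

#' Remove each joint coordinate's temporal mean
#'
#' Subtracts, per channel and joint, the sequence's temporal mean, leaving
#' pure motion around zero. Used (by default) as the last preprocessing
#' step of the training pipeline: with motion-centred input, rectifying
#' activations turn oscillation amplitude into pooled features, which is
#' what makes the untrained near-identity network produce class-informative
#' embeddings.
#'
#' @param x A `skeleton_sequence`.
#' @return The motion-centred `skeleton_sequence`.
#' @export
center_temporal <- function(x) {
  v <- x$values  # (C, T, V)
  mu <- apply(v, c(1, 3), mean)
  x$values <- v - aperm(array(mu, c(dim(v)[1], dim(v)[3], dim(v)[2])),
                        c(1, 3, 2))
  x
}
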