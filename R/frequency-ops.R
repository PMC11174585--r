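# The frequency-domain graph convolution layer, exposed as four composable
# operations on single feature maps plus the fixed-window temporal
# convolution baseline. Feature maps are real arrays of shape
# (channels C, frames T, joints V). The spatial axis of the 2D Fourier
# transform is the channel-fastest flattening of (C, V), so S = C*V, and the
# temporal axis keeps floor(T/2)+1 bins by conjugate symmetry of real
# signals.

#' Parameters of a frequency-domain GCN layer
#'
#' Creates the learnable parameter set of one layer bound to a graph and a
#' feature shape: one weight per bone edge plus one per self-loop
#' (`edge_weights`, ordered bone edges first, then the V self-loops), a
#' spatial-frequency mask of length `S = channels * n_joints`
#' (`spatial_mask`), and a temporal-frequency mask of length
#' `floor(frames/2) + 1` (`temporal_mask`). All weights initialise to 1 and
#' the LeakyReLU slope to 0.01, so the untrained layer is a near-identity
#' spectral filter.
#'
#' @param graph A [skeleton_graph()].
#' @param channels,frames Feature-map channel and frame counts.
#' @param slope LeakyReLU negative slope used for the aggregation and the
#'   mask activations.
#' @return An `fgcn_params` object.
#' @export
fgcn_params <- function(graph, channels, frames, slope = 0.01) {
  stopifnot(inherits(graph, "skeleton_graph"))
  if (frames < 2) abort_validation("frames must be at least 2")
  structure(
    list(
      edge_weights = rep(1, nrow(graph$edges) + graph$n_joints),
      spatial_mask = rep(1, channels * graph$n_joints),
      temporal_mask = rep(1, frames %/% 2 + 1),
      slope = slope,
      channels = channels,
      frames = frames
    ),
    class = "fgcn_params"
  )
}

# Degree-normalised, edge-weighted aggregation matrix: row i mixes the
# features of i's neighbourhood (self-loop included), scaled by 1/d_i.
aggregation_matrix <- function(graph, edge_weights) {
  V <- graph$n_joints
  k <- nrow(graph$edges)
  if (length(edge_weights) != k + V) {
    abort_validation("edge_weights must have length n_edges + n_joints (= %d)", k + V)
  }
  M <- matrix(0, V, V)
  if (k > 0) {
    iu <- graph$edges[, 1] + 1L
    iv <- graph$edges[, 2] + 1L
    M[cbind(iu, iv)] <- edge_weights[seq_len(k)]
    M[cbind(iv, iu)] <- edge_weights[seq_len(k)]
  }
  diag(M) <- edge_weights[k + seq_len(V)]
  M / graph$degrees
}

#' Spatial graph aggregation
#'
#' For each channel and frame, replaces the feature of joint `i` by the
#' LeakyReLU of the degree-normalised, edge-weighted sum over its
#' neighbourhood (self-loop included):
#' `mu( (1/d_i) * sum_{j in N(i)} W_E(ij) x_j )`.
#'
#' @param x Real array `(C, T, V)`.
#' @param graph A [skeleton_graph()] with `V` joints.
#' @param params An [fgcn_params()] bound to `graph`.
#' @return Array of the same shape as `x`.
#' @export
spatial_aggregate <- function(x, graph, params) {
  d <- dim(x)
  if (length(d) != 3L || d[3] != graph$n_joints) {
    abort_validation("feature map joints (%s) do not match graph (%d joints)",
                     paste(d, collapse = "x"), graph$n_joints)
  }
  check_finite(x, "feature map")
  M <- aggregation_matrix(graph, params$edge_weights)
  xm <- matrix(aperm(x, c(3, 1, 2)), d[3], d[1] * d[2])
  z <- M %*% xm
  aperm(array(leaky_relu(z, params$slope), c(d[3], d[1], d[2])), c(2, 3, 1))
}

#' Forward 2D Fourier transform of a feature map
#'
#' Flattens `(C, V)` into the spatial axis (channel-fastest, `S = C*V`),
#' applies the orthonormally scaled two-dimensional DFT over (space, time)
#' and keeps only the `floor(T/2) + 1` non-negative temporal frequency bins;
#' the discarded half is redundant by conjugate symmetry of real input.
#'
#' @param x Real array `(C, T, V)` with `T >= 2`.
#' @return A `spectral_tensor`: list with complex `coeffs` (`S x F`),
#'   `source_T`, and the originating `shape`.
#' @export
to_frequency <- function(x) {
  d <- dim(x)
  if (length(d) != 3L) abort_validation("feature map must be a (C, T, V) array")
  if (d[2] < 2L) abort_validation("feature map must have at least 2 frames")
  check_finite(x, "feature map")
  S <- d[1] * d[3]
  T <- d[2]
  xm <- matrix(aperm(x, c(1, 3, 2)), S, T)
  Fz <- stats::fft(xm) / sqrt(S * T)
  Fbins <- T %/% 2 + 1L
  structure(
    list(coeffs = Fz[, seq_len(Fbins), drop = FALSE], source_T = T, shape = d),
    class = "spectral_tensor"
  )
}

#' @export
print.spectral_tensor <- function(x, ...) {
  cat(sprintf("<spectral_tensor> %d spatial x %d temporal bins (T = %d)\n",
              nrow(x$coeffs), ncol(x$coeffs), x$source_T))
  invisible(x)
}

# Activated mask factors shared by the reference and the compiled paths.
# The activated spatial mask is symmetrised across mirrored spatial
# frequency bins so the masked spectrum stays Hermitian and the inverse
# transform is exactly real.
spectral_factors <- function(params) {
  S <- length(params$spatial_mask)
  g <- mean(leaky_relu(params$edge_weights, params$slope))
  a <- leaky_relu(g * params$spatial_mask, params$slope)
  rev_idx <- c(1L, rev(seq_len(S - 1L) + 1L))
  list(
    spatial = (a + a[rev_idx]) / 2,
    temporal = leaky_relu(params$temporal_mask, params$slope)
  )
}

#' Learnable spectral weighting
#'
#' Multiplies every complex coefficient at spatial bin `s` and temporal bin
#' `t` by the real factor
#' `theta(mean(theta(W_E)) * W_A(s)) * theta(W_F(t))`:
#' a per-bin spatial mask modulated by the normalised summary of the learned
#' edge weights, times a per-bin temporal mask, both passed through
#' LeakyReLU. The activated spatial factor is averaged with its
#' frequency-reversed copy so the weighted spectrum remains conjugate
#' symmetric and the inverse transform real.
#'
#' @param xf A [to_frequency()] result.
#' @param params An [fgcn_params()] whose mask lengths match `xf`.
#' @param graph The [skeleton_graph()] the edge weights belong to
#'   (validation only).
#' @return A `spectral_tensor` of identical shape.
#' @export
apply_spectral_weights <- function(xf, params, graph) {
  stopifnot(inherits(xf, "spectral_tensor"))
  if (length(params$spatial_mask) != nrow(xf$coeffs)) {
    abort_validation("spatial mask length %d does not match %d spatial bins",
                     length(params$spatial_mask), nrow(xf$coeffs))
  }
  if (length(params$temporal_mask) != ncol(xf$coeffs)) {
    abort_validation("temporal mask length %d does not match %d temporal bins",
                     length(params$temporal_mask), ncol(xf$coeffs))
  }
  if (!missing(graph) && !is.null(graph)) {
    if (length(params$edge_weights) != nrow(graph$edges) + graph$n_joints) {
      abort_validation("edge weight vector does not match the graph")
    }
  }
  f <- spectral_factors(params)
  xf$coeffs <- xf$coeffs * outer(f$spatial, f$temporal)
  xf
}

#' Inverse 2D Fourier transform back to a feature map
#'
#' Reconstructs the redundant negative-frequency half from conjugate
#' symmetry, applies the orthonormal inverse transform and reshapes the
#' spatial axis back to `(C, V)`. The output is real; any imaginary residue
#' (numerically below 1e-9 for spectra of real signals) is discarded.
#'
#' @param xf A `spectral_tensor`.
#' @param target_shape Integer vector `(C, T, V)` with `C*V` equal to the
#'   spatial bin count and `T` equal to `xf$source_T`.
#' @return Real array `(C, T, V)`.
#' @export
from_frequency <- function(xf, target_shape = xf$shape) {
  stopifnot(inherits(xf, "spectral_tensor"))
  C <- target_shape[1]; T <- target_shape[2]; V <- target_shape[3]
  S <- nrow(xf$coeffs)
  Fbins <- ncol(xf$coeffs)
  if (S != C * V) {
    abort_validation("spatial bins (%d) do not factor as C*V = %d", S, C * V)
  }
  if (T != xf$source_T || Fbins != T %/% 2 + 1L) {
    abort_validation("temporal bins inconsistent with %d frames", T)
  }
  full <- matrix(0 + 0i, S, T)
  full[, seq_len(Fbins)] <- xf$coeffs
  if (T > 2L) {
    srev <- c(1L, rev(seq_len(S - 1L) + 1L))
    for (t in seq.int(Fbins + 1L, T)) {
      full[, t] <- Conj(xf$coeffs[srev, T - t + 2L])
    }
  }
  y <- stats::fft(full, inverse = TRUE) / sqrt(S * T)
  y <- Re(y)
  aperm(array(y, c(C, V, T)), c(1, 3, 2))
}

#' Frequency-domain GCN layer forward pass
#'
#' Composes [spatial_aggregate()], [to_frequency()],
#' [apply_spectral_weights()] and [from_frequency()]: graph aggregation in
#' the joint domain followed by learnable filtering in the 2D frequency
#' domain. With all-ones parameters the layer reduces to the LeakyReLU of
#' the degree-normalised neighbourhood mean.
#'
#' @inheritParams spatial_aggregate
#' @return Array shaped like `x`.
#' @export
fgcn_layer_forward <- function(x, graph, params) {
  a <- spatial_aggregate(x, graph, params)
  xf <- to_frequency(a)
  xf <- apply_spectral_weights(xf, params, graph)
  from_frequency(xf, dim(a))
}

#' Parameters of the fixed-window temporal convolution baseline
#'
#' @param channels Number of feature channels.
#' @param stride Temporal window length `s_d >= 1`.
#' @param kernel Optional `channels x stride` kernel matrix (default all
#'   ones).
#' @return A `tcn_params` object.
#' @export
tcn_params <- function(channels, stride, kernel = NULL) {
  if (!is_count(stride)) abort_validation("stride must be a positive integer")
  if (is.null(kernel)) kernel <- matrix(1, channels, stride)
  kernel <- as.matrix(kernel)
  if (nrow(kernel) != channels || ncol(kernel) != stride) {
    abort_validation("kernel must be channels x stride")
  }
  structure(list(kernel = kernel, stride = as.integer(stride)),
            class = "tcn_params")
}

#' Fixed-window temporal convolution baseline
#'
#' The comparison layer the frequency-domain filter is designed to improve
#' on: for each joint `i` and frame `t`, sums the kernel-weighted features
#' of all neighbours `j` (self-loop included) over the window
#' `t .. t+s_d-1`, with zero padding past the end of the sequence:
#' `Y_i(t) = sum_{j in N(i)} sum_{tau=0}^{s_d-1} W_t(c, tau) X_j(c, t+tau)`.
#'
#' @param x Real array `(C, T, V)`.
#' @param graph A [skeleton_graph()].
#' @param params A [tcn_params()] with `stride <= T`.
#' @return Array shaped like `x`.
#' @export
tcn_baseline_forward <- function(x, graph, params) {
  d <- dim(x)
  if (length(d) != 3L || d[3] != graph$n_joints) {
    abort_validation("feature map joints do not match graph")
  }
  if (params$stride > d[2]) {
    abort_validation("temporal stride %d exceeds %d frames", params$stride, d[2])
  }
  # neighbour sum (unnormalised, self-loop included), then temporal window
  xm <- matrix(aperm(x, c(3, 1, 2)), d[3], d[1] * d[2])
  nb <- aperm(array(graph$adjacency %*% xm, c(d[3], d[1], d[2])), c(2, 3, 1))
  out <- array(0, d)
  for (tau in seq_len(params$stride) - 1L) {
    t_in <- seq_len(d[2] - tau) + tau
    t_out <- seq_len(d[2] - tau)
    out[, t_out, ] <- out[, t_out, , drop = FALSE] +
      params$kernel[, tau + 1L] * nb[, t_in, , drop = FALSE]
  }
  out
}
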