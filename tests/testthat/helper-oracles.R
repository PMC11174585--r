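# Shared fixtures and independent oracles used across the suite.

# Random connected-ish undirected graph on V joints (path backbone plus
# random chords), 0-based edges.
random_graph <- function(V, extra = V %/% 2, seed = 1L) {
  withr::with_seed(seed, {
    edges <- cbind(0:(V - 2L), 1:(V - 1L))
    if (extra > 0 && V > 2) {
      for (i in seq_len(extra)) {
        pair <- sort(sample.int(V, 2L) - 1L)
        key <- paste(pair[1], pair[2])
        have <- paste(edges[, 1], edges[, 2])
        if (!(key %in% have)) edges <- rbind(edges, pair)
      }
    }
    skeleton_graph(edges, V)
  })
}

# Brute-force oracle for the degree-normalised, edge-weighted spatial
# aggregation: explicit loop over nodes and incident edges.
spatial_aggregate_oracle <- function(x, graph, params) {
  d <- dim(x)
  V <- graph$n_joints
  k <- nrow(graph$edges)
  out <- array(0, d)
  for (i in seq_len(V)) {
    acc <- array(0, d[1:2])
    # bone edges incident to i
    if (k > 0) {
      for (e in seq_len(k)) {
        u <- graph$edges[e, 1] + 1L
        v <- graph$edges[e, 2] + 1L
        if (u == i) acc <- acc + params$edge_weights[e] * x[, , v]
        if (v == i) acc <- acc + params$edge_weights[e] * x[, , u]
      }
    }
    acc <- acc + params$edge_weights[k + i] * x[, , i]  # self-loop
    out[, , i] <- leaky_relu(acc / graph$degrees[i], params$slope)
  }
  out
}

# O(N^2) direct 2D DFT with orthonormal scaling, half temporal spectrum.
naive_dft_oracle <- function(x) {
  d <- dim(x)
  S <- d[1] * d[3]
  T <- d[2]
  xm <- matrix(aperm(x, c(1, 3, 2)), S, T)
  Fb <- T %/% 2 + 1L
  out <- matrix(0 + 0i, S, Fb)
  for (ks in seq_len(S) - 1L) {
    for (kt in seq_len(Fb) - 1L) {
      acc <- 0 + 0i
      for (s in seq_len(S) - 1L) {
        for (t in seq_len(T) - 1L) {
          acc <- acc + xm[s + 1, t + 1] *
            exp(-2i * pi * (ks * s / S + kt * t / T))
        }
      }
      out[ks + 1, kt + 1] <- acc / sqrt(S * T)
    }
  }
  out
}

# Triple-loop oracle for the fixed-window temporal convolution baseline.
tcn_oracle <- function(x, graph, params) {
  d <- dim(x)
  out <- array(0, d)
  A <- graph$adjacency
  for (v in seq_len(d[3])) {
    nbrs <- which(A[v, ] > 0)
    for (t in seq_len(d[2])) {
      for (tau in seq_len(params$stride) - 1L) {
        if (t + tau > d[2]) next
        for (j in nbrs) {
          out[, t, v] <- out[, t, v] +
            params$kernel[, tau + 1L] * x[, t + tau, j]
        }
      }
    }
  }
  out
}

# Parseval check helper: total energy recovered from the half spectrum,
# accounting for the conjugate-symmetric bins that are not stored.
spectrum_energy <- function(xf) {
  T <- xf$source_T
  Fb <- ncol(xf$coeffs)
  w <- rep(2, Fb)
  w[1] <- 1
  if (T %% 2 == 0L) w[Fb] <- 1
  sum(t(Mod(xf$coeffs)^2) * w)
}

# Tiny toy model pieces shared by model/training tests.
toy_graph <- function() skeleton_graph(list(c(0, 1), c(1, 2), c(2, 3)), 4)

toy_partition <- function() {
  partition_scheme(list(
    global = list(all = 0:3),
    half = list(up = c(0, 1), lo = c(1, 2, 3)),
    limb = list(a = 0:1, b = 2:3)
  ))
}

toy_config <- function(variant = "fpgcn", frames = 8, n_classes = 3,
                       depth = 2, widths = c(4, 3, 3)) {
  model_config(graph = toy_graph(), partition = toy_partition(),
               channels_in = 2, n_classes = n_classes, frames = frames,
               widths = widths, depth = depth, variant = variant)
}

# Full-model numeric gradient check; returns the worst relative error over
# (a sample of) parameters. Parameters are jittered off the identity
# initialisation so no activation sits exactly at a kink.
numeric_grad_check <- function(variant, seed = 7, n_items = 4,
                               sample_n = NULL) {
  cfg <- toy_config(variant)
  m <- fpgcn_init(cfg, seed = seed)
  withr::with_seed(seed + 1, {
    pv <- fpgait:::param_vector(m$params)
    pv <- pv + rnorm(length(pv), 0, 0.15)
    m$params <- fpgait:::param_relist(pv, m$params)
    X <- array(rnorm(2 * 4 * 8 * n_items), c(2, 4, 8, n_items))
    labels <- sample.int(3, n_items, replace = TRUE)
  })
  fw <- fpgait:::network_forward(m, X, keep_cache = TRUE)
  ds <- fpgait:::smoothed_ce_grad(fw$scores, labels, 0.1)
  gr <- fpgait:::network_backward(m, fw, ds)
  gv <- unlist(fpgait:::map_params(
    m$params, gr, function(w, g) if (is.null(g)) w * 0 else g),
    use.names = FALSE)
  f <- function(v) {
    m2 <- m
    m2$params <- fpgait:::param_relist(v, m$params)
    label_smoothed_loss(
      t(fpgait:::network_forward(m2, X, keep_cache = TRUE)$scores),
      labels, 0.1)
  }
  idx <- seq_along(pv)
  if (!is.null(sample_n) && sample_n < length(pv)) {
    idx <- withr::with_seed(seed, sort(sample(length(pv), sample_n)))
  }
  fd <- function(i, e) {
    vp <- pv; vp[i] <- vp[i] + e
    vm <- pv; vm[i] <- vm[i] - e
    (f(vp) - f(vm)) / (2 * e)
  }
  num <- vapply(idx, fd, numeric(1), e = 1e-5)
  rel <- abs(num - gv[idx]) / pmax(1e-6, abs(num) + abs(gv[idx]))
  # differences below the finite-difference round-off floor
  # (~eps_machine * |loss| / h) are indistinguishable from noise
  rel[abs(num - gv[idx]) < 1e-8] <- 0
  # a coordinate whose +/-eps evaluations straddle a ReLU/LeakyReLU kink has
  # no valid finite-difference estimate: confirm suspect coordinates with a
  # 10x smaller step and drop those where the two estimates disagree (the
  # point is non-smooth), keeping ones where they agree (a true mismatch)
  for (j in which(rel > 5e-5)) {
    num2 <- fd(idx[j], 1e-6)
    if (abs(num2 - num[j]) > 1e-3 * pmax(1e-6, abs(num[j]) + abs(num2))) {
      rel[j] <- 0
    } else {
      rel[j] <- abs(num2 - gv[idx[j]]) /
        pmax(1e-6, abs(num2) + abs(gv[idx[j]]))
    }
  }
  max(rel)
}

make_tiny_dataset <- function(n_per_class = 6, frames = 24, seed = 1) {
  specs <- list(
    gait_class_spec(1, "slow", cadence_hz = 0.9,
                    amplitude = c(arm = 0.1, leg = 0.15, torso = 0.01)),
    gait_class_spec(2, "fast", cadence_hz = 3.0,
                    amplitude = c(arm = 0.25, leg = 0.45, torso = 0.04),
                    asymmetry = 0.6)
  )
  generate_dataset(specs, n_per_class, noise_spec(jitter_sd = 0.003),
                   frames = frames, seed = seed)
}

tiny_model_config <- function(variant = "fpgcn", frames = 24) {
  model_config(layout = "kinect25", n_classes = 2, frames = frames,
               widths = c(6, 5, 4), depth = 1, variant = variant)
}

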