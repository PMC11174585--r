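test_that("spatial aggregation matches hand computation and fixed points", {
  # node 0 sees its own value 2 (self-loop) and a neighbour's 4; d_0 = 2
  g <- skeleton_graph(list(c(0, 1)), 2)
  pr <- fgcn_params(g, channels = 1, frames = 2)
  x <- array(c(2, 2, 4, 4), c(1, 2, 2))
  out <- spatial_aggregate(x, g, pr)
  expect_equal(out[1, , 1], c(3, 3))

  # zero input is a fixed point of the LeakyReLU aggregation
  z <- array(0, c(2, 4, 2))
  expect_equal(spatial_aggregate(z, g, fgcn_params(g, 2, 4)), z)

  expect_error(spatial_aggregate(array(0, c(1, 2, 3)), g, pr),
               class = "fpgait_validation_error")
})

test_that("spatial aggregation equals the brute-force edge-loop oracle", {
  for (seed in 1:6) {
    V <- 3 + seed
    g <- random_graph(V, seed = seed)
    pr <- fgcn_params(g, channels = 2, frames = 5)
    withr::with_seed(seed * 11, {
      pr$edge_weights <- rnorm(length(pr$edge_weights))
      x <- array(rnorm(2 * 5 * V), c(2, 5, V))
    })
    expect_equal(spatial_aggregate(x, g, pr),
                 spatial_aggregate_oracle(x, g, pr), tolerance = 1e-12)
  }
})

test_that("forward transform has the expected spectra", {
  # constant input: all energy in the DC bin with orthonormal magnitude
  x <- array(2.5, c(2, 8, 3))
  xf <- to_frequency(x)
  expect_equal(dim(xf$coeffs), c(6L, 5L))
  expect_equal(Mod(xf$coeffs[1, 1]), 2.5 * sqrt(6 * 8))
  expect_lt(max(Mod(xf$coeffs[-1])), 1e-10)
  expect_lt(max(Mod(xf$coeffs[1, -1])), 1e-10)

  # pure temporal cosine at integer frequency k: energy confined to bin k
  T <- 16; k <- 3
  sig <- cos(2 * pi * k * (0:(T - 1)) / T)
  x <- array(0, c(2, T, 3))
  for (v in 1:3) for (c in 1:2) x[c, , v] <- sig
  xf <- to_frequency(x)
  mag_t <- colSums(Mod(xf$coeffs)^2)
  expect_gt(mag_t[k + 1] / sum(mag_t), 1 - 1e-12)

  expect_error(to_frequency(array(NaN, c(1, 4, 1))),
               class = "fpgait_validation_error")
})

test_that("forward transform matches the naive O(N^2) DFT oracle", {
  withr::with_seed(5, x <- array(rnorm(2 * 8 * 3), c(2, 8, 3)))
  expect_equal(to_frequency(x)$coeffs, naive_dft_oracle(x), tolerance = 1e-10)
  # odd frame count stores floor(T/2)+1 bins
  withr::with_seed(6, x7 <- array(rnorm(2 * 7 * 3), c(2, 7, 3)))
  expect_equal(ncol(to_frequency(x7)$coeffs), 4L)
  expect_equal(to_frequency(x7)$coeffs, naive_dft_oracle(x7),
               tolerance = 1e-10)
})

test_that("spectral weighting applies activated separable masks", {
  g <- toy_graph()
  withr::with_seed(2, x <- array(rnorm(2 * 8 * 4), c(2, 8, 4)))
  pr <- fgcn_params(g, 2, 8)
  xf <- to_frequency(x)

  # all-ones parameters are an identity mask
  expect_equal(apply_spectral_weights(xf, pr, g)$coeffs, xf$coeffs)

  # temporal mask selecting only bin 0: inverse is the per-node temporal mean
  pr0 <- pr
  pr0$temporal_mask <- c(1, rep(0, 4))
  y <- from_frequency(apply_spectral_weights(xf, pr0, g), dim(x))
  means <- apply(x, c(1, 3), mean)
  for (t in 1:8) expect_equal(y[, t, ], means, tolerance = 1e-10)

  # random masks equal the scalar elementwise oracle
  withr::with_seed(3, {
    pr$edge_weights <- rnorm(length(pr$edge_weights), 1, 0.3)
    pr$spatial_mask <- rnorm(8, 1, 0.5)
    pr$temporal_mask <- rnorm(5, 1, 0.5)
  })
  got <- apply_spectral_weights(xf, pr, g)$coeffs
  slope <- pr$slope
  gmean <- mean(leaky_relu(pr$edge_weights, slope))
  a <- leaky_relu(gmean * pr$spatial_mask, slope)
  a <- (a + a[c(1, 8:2)]) / 2
  b <- leaky_relu(pr$temporal_mask, slope)
  expected <- xf$coeffs
  for (s in 1:8) for (t in 1:5) {
    expected[s, t] <- xf$coeffs[s, t] * a[s] * b[t]
  }
  expect_equal(got, expected, tolerance = 1e-12)

  bad <- pr; bad$temporal_mask <- rep(1, 7)
  expect_error(apply_spectral_weights(xf, bad, g),
               class = "fpgait_validation_error")
})

test_that("the transform round trip is the identity and preserves energy", {
  for (spec in list(c(2, 8, 3), c(1, 7, 5), c(3, 31, 4))) {
    withr::with_seed(sum(spec), x <- array(rnorm(prod(spec)), spec))
    xf <- to_frequency(x)
    expect_lt(max(abs(from_frequency(xf, spec) - x)), 1e-6)
    expect_lt(abs(sum(x^2) - spectrum_energy(xf)) / sum(x^2), 1e-10)
  }
  # all-zero spectrum inverts to zero
  xf0 <- to_frequency(array(0, c(2, 6, 2)))
  expect_equal(from_frequency(xf0), array(0, c(2, 6, 2)))
  expect_error(from_frequency(to_frequency(array(0, c(2, 6, 2))), c(2, 8, 2)),
               class = "fpgait_validation_error")
})

test_that("the composed layer reduces to the aggregation under identity masks", {
  g <- toy_graph()
  pr <- fgcn_params(g, 2, 8)
  withr::with_seed(4, x <- array(rnorm(2 * 8 * 4), c(2, 8, 4)))
  expect_equal(fgcn_layer_forward(x, g, pr), spatial_aggregate(x, g, pr),
               tolerance = 1e-9)
  # self-loop-only graph with unit weights: layer output is mu(x)
  g1 <- skeleton_graph(list(), 1)
  pr1 <- fgcn_params(g1, 2, 8)
  x1 <- array(rnorm(2 * 8 * 1), c(2, 8, 1))
  expect_equal(fgcn_layer_forward(x1, g1, pr1), leaky_relu(x1, pr1$slope),
               tolerance = 1e-9)
})

test_that("the spectral layer is equivariant to circular time shifts", {
  g <- toy_graph()
  pr <- fgcn_params(g, 2, 12)
  withr::with_seed(9, {
    pr$edge_weights <- rnorm(length(pr$edge_weights), 1, 0.2)
    pr$spatial_mask <- rnorm(8, 1, 0.4)
    pr$temporal_mask <- rnorm(7, 1, 0.4)
    x <- array(rnorm(2 * 12 * 4), c(2, 12, 4))
  })
  shift <- 5L
  xs <- x[, c((shift + 1):12, 1:shift), ]
  y <- fgcn_layer_forward(x, g, pr)
  ys <- fgcn_layer_forward(xs, g, pr)
  expect_equal(ys, y[, c((shift + 1):12, 1:shift), ], tolerance = 1e-9)
})

test_that("the temporal-convolution baseline matches its oracles", {
  # stride 1, unit kernel, self-loop-only graph: identity
  g1 <- skeleton_graph(list(), 1)
  x1 <- array(rnorm(2 * 6), c(2, 6, 1))
  expect_equal(tcn_baseline_forward(x1, g1, tcn_params(2, 1)), x1)

  # constant input c, stride 3, unit kernel: 3*k*c at interior frames,
  # where k counts incident edges including the self-loop
  g <- skeleton_graph(list(c(0, 1), c(1, 2)), 3)
  cst <- 1.5
  x <- array(cst, c(1, 10, 3))
  out <- tcn_baseline_forward(x, g, tcn_params(1, 3))
  expect_equal(out[1, 1:8, 2], rep(3 * 3 * cst, 8))  # middle node: k = 3
  expect_equal(out[1, 1:8, 1], rep(3 * 2 * cst, 8))  # end node: k = 2

  # random instance against the triple-loop oracle
  for (seed in 1:4) {
    V <- 3 + seed
    g <- random_graph(V, seed = seed + 20)
    pr <- tcn_params(2, 4, kernel = matrix(rnorm(8), 2, 4))
    withr::with_seed(seed, x <- array(rnorm(2 * 7 * V), c(2, 7, V)))
    expect_equal(tcn_baseline_forward(x, g, pr), tcn_oracle(x, g, pr),
                 tolerance = 1e-12)
  }

  expect_error(tcn_baseline_forward(x1, g1, tcn_params(2, 9)),
               class = "fpgait_validation_error")
})
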