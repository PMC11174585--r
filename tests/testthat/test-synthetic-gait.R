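test_that("degenerate specs give a static repeated pose", {
  spec <- gait_class_spec(1, "still", cadence_hz = 1,
                          amplitude = c(arm = 0, leg = 0, torso = 0))
  s <- generate_sequence(spec, noise_spec(), frames = 12, fps = 30, seed = 1)
  expect_equal(dim(s$values), c(3L, 12L, 25L))
  for (t in 2:12) expect_equal(s$values[, t, ], s$values[, 1, ])
})

test_that("configured cadence is recovered at the nearest frequency bin", {
  spec <- gait_class_spec(1, "walk", cadence_hz = 1.0,
                          amplitude = c(arm = 0.2, leg = 0.3, torso = 0))
  s <- generate_sequence(spec, noise_spec(), frames = 120, fps = 30, seed = 2)
  m <- measure_cadence(s)
  expect_equal(m$n_bins, 61L)
  expect_equal(m$bin, 4L)  # 1.0 Hz at 0.25 Hz resolution
  expect_equal(m$freq_hz, 1.0)
})

test_that("configured asymmetry ratio is recovered exactly without noise", {
  spec <- gait_class_spec(1, "asym", cadence_hz = 1.0, asymmetry = 0.5,
                          amplitude = c(arm = 0.2, leg = 0.3, torso = 0))
  s <- generate_sequence(spec, noise_spec(), frames = 120, fps = 30, seed = 3)
  expect_equal(measure_asymmetry(s), 0.5, tolerance = 1e-6)
})

test_that("cadence at or above Nyquist is rejected", {
  spec <- gait_class_spec(1, "fast", cadence_hz = 15)
  expect_error(generate_sequence(spec, noise_spec(), 60, fps = 30, seed = 1),
               class = "fpgait_validation_error")
  expect_error(gait_class_spec(1, "bad", cadence_hz = 1, asymmetry = 0),
               class = "fpgait_validation_error")
})

test_that("datasets are balanced, labelled and reproducible", {
  specs <- gait_benchmark_specs()
  ds <- generate_dataset(specs, 5, benchmark_noise(), frames = 60, seed = 9)
  expect_s3_class(ds, "gait_dataset")
  expect_equal(nrow(ds), 20L)
  expect_equal(as.integer(table(ds$class_id)), rep(5L, 4))
  expect_setequal(unique(ds$class_id), 1:4)

  ds2 <- generate_dataset(specs, 5, benchmark_noise(), frames = 60, seed = 9)
  for (i in seq_len(nrow(ds))) {
    expect_identical(ds$seq[[i]]$values, ds2$seq[[i]]$values)
  }
  ds3 <- generate_dataset(specs, 5, benchmark_noise(), frames = 60, seed = 10)
  expect_true(any(ds$seq[[1]]$values != ds3$seq[[1]]$values))

  expect_error(generate_dataset(specs[1], 5, noise_spec(), frames = 60),
               class = "fpgait_validation_error")
  expect_error(generate_dataset(specs, 0, noise_spec(), frames = 60),
               class = "fpgait_validation_error")
})

test_that("dropout fill policies behave as documented", {
  spec <- gait_class_spec(1, "drop", cadence_hz = 1.2)
  nz <- noise_spec(jitter_sd = 0, dropout_prob = 0.3, dropout_fill = "zero")
  s <- generate_sequence(spec, nz, frames = 40, fps = 30, seed = 4)
  # zero-fill leaves exact zero columns where joints were lost
  zero_cols <- apply(s$values, c(2, 3), function(v) all(v == 0))
  expect_gt(sum(zero_cols), 0)
  nh <- noise_spec(jitter_sd = 0, dropout_prob = 0.3, dropout_fill = "hold")
  sh <- generate_sequence(spec, nh, frames = 40, fps = 30, seed = 4)
  expect_true(all(is.finite(sh$values)))
  expect_false(any(apply(sh$values, c(2, 3), function(v) all(v == 0))))
})

test_that("mirroring is an involution that inverts the asymmetry ratio", {
  spec <- gait_class_spec(2, "hemi", cadence_hz = 1.1, asymmetry = 0.6,
                          amplitude = c(arm = 0.2, leg = 0.3, torso = 0))
  s <- generate_sequence(spec, noise_spec(), frames = 120, fps = 30, seed = 5)
  sm <- augment_mirror(s)
  expect_equal(sm$label, s$label)
  expect_identical(augment_mirror(sm)$values, s$values)
  expect_equal(measure_asymmetry(sm), 1 / 0.6, tolerance = 1e-6)

  # a laterally symmetric static pose is a fixed point of mirroring
  still <- generate_sequence(
    gait_class_spec(1, "still", cadence_hz = 1,
                    amplitude = c(arm = 0, leg = 0, torso = 0)),
    noise_spec(), frames = 6, fps = 30, seed = 6)
  expect_equal(augment_mirror(still)$values, still$values, tolerance = 1e-12)
})

test_that("channel flip, noise and crop behave as documented", {
  spec <- gait_class_spec(3, "walk", cadence_hz = 1.5)
  s <- generate_sequence(spec, noise_spec(), frames = 120, fps = 30, seed = 7)

  sf <- augment_channel_flip(s)
  expect_equal(sf$label, s$label)
  expect_equal(sf$values[1, , ], s$values[3, , ])
  expect_identical(augment_channel_flip(sf)$values, s$values)
  expect_error(augment_channel_flip(s, c(1, 1, 2)),
               class = "fpgait_validation_error")

  # sd = 0 noise and full-length crop are identities
  expect_identical(augment_noise(s, 0)$values, s$values)
  expect_identical(augment_crop(s, 120)$values, s$values)
  expect_error(augment_crop(s, 150), class = "fpgait_validation_error")

  sn <- augment_noise(s, 0.05, seed = 8)
  expect_equal(sn$label, s$label)
  expect_true(all(is.finite(sn$values)))
  expect_identical(augment_noise(s, 0.05, seed = 8)$values, sn$values)

  # a crop retains the cadence peak within one frequency bin
  sc <- augment_crop(s, 90, seed = 9)
  expect_equal(dim(sc$values)[2], 90L)
  f_full <- measure_cadence(s)$freq_hz
  f_crop <- measure_cadence(sc)$freq_hz
  expect_lte(abs(f_full - f_crop), 30 / 90 + 1e-9)  # one bin of the window
})

test_that("augmentations preserve label, rank and finiteness", {
  ds <- generate_dataset(gait_benchmark_specs(), 2, benchmark_noise(),
                         frames = 60, seed = 11)
  for (i in seq_len(nrow(ds))) {
    s <- ds$seq[[i]]
    for (aug in list(augment_mirror(s), augment_channel_flip(s),
                     augment_noise(s, 0.02, seed = i),
                     augment_crop(s, 40, seed = i))) {
      expect_equal(aug$label, s$label)
      expect_length(dim(aug$values), 3L)
      expect_true(all(is.finite(aug$values)))
    }
  }
})

test_that("cadence-separated classes are 1-NN separable on FFT magnitudes", {
  # two specs >= 2 frequency bins apart, noise off
  specs <- list(
    gait_class_spec(1, "a", cadence_hz = 1.0,
                    amplitude = c(arm = 0.2, leg = 0.3, torso = 0)),
    gait_class_spec(2, "b", cadence_hz = 1.6,
                    amplitude = c(arm = 0.2, leg = 0.3, torso = 0))
  )
  ds <- generate_dataset(specs, 8, noise_spec(), frames = 120, seed = 13)
  lay <- skeleton_layout("kinect25")
  v <- lay$measure_joints$right_ankle + 1L
  feats <- t(vapply(ds$seq, function(s) {
    sig <- s$values[lay$forward_channel, , v]
    Mod(stats::fft(sig - mean(sig)))[1:61]
  }, numeric(61)))
  # leave-one-out 1-nearest-neighbour
  preds <- vapply(seq_len(nrow(feats)), function(i) {
    dists <- colSums((t(feats[-i, ]) - feats[i, ])^2)
    ds$class_id[-i][which.min(dists)]
  }, integer(1))
  expect_equal(preds, ds$class_id)
})

test_that("the nine shipped phenotypes are valid and distinct", {
  classes <- default_gait_classes()
  expect_length(classes, 9L)
  expect_setequal(vapply(classes, function(s) s$class_id, integer(1)), 1:9)
  cadences <- vapply(classes, function(s) s$cadence_hz, numeric(1))
  expect_true(all(cadences > 0 & cadences < 15))
  for (spec in classes) {
    s <- generate_sequence(spec, noise_spec(), frames = 30, fps = 30, seed = 1)
    expect_true(all(is.finite(s$values)))
  }
})

test_that("normalisation centres the pelvis and scales the torso", {
  ds <- generate_dataset(gait_benchmark_specs(), 1, benchmark_noise(),
                         frames = 30, seed = 15)
  lay <- skeleton_layout("kinect25")
  sn <- normalize_sequence(ds$seq[[1]])
  centre <- apply(sn$values[, , lay$center_joints + 1L, drop = FALSE],
                  c(1, 2), mean)
  expect_lt(max(abs(centre)), 1e-12)
  lo <- apply(sn$values[, , lay$torso_from + 1L, drop = FALSE], c(1, 2), mean)
  hi <- apply(sn$values[, , lay$torso_to + 1L, drop = FALSE], c(1, 2), mean)
  expect_equal(mean(sqrt(colSums((hi - lo)^2))), 1, tolerance = 1e-12)
  # motion centring removes every joint's temporal mean
  sc <- center_temporal(sn)
  expect_lt(max(abs(apply(sc$values, c(1, 3), mean))), 1e-12)
})
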