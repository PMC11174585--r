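# Synthetic pathological-gait simulator. Kinematics are phenomenological:
# limb joints follow phase-opposed sinusoids at the class cadence, with the
# left side scaled by an asymmetry ratio, cadence modulated by a slow speed
# drift, an optional high-frequency tremor overlay, and pose-estimation
# noise (coordinate jitter and joint dropout) applied last. The goal is
# class-discriminable frequency/asymmetry structure, not anatomical
# fidelity.

#' Parametric description of one synthetic gait phenotype
#'
#' @param class_id Integer class label (1-based).
#' @param name Class name.
#' @param cadence_hz Step frequency in Hz (fundamental of the limb
#'   oscillation); must stay below the Nyquist frequency of the sampling
#'   rate at generation time.
#' @param amplitude Named numeric vector of oscillation amplitudes in
#'   coordinate units (metres) per joint group: `arm`, `leg`, `torso`
#'   (vertical bounce).
#' @param asymmetry Left/right amplitude ratio in (0, 1]; left-side limb
#'   amplitudes are scaled by this factor.
#' @param speed_drift Fractional cadence modulation over the sequence (one
#'   slow sinusoidal cycle); 0.1 means the instantaneous cadence wanders
#'   +/-10%.
#' @param tremor_hz,tremor_amplitude Optional high-frequency sinusoidal
#'   overlay on the limb joints (Hz / metres).
#' @param trunk_lean Forward trunk lean in radians (static postural offset
#'   of joints above the pelvis).
#' @return A `gait_class_spec` object.
#' @export
gait_class_spec <- function(class_id, name = paste0("class_", class_id),
                            cadence_hz,
                            amplitude = c(arm = 0.2, leg = 0.3, torso = 0.03),
                            asymmetry = 1, speed_drift = 0,
                            tremor_hz = 0, tremor_amplitude = 0,
                            trunk_lean = 0) {
  if (!is.numeric(cadence_hz) || cadence_hz <= 0) {
    abort_validation("cadence_hz must be positive")
  }
  if (asymmetry <= 0 || asymmetry > 1) {
    abort_validation("asymmetry ratio must be in (0, 1]")
  }
  amp <- c(arm = 0.2, leg = 0.3, torso = 0.03)
  amp[names(amplitude)] <- amplitude
  structure(
    list(class_id = as.integer(class_id), name = name,
         cadence_hz = cadence_hz, amplitude = amp, asymmetry = asymmetry,
         speed_drift = speed_drift, tremor_hz = tremor_hz,
         tremor_amplitude = tremor_amplitude, trunk_lean = trunk_lean),
    class = "gait_class_spec"
  )
}

#' Pose-estimation noise model
#'
#' @param jitter_sd Standard deviation of i.i.d. Gaussian coordinate noise
#'   (metres); emulates per-frame keypoint localisation error.
#' @param dropout_prob Per-joint per-frame probability that the joint is
#'   lost by the tracker, in `[0, 1)`.
#' @param dropout_fill `"hold"` (carry the last observed position, the
#'   default tracker-like behaviour) or `"zero"`.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(jitter_sd = 0, dropout_prob = 0,
                       dropout_fill = c("hold", "zero")) {
  if (jitter_sd < 0) abort_validation("jitter_sd must be >= 0")
  if (dropout_prob < 0 || dropout_prob >= 1) {
    abort_validation("dropout_prob must be in [0, 1)")
  }
  structure(
    list(jitter_sd = jitter_sd, dropout_prob = dropout_prob,
         dropout_fill = match.arg(dropout_fill)),
    class = "noise_spec"
  )
}

#' Generate one synthetic skeleton gait sequence
#'
#' Deterministic for a fixed seed. Limb joints oscillate along the walking
#' direction at the class cadence with left/right phase opposition (arms in
#' counter-phase with the ipsilateral leg) and distal joints swinging more;
#' left amplitudes are scaled by the asymmetry ratio; the instantaneous
#' cadence is modulated by `speed_drift`; tremor is added as a second
#' sinusoid on the limbs; jitter and dropout are applied last.
#'
#' @param spec A [gait_class_spec()].
#' @param noise A [noise_spec()] (default: noise-free).
#' @param frames Number of frames `T >= 2`.
#' @param fps Sampling rate (frames/second).
#' @param layout Layout name or object (default `"kinect25"`).
#' @param seed Integer seed.
#' @param phase Initial gait phase in radians.
#' @return A `skeleton_sequence`: list with `values` (C x T x V array),
#'   `fps`, `label`, `class_name`, `subject_id` and `provenance`.
#' @export
generate_sequence <- function(spec, noise = noise_spec(), frames, fps = 30,
                              layout = "kinect25", seed = 1L, phase = 0) {
  stopifnot(inherits(spec, "gait_class_spec"), inherits(noise, "noise_spec"))
  if (!is_count(frames, min = 2)) abort_validation("frames must be >= 2")
  if (is.character(layout)) layout <- skeleton_layout(layout)
  if (spec$cadence_hz >= fps / 2) {
    abort_validation("cadence %.2f Hz is at or above Nyquist (fps %.1f)",
                     spec$cadence_hz, fps)
  }
  if (spec$tremor_amplitude > 0 && spec$tremor_hz >= fps / 2) {
    abort_validation("tremor frequency is at or above Nyquist")
  }
  C <- layout$n_channels
  V <- layout$graph$n_joints
  tau <- (seq_len(frames) - 1) / fps
  duration <- frames / fps
  # integrated phase of a sinusoidally modulated cadence
  phi <- phase + 2 * pi * spec$cadence_hz *
    (tau + spec$speed_drift * (duration / (2 * pi)) *
       (1 - cos(2 * pi * tau / duration)))
  values <- array(rep(layout$pose, frames), c(C, V, frames))
  fwd <- layout$forward_channel
  vert <- layout$vertical_channel
  amp_part <- c(arm = unname(spec$amplitude["arm"]),
                leg = unname(spec$amplitude["leg"]),
                torso = 0, head = 0)
  phase_joint <- ifelse(layout$part == "leg",
                        ifelse(layout$side == "L", pi, 0),
                        ifelse(layout$side == "L", 0, pi))
  side_factor <- ifelse(layout$side == "L", spec$asymmetry, 1)
  pelvis_y <- mean(layout$pose[vert, layout$center_joints + 1L])
  for (v in seq_len(V)) {
    a <- amp_part[[layout$part[v]]] * layout$swing[v] * side_factor[v]
    if (a > 0) {
      values[fwd, v, ] <- values[fwd, v, ] + a * sin(phi + phase_joint[v])
    }
    if (spec$tremor_amplitude > 0 && layout$swing[v] > 0) {
      values[fwd, v, ] <- values[fwd, v, ] +
        spec$tremor_amplitude * layout$swing[v] *
        sin(2 * pi * spec$tremor_hz * tau + 0.7 * v)
    }
    if (spec$trunk_lean != 0) {
      h <- layout$pose[vert, v] - pelvis_y
      if (h > 0) values[fwd, v, ] <- values[fwd, v, ] + sin(spec$trunk_lean) * h
    }
  }
  # vertical bounce at step frequency, shared by all joints
  if (spec$amplitude[["torso"]] > 0) {
    bounce <- spec$amplitude[["torso"]] * sin(2 * phi)
    values[vert, , ] <- values[vert, , ] + rep(bounce, each = V)
  }
  withr::with_seed(seed, {
    if (noise$jitter_sd > 0) {
      values <- values + rnorm(length(values), sd = noise$jitter_sd)
    }
    if (noise$dropout_prob > 0) {
      lost <- matrix(runif(V * frames) < noise$dropout_prob, V, frames)
      for (v in seq_len(V)) {
        for (t in seq_len(frames)) {
          if (lost[v, t]) {
            values[, v, t] <- if (noise$dropout_fill == "zero") {
              0
            } else if (t == 1L) {
              layout$pose[, v]
            } else {
              values[, v, t - 1L]
            }
          }
        }
      }
    }
  })
  structure(
    list(
      values = aperm(values, c(1, 3, 2)),  # (C, T, V)
      fps = fps,
      label = spec$class_id,
      class_name = spec$name,
      subject_id = NA_character_,
      layout = layout$name,
      provenance = list(spec = spec, noise = noise, seed = as.integer(seed),
                        phase = phase)
    ),
    class = "skeleton_sequence"
  )
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<skeleton_sequence> %s: C=%d T=%d V=%d @ %g fps (label %s)\n",
    x$class_name %||% "?", d[1], d[2], d[3], x$fps,
    x$label %||% NA
  ))
  invisible(x)
}

#' Generate a balanced labelled dataset of synthetic gait sequences
#'
#' Produces `n_per_class` sequences per class spec, with per-sequence seeds
#' derived deterministically from `seed`. Mild per-sequence variability
#' (cadence and amplitude scale factors, random initial phase) emulates
#' inter-trial variation within a gait class.
#'
#' @param class_specs List of [gait_class_spec()] objects (>= 2 classes).
#' @param n_per_class Sequences per class (>= 1).
#' @param noise A [noise_spec()].
#' @param frames,fps,layout As in [generate_sequence()].
#' @param seed Integer master seed.
#' @param cadence_jitter,amplitude_jitter Relative standard deviations of
#'   the per-sequence cadence and amplitude scale factors.
#' @return A `gait_dataset` tibble with columns `sequence_id`, `class_id`,
#'   `class_name`, `subject_id`, `seed` and the list-column `seq` of
#'   `skeleton_sequence` objects; layout/fps/frames stored as attributes.
#' @export
generate_dataset <- function(class_specs, n_per_class, noise = noise_spec(),
                             frames = 120, fps = 30, layout = "kinect25",
                             seed = 1L, cadence_jitter = 0.03,
                             amplitude_jitter = 0.05) {
  if (length(class_specs) < 2L) abort_validation("at least 2 classes required")
  if (!is_count(n_per_class)) abort_validation("n_per_class must be >= 1")
  if (is.character(layout)) layout <- skeleton_layout(layout)
  rows <- list()
  idx <- 0L
  for (k in seq_along(class_specs)) {
    spec <- class_specs[[k]]
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      sseed <- derive_seed(seed, idx)
      spec_i <- spec
      ph <- 0
      withr::with_seed(derive_seed(sseed, 0L), {
        spec_i$cadence_hz <- spec$cadence_hz *
          exp(rnorm(1, 0, cadence_jitter))
        spec_i$amplitude <- spec$amplitude *
          exp(rnorm(length(spec$amplitude), 0, amplitude_jitter))
        ph <- runif(1, 0, 2 * pi)
      })
      s <- generate_sequence(spec_i, noise, frames, fps, layout,
                             seed = sseed, phase = ph)
      s$subject_id <- sprintf("sim_%02d_%03d", k, i)
      rows[[idx]] <- tibble::tibble(
        sequence_id = idx, class_id = spec$class_id,
        class_name = spec$name, subject_id = s$subject_id,
        seed = sseed, seq = list(s)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "layout") <- layout$name
  attr(out, "fps") <- fps
  attr(out, "frames") <- as.integer(frames)
  class(out) <- c("gait_dataset", class(out))
  out
}

#' The nine shipped synthetic gait phenotypes
#'
#' Illustrative parameterisations named after commonly described gait
#' classes (normal, steppage, waddling, ataxic, scissors, festinating,
#' hemiplegic, choreic, antalgic). The parameters encode the coarse
#' phenomenology a clinician would name first -- cadence, limb amplitude,
#' left/right asymmetry, rhythm irregularity, tremor -- and are not
#' clinically validated.
#'
#' @return Named list of [gait_class_spec()] objects.
#' @export
default_gait_classes <- function() {
  list(
    normal = gait_class_spec(1, "normal", cadence_hz = 1.85,
      amplitude = c(arm = 0.20, leg = 0.30, torso = 0.03),
      asymmetry = 1, speed_drift = 0.02),
    steppage = gait_class_spec(2, "steppage", cadence_hz = 1.6,
      amplitude = c(arm = 0.15, leg = 0.42, torso = 0.03),
      asymmetry = 0.95, speed_drift = 0.04),
    wadding = gait_class_spec(3, "wadding", cadence_hz = 1.5,
      amplitude = c(arm = 0.18, leg = 0.26, torso = 0.08),
      asymmetry = 0.95, speed_drift = 0.04),
    ataxic = gait_class_spec(4, "ataxic", cadence_hz = 1.35,
      amplitude = c(arm = 0.22, leg = 0.32, torso = 0.05),
      asymmetry = 0.85, speed_drift = 0.25),
    scissors = gait_class_spec(5, "scissors", cadence_hz = 1.4,
      amplitude = c(arm = 0.16, leg = 0.18, torso = 0.04),
      asymmetry = 0.9, speed_drift = 0.05),
    festinating = gait_class_spec(6, "festinating", cadence_hz = 2.6,
      amplitude = c(arm = 0.08, leg = 0.14, torso = 0.02),
      asymmetry = 0.95, speed_drift = 0.08, trunk_lean = 0.15),
    hemiplegic = gait_class_spec(7, "hemiplegic", cadence_hz = 1.3,
      amplitude = c(arm = 0.18, leg = 0.3, torso = 0.04),
      asymmetry = 0.45, speed_drift = 0.05),
    chorea = gait_class_spec(8, "chorea", cadence_hz = 1.45,
      amplitude = c(arm = 0.2, leg = 0.28, torso = 0.05),
      asymmetry = 0.9, speed_drift = 0.3,
      tremor_hz = 4.5, tremor_amplitude = 0.06),
    antalgic = gait_class_spec(9, "antalgic", cadence_hz = 1.2,
      amplitude = c(arm = 0.15, leg = 0.22, torso = 0.03),
      asymmetry = 0.6, speed_drift = 0.05)
  )
}

#' The shipped four-class benchmark phenotypes
#'
#' Four synthetic classes whose cadences are spaced so widely (geometric
#' ratio > 1.5) that even a +/-20% cadence perturbation leaves the class
#' bands disjoint, with a secondary left/right asymmetry cue. This is the
#' dataset used by the package's end-to-end, ablation and speed-robustness
#' experiments.
#'
#' @return Named list of four [gait_class_spec()] objects.
#' @export
gait_benchmark_specs <- function() {
  list(
    slow = gait_class_spec(1, "slow", cadence_hz = 0.7,
      amplitude = c(arm = 0.18, leg = 0.3, torso = 0.03), asymmetry = 1),
    moderate = gait_class_spec(2, "moderate", cadence_hz = 1.1,
      amplitude = c(arm = 0.18, leg = 0.3, torso = 0.03), asymmetry = 0.9),
    brisk = gait_class_spec(3, "brisk", cadence_hz = 1.7,
      amplitude = c(arm = 0.18, leg = 0.3, torso = 0.03), asymmetry = 0.8),
    rapid = gait_class_spec(4, "rapid", cadence_hz = 2.6,
      amplitude = c(arm = 0.18, leg = 0.3, torso = 0.03), asymmetry = 0.65)
  )
}

#' Default pose-noise level of the shipped benchmark
#' @return A [noise_spec()] with 1 cm jitter and 2% joint dropout.
#' @export
benchmark_noise <- function() {
  noise_spec(jitter_sd = 0.01, dropout_prob = 0.02)
}

# ---------------------------------------------------------------------------
# measurement helpers (used by tests and diagnostics)

#' Recover the dominant gait frequency from a sequence
#'
#' FFT-peak estimate on the mean-removed walking-direction coordinate of an
#' ankle joint.
#'
#' @param x A `skeleton_sequence`.
#' @param joint Which ankle (`"right_ankle"` or `"left_ankle"`).
#' @return List with `freq_hz`, `bin` (0-based temporal frequency bin) and
#'   `n_bins` (number of non-negative frequency bins).
#' @export
measure_cadence <- function(x, joint = "right_ankle") {
  layout <- skeleton_layout(x$layout)
  v <- layout$measure_joints[[joint]] + 1L
  sig <- x$values[layout$forward_channel, , v]
  sig <- sig - mean(sig)
  T <- length(sig)
  Fb <- T %/% 2 + 1L
  mag <- Mod(stats::fft(sig))[seq_len(Fb)]
  bin <- which.max(mag[-1])  # exclude DC
  list(freq_hz = bin * x$fps / T, bin = bin, n_bins = Fb)
}

#' Measured left/right ankle oscillation amplitude ratio
#'
#' @param x A `skeleton_sequence`.
#' @return Ratio of left to right ankle forward-coordinate standard
#'   deviation.
#' @export
measure_asymmetry <- function(x) {
  layout <- skeleton_layout(x$layout)
  fwd <- layout$forward_channel
  l <- x$values[fwd, , layout$measure_joints[["left_ankle"]] + 1L]
  r <- x$values[fwd, , layout$measure_joints[["right_ankle"]] + 1L]
  stats::sd(l) / stats::sd(r)
}
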