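# Synthetic multi-subject generator.  Emulates the structure that makes
# cross-subject EEG emotion recognition hard: a subject-invariant,
# class-dependent lateralized alpha-band asymmetry (the signal), strong
# smooth per-subject spatial band-power offsets (the confound), and additive
# pixel noise.

#' Synthetic dataset specification
#'
#' @param n_subjects Number of subjects (>= 2, default 8).
#' @param n_classes Number of emotion classes (>= 2, default 2).
#' @param samples_per_subject Samples (windows) per subject (default 200).
#' @param class_effect Amplitude of the subject-invariant lateralized
#'   alpha-band class pattern (default 1).
#' @param subject_effect Amplitude of the per-subject smooth spatial offset
#'   (default 2, i.e. twice the class effect).
#' @param noise_sd Pixel-scale additive Gaussian noise (default 0.5).
#' @param base_amp Amplitude of the shared smooth baseline field (default 1).
#' @param n_channels Electrode count for EEG mode (default 32).
#' @param fs Sampling rate for EEG mode in Hz (default 128).
#' @param window_s Trial length in seconds for EEG mode (default 15).
#' @param mode `"topograph"` (direct image synthesis) or `"eeg"` (band-limited
#'   time series run through the full feature pipeline).
#' @param seed Integer seed; the same spec always yields the same dataset.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_subjects = 8, n_classes = 2,
                           samples_per_subject = 200, class_effect = 1,
                           subject_effect = 2, noise_sd = 0.5, base_amp = 1,
                           n_channels = 32, fs = 128, window_s = 15,
                           mode = c("topograph", "eeg"), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_subjects >= 2, n_classes >= 2, samples_per_subject >= 1,
            class_effect >= 0, subject_effect >= 0, noise_sd >= 0,
            base_amp >= 0, n_channels >= 4, fs > 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_classes = as.integer(n_classes),
                 samples_per_subject = as.integer(samples_per_subject),
                 class_effect = class_effect, subject_effect = subject_effect,
                 noise_sd = noise_sd, base_amp = base_amp,
                 n_channels = as.integer(n_channels), fs = fs,
                 window_s = window_s, mode = mode, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Subject-to-class effect ratio
#'
#' The single scalar that controls identifiability: as it grows, subject
#' offsets dominate and unregularized classifiers overfit to subjects.
#'
#' @param spec A [synthetic_spec()].
#' @return `subject_effect / class_effect` (Inf when `class_effect` is 0).
#' @export
effect_ratio <- function(spec) {
  if (spec$class_effect == 0) return(Inf)
  spec$subject_effect / spec$class_effect
}

# smooth low-order random field on the grid, sd ~ 1 over the disc
smooth_pattern <- function(gx, gy, inside, n_harmonics = 4) {
  f <- matrix(0, nrow(gx), ncol(gx))
  for (k in seq_len(n_harmonics)) {
    u <- sample(0:2, 1); v <- sample(0:2, 1)
    if (u == 0 && v == 0) u <- 1
    a <- stats::rnorm(1)
    phi <- stats::runif(1, 0, 2 * pi)
    f <- f + a * cos(pi * (u * gx + v * gy) + phi)
  }
  sdv <- stats::sd(f[inside])
  if (sdv > 0) f <- f / sdv
  f
}

# lateralized class template: antisymmetric in x (left-right), focused
# fronto-temporally, unit sd over the disc
class_template <- function(gx, gy, inside) {
  g <- sin(pi * gx) * exp(-(gy - 0.2)^2 / 0.5)
  g / stats::sd(g[inside])
}

# per-class signed magnitude of the lateralized pattern
class_levels <- function(n_classes) {
  if (n_classes == 2) c(-1, 1) else seq(-1, 1, length.out = n_classes)
}

synth_fields <- function(spec) {
  g <- (seq_len(64) - 0.5) / 64 * 2 - 1
  gx <- matrix(g, 64, 64, byrow = TRUE)
  gy <- matrix(rev(g), 64, 64)
  inside <- gx^2 + gy^2 <= 1
  base <- lapply(c(1, 0.8, 0.6), function(a)
    spec$base_amp * a * exp(-(gx^2 + gy^2) / 0.9))
  subj <- lapply(seq_len(spec$n_subjects), function(s)
    lapply(1:3, function(b) smooth_pattern(gx, gy, inside)))
  list(gx = gx, gy = gy, inside = inside, base = base, subj = subj,
       template = class_template(gx, gy, inside))
}

#' Generate a labeled synthetic topograph dataset
#'
#' For each subject a fixed smooth random spatial offset per band is drawn
#' once; each sample adds the shared baseline, the class-dependent
#' lateralized alpha pattern, the subject offset and pixel noise, masks the
#' area outside the head disc, and encodes the result with the standard
#' 0-255 per-band min-max scaling.
#'
#' @param spec A [synthetic_spec()].
#' @return A `topograph_dataset` with balanced class labels per subject.
#' @export
generate_topographs <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    fl <- synth_fields(spec)
    lev <- class_levels(spec$n_classes)
    n <- spec$n_subjects * spec$samples_per_subject
    images <- array(0L, c(n, 3, 64, 64))
    subject_id <- character(n); label <- character(n)
    i <- 0L
    for (s in seq_len(spec$n_subjects)) {
      cls <- rep_len(seq_len(spec$n_classes), spec$samples_per_subject)
      for (j in seq_len(spec$samples_per_subject)) {
        i <- i + 1L
        c_ <- cls[j]
        fields <- lapply(1:3, function(b) {
          f <- fl$base[[b]] + spec$subject_effect * fl$subj[[s]][[b]] +
            spec$noise_sd * matrix(stats::rnorm(64 * 64), 64, 64)
          if (b == 1) f <- f + spec$class_effect * lev[c_] * fl$template
          f[!fl$inside] <- 0
          f
        })
        t <- encode_image(fields, meta = list(
          subject_id = sprintf("S%02d", s), trial_id = sprintf("S%02d_%04d", s, j),
          label = sprintf("class%d", c_), start_time = 0))
        images[i, , , ] <- t$image
        subject_id[i] <- t$subject_id
        label[i] <- t$label
      }
    }
    structure(list(
      images = images,
      meta = data.frame(subject_id = subject_id,
                        trial_id = sprintf("tr%05d", seq_len(n)),
                        label = label, start_time = 0,
                        stringsAsFactors = FALSE),
      band_edges = list(c(8, 13), c(13, 30), c(30, 50))),
      class = "topograph_dataset")
  })
}

#' Generate synthetic multi-subject EEG recordings
#'
#' Each recording is a sum of band-limited sinusoids (two per band inside
#' 8-13, 13-30 and 30-50 Hz) whose per-channel amplitudes follow the same
#' baseline + class + subject decomposition evaluated at the electrode
#' positions, plus white measurement noise, so the full windowing and
#' topograph pipeline reproduces the designed band-power structure.
#'
#' @param spec A [synthetic_spec()] with `mode = "eeg"`.
#' @param montage Electrode montage; defaults to the first `n_channels`
#'   standard positions.
#' @return List of [recording()] objects, one per subject and sample.
#' @export
generate_eeg <- function(spec, montage = standard_montage(n = spec$n_channels)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$mode != "eeg") stop("spec mode must be 'eeg'")
  pos <- montage$positions
  with_seed(spec$seed, {
    lev <- class_levels(spec$n_classes)
    inside_all <- rep(TRUE, nrow(pos))
    # per-channel pattern values (same decomposition as the image mode,
    # evaluated at electrode coordinates)
    base_ch <- lapply(c(1, 0.8, 0.6), function(a)
      spec$base_amp * a * exp(-(pos$x^2 + pos$y^2) / 0.9))
    tmpl_ch <- {
      g <- sin(pi * pos$x) * exp(-(pos$y - 0.2)^2 / 0.5)
      if (stats::sd(g) > 0) g / stats::sd(g) else g
    }
    subj_ch <- lapply(seq_len(spec$n_subjects), function(s)
      lapply(1:3, function(b) {
        f <- rep(0, nrow(pos))
        for (k in 1:4) {
          u <- sample(0:2, 1); v <- sample(0:2, 1)
          if (u == 0 && v == 0) u <- 1
          f <- f + stats::rnorm(1) * cos(pi * (u * pos$x + v * pos$y) +
                                           stats::runif(1, 0, 2 * pi))
        }
        if (stats::sd(f) > 0) f / stats::sd(f) else f
      }))
    band_freqs <- list(c(9.5, 11), c(18, 24), c(35, 42))
    nsamp <- round(spec$window_s * spec$fs)
    tt <- (seq_len(nsamp) - 1) / spec$fs
    out <- list()
    for (s in seq_len(spec$n_subjects)) {
      cls <- rep_len(seq_len(spec$n_classes), spec$samples_per_subject)
      for (j in seq_len(spec$samples_per_subject)) {
        c_ <- cls[j]
        x <- matrix(0, nrow(pos), nsamp)
        for (b in 1:3) {
          amp_field <- base_ch[[b]] + spec$subject_effect * subj_ch[[s]][[b]]
          if (b == 1) amp_field <- amp_field + spec$class_effect * lev[c_] * tmpl_ch
          amp <- sqrt(pmax(amp_field, 0))
          for (f0 in band_freqs[[b]]) {
            ph <- stats::runif(nrow(pos), 0, 2 * pi)
            x <- x + amp * sin(outer(rep(2 * pi * f0, nrow(pos)), tt) + ph)
          }
        }
        if (spec$noise_sd > 0)
          x <- x + spec$noise_sd * matrix(stats::rnorm(length(x)), nrow(x))
        out[[length(out) + 1L]] <- recording(
          x, spec$fs, pos$channel,
          subject_id = sprintf("S%02d", s),
          trial_id = sprintf("S%02d_%04d", s, j),
          label = sprintf("class%d", c_))
      }
    }
    out
  })
}
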