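# Seeded synthetic multichannel EEG-like recordings. Classes differ in
# DYNAMICS (oscillation bandwidth, chaotic mixing weight, 1/f exponent),
# never in amplitude: the planar embedding normalises scale away, so an
# amplitude-coded class effect would be invisible to the topological
# features. Channels are unit-variance mixtures of
#   (1 - mix) * band-limited oscillation + mix * chaotic flow + 1/f noise.

#' Class-dynamics presets
#'
#' Per-class generator parameters: `band` (oscillation band edges, Hz),
#' `mix` (chaotic-component weight in \[0, 1\]), `beta` (1/f noise
#' exponent), and optionally `speed` (time compression of the chaotic
#' flow; larger pushes its spectral content higher, default 25). The
#' three defaults realise a complexity ordering
#' neutral < sad < happy (narrowband/regular to broadband/chaotic),
#' mirroring the within-group pattern reported for emotion classes.
#'
#' @return Named list of parameter lists.
#' @export
default_class_dynamics <- function() {
  list(neutral = list(band = c(2.5, 3.5), mix = 0.10, beta = 1.3),
       sad     = list(band = c(7, 9), mix = 0.25, beta = 1.1),
       happy   = list(band = c(10, 24), mix = 0.70, beta = 0.8))
}

#' Synthetic dataset configuration
#'
#' @param n_subjects subjects per group.
#' @param groups group labels (default `"normal_hearing"`).
#' @param classes emotion-class labels; must name entries of
#'   `class_dynamics`.
#' @param n_trials trials per class per subject.
#' @param rate sampling rate, Hz.
#' @param duration trial length, seconds (a multiple of 9 keeps windows
#'   exact; default 27 = 3 windows).
#' @param n_channels channel count (default 8; 10-20 labels are assigned
#'   for up to 8 channels, `chN` beyond).
#' @param class_dynamics per-class parameters, see
#'   [default_class_dynamics()].
#' @param background_dynamics parameters for class-independent channels.
#' @param discriminative_channels indices of channels carrying the class
#'   effect (default: channels 2, 3, 5 and 8 of those present, or channel
#'   1 if none of them exist); all other channels are class-independent.
#' @param group_effects named list per group of
#'   `list(mix_shift=, band_scale=, band_shift=, background=)` applied on
#'   top of the class dynamics (a group-wide complexity shift: more
#'   chaotic mixing, wider and upward-shifted oscillation bands). An
#'   optional `background` entry replaces `background_dynamics` for that
#'   group entirely, emulating group-reorganised ongoing activity on the
#'   class-independent channels; groups absent from the list get no
#'   shift.
#' @param noise_level amplitude of the 1/f noise component.
#' @param seed integer; the same seed reproduces the dataset bit-exactly.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 4L, groups = "normal_hearing",
                         classes = c("neutral", "sad", "happy"),
                         n_trials = 3L, rate = 200, duration = 27,
                         n_channels = 8L,
                         class_dynamics = default_class_dynamics(),
                         background_dynamics = list(band = c(8, 12),
                                                    mix = 0.40, beta = 1.0),
                         discriminative_channels = NULL,
                         group_effects = list(
                           hearing_impaired = list(
                             mix_shift = 0.2, band_scale = 1.3,
                             band_shift = 2,
                             background = list(band = c(2, 3), mix = 0.05,
                                               beta = 1.4))),
                         noise_level = 0.1, seed = 7L) {
  if (length(classes) < 2L) .fail("need at least 2 classes")
  if (!all(classes %in% names(class_dynamics)))
    .fail("classes without dynamics: %s",
          paste(setdiff(classes, names(class_dynamics)), collapse = ", "))
  if (n_channels < 1L) .fail("need at least one channel")
  if (is.null(discriminative_channels)) {
    discriminative_channels <- intersect(c(2L, 3L, 5L, 8L),
                                         seq_len(n_channels))
    if (!length(discriminative_channels)) discriminative_channels <- 1L
  }
  if (any(discriminative_channels < 1L |
            discriminative_channels > n_channels))
    .fail("discriminative_channels out of range")
  for (dyn in c(class_dynamics[classes], list(background_dynamics))) {
    if (dyn$band[1] <= 0 || dyn$band[2] >= rate / 2 || dyn$band[1] >= dyn$band[2])
      .fail("oscillation band (%g, %g) outside (0, Nyquist)",
            dyn$band[1], dyn$band[2])
  }
  structure(list(n_subjects = as.integer(n_subjects), groups = groups,
                 classes = classes, n_trials = as.integer(n_trials),
                 rate = rate, duration = duration,
                 n_channels = as.integer(n_channels),
                 class_dynamics = class_dynamics,
                 background_dynamics = background_dynamics,
                 discriminative_channels = as.integer(discriminative_channels),
                 group_effects = group_effects,
                 noise_level = noise_level, seed = as.integer(seed)),
            class = "synth_config")
}

.default_channel_labels <- function(k) {
  base <- c("F3", "F4", "T7", "T8", "C3", "C4", "O1", "O2")
  if (k <= length(base)) base[seq_len(k)]
  else c(base, paste0("ch", seq_len(k - length(base))))
}

# band-limited oscillation: sinusoids on a fixed grid spanning the band
# (the class signature), random phases and slow amplitude modulation (the
# trial-to-trial variability); unit population sd
.osc_component <- function(n, rate, band, k = 3L) {
  t <- (seq_len(n) - 1L) / rate
  f <- seq(band[1], band[2], length.out = k)
  ph <- runif(k, 0, 2 * pi)
  amp <- 1 + 0.3 * sin(2 * pi * runif(k, 0.05, 0.2) %o% t +
                         runif(k, 0, 2 * pi))
  x <- colSums(amp * sin(2 * pi * f %o% t + ph))
  x / pop_sd(x)
}

# chaotic flow trace: Lorenz x component, time-compressed so its spectral
# content lands in the EEG range; unit population sd
.chaos_component <- function(n, rate, speed = 25, dt = 0.005) {
  substeps <- max(1L, as.integer(round(speed / rate / dt)))
  init <- c(rnorm(1, 1, 2), rnorm(1, 1, 2), rnorm(1, 25, 2))
  x <- .lorenz_x_cpp(n, dt, substeps, init[1], init[2], init[3],
                     skip = 2000L)
  x / pop_sd(x)
}

# 1/f^beta noise by spectral shaping; unit population sd
.pink_component <- function(n, beta) {
  half <- n %/% 2L
  f <- seq_len(half)
  mag <- f^(-beta / 2)
  phases <- runif(half, 0, 2 * pi)
  spec <- complex(modulus = mag, argument = phases)
  full <- complex(real = numeric(n))
  full[2:(half + 1L)] <- spec
  full[n:(n - half + 2L)] <- Conj(spec[seq_len(half - 1L)])
  x <- Re(fft(full, inverse = TRUE)) / n
  x / pop_sd(x)
}

.apply_group_effect <- function(dyn, effect) {
  if (is.null(effect)) return(dyn)
  dyn$mix <- min(0.95, dyn$mix + (effect$mix_shift %||% 0))
  sc <- effect$band_scale %||% 1
  ctr <- mean(dyn$band) + (effect$band_shift %||% 0)
  hw <- diff(dyn$band) / 2 * sc
  dyn$band <- c(max(0.5, ctr - hw), ctr + hw)
  dyn
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.synth_channel <- function(n, rate, dyn, noise_level) {
  osc <- .osc_component(n, rate, dyn$band)
  ch <- .chaos_component(n, rate, speed = dyn$speed %||% 25)
  nz <- .pink_component(n, dyn$beta)
  x <- (1 - dyn$mix) * osc + dyn$mix * ch + noise_level * nz
  x / pop_sd(x)
}

# Class-independent channels are generated as independent realisations per
# analysis window (nonstationary ongoing activity). A single realisation
# per trial would give every background channel a trial-specific signature
# that boosted trees can memorise - and trials are confounded with class,
# so that signature would masquerade as class information.
.synth_background_channel <- function(n, rate, dyn, noise_level,
                                      window_samples) {
  if (n %% window_samples == 0L) {
    chunks <- replicate(n %/% window_samples,
                        .synth_channel(window_samples, rate, dyn, noise_level))
    as.numeric(chunks)
  } else {
    .synth_channel(n, rate, dyn, noise_level)
  }
}

#' Generate a seeded synthetic dataset
#'
#' Every `(subject, trial-slot, channel)` gets its own derived seed, so the
#' output is bit-reproducible and - crucially - the class label enters only
#' through the dynamics of the discriminative channels: permuting the class
#' labels over trial slots leaves every class-independent channel
#' bit-identical.
#'
#' @param config a [synth_config()].
#' @return A list with `recordings` (list of [eeg_recording()]s, one per
#'   subject x class x trial) and `manifest` (data frame with columns
#'   `source`, `subject_id`, `group`, `trial_id`, `label`).
#' @examples
#' ds <- generate_dataset(synth_config(n_subjects = 1, n_trials = 1,
#'                                     duration = 9))
#' length(ds$recordings)
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n <- as.integer(round(config$duration * config$rate))
  labels <- .default_channel_labels(config$n_channels)
  recordings <- list()
  manifest <- list()
  slot <- 0L
  for (g in seq_along(config$groups)) {
    group <- config$groups[g]
    effect <- config$group_effects[[group]]
    for (s in seq_len(config$n_subjects)) {
      subject <- sprintf("%s_s%02d", group, s)
      for (ci in seq_along(config$classes)) {
        cls <- config$classes[ci]
        dyn_cls <- .apply_group_effect(config$class_dynamics[[cls]], effect)
        dyn_bg <- if (!is.null(effect$background)) effect$background
                  else .apply_group_effect(config$background_dynamics, effect)
        for (tr in seq_len(config$n_trials)) {
          slot <- slot + 1L
          trial_id <- sprintf("t%02d_%s", (ci - 1L) * config$n_trials + tr, cls)
          data <- matrix(0, n, config$n_channels)
          for (ch in seq_len(config$n_channels)) {
            disc <- ch %in% config$discriminative_channels
            # background channels must not see the class: their seed and
            # dynamics depend only on (slot, channel)
            set.seed((config$seed * 7919L + slot * 211L + ch * 17L) %%
                       2147483629L)
            data[, ch] <- if (disc)
              .synth_channel(n, config$rate, dyn_cls, config$noise_level)
            else
              .synth_background_channel(n, config$rate, dyn_bg,
                                        config$noise_level,
                                        as.integer(round(9 * config$rate)))
          }
          rec <- eeg_recording(data, config$rate, labels,
                               subject_id = subject, group = group,
                               trial_id = trial_id, label = cls)
          recordings[[length(recordings) + 1L]] <- rec
          manifest[[length(manifest) + 1L]] <-
            data.frame(source = NA_character_, subject_id = subject,
                       group = group, trial_id = trial_id, label = cls,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  attr(manifest, "class_set") <- config$classes
  list(recordings = recordings, manifest = manifest)
}

#' Generate reference dynamical fixtures
#'
#' Small known systems for validating the embedding and projection stages:
#' `"sinusoid"` - an exact-integer-period sine (zero cross-prediction
#' error at a delay of one period); `"chaotic_flow"` - a Lorenz x-trace
#' (qualitative trajectory fixture); `"plane_cloud"` - 3-D points on a
#' known 2-D affine plane plus optional jitter (planar-recovery fixture).
#'
#' @param kind one of `"sinusoid"`, `"chaotic_flow"`, `"plane_cloud"`.
#' @param params named list: sinusoid takes `period` (samples) and
#'   `length`; chaotic_flow takes `length` and optionally `rate`, `speed`;
#'   plane_cloud takes `n` and `jitter` (sd of the off-plane noise).
#' @param seed RNG seed.
#' @return For the series kinds, a numeric vector. For `plane_cloud`, a
#'   list with `points` (n x 3), `uv` (the true plane coordinates), and
#'   `basis`.
#' @export
generate_known_system <- function(kind = c("sinusoid", "chaotic_flow",
                                           "plane_cloud"),
                                  params = list(), seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  switch(kind,
    sinusoid = {
      period <- params$period %||% 20L
      len <- params$length %||% 400L
      sin(2 * pi * (seq_len(len) - 1L) / period)
    },
    chaotic_flow = {
      len <- params$length %||% 1000L
      .chaos_component(len, params$rate %||% 200, params$speed %||% 25)
    },
    plane_cloud = {
      n <- params$n %||% 200L
      jitter <- params$jitter %||% 0
      basis <- qr.Q(qr(matrix(rnorm(9), 3L, 3L)))[, 1:2]
      uv <- cbind(runif(n), runif(n))
      pts <- uv %*% t(basis) + matrix(rnorm(3L * n, sd = jitter), n, 3L)
      list(points = pts, uv = uv, basis = basis)
    })
}
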