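#' Default EEG frequency bands
#'
#' delta 1-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-50 Hz.
#' @return Named list of `c(low, high)` pairs in Hz.
#' @export
default_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 50))
}

#' Differential entropy of a signal, per frequency band
#'
#' Under a Gaussian model the differential entropy of a signal with
#' variance `sigma^2` is `0.5 * log(2 * pi * e * sigma^2)` (natural log).
#' With `bands` given, each band is isolated by a zero-phase 4th-order
#' Butterworth band-pass before the variance is taken; with `bands = NULL`
#' the broadband variance is used directly. The variance estimator is the
#' population (1/n) form.
#'
#' @param series numeric vector, length >= 2.
#' @param bands named list of `c(low, high)` Hz pairs (see
#'   [default_bands()]), or `NULL` for a single broadband value.
#' @param rate sampling rate in Hz (required when `bands` is given).
#' @return Named numeric vector of differential entropies (nats). A
#'   zero-variance band yields `-Inf` with a warning.
#' @examples
#' de_feature(rnorm(10000), bands = NULL)  # about 0.5*log(2*pi*e) = 1.42
#' @export
de_feature <- function(series, bands = default_bands(), rate = NULL) {
  series <- as.numeric(series)
  if (length(series) < 2L) .fail("series must have length >= 2")
  gauss_de <- function(x) {
    v <- mean((x - mean(x))^2)
    if (v <= 0) {
      warning("zero variance: differential entropy is -Inf")
      return(-Inf)
    }
    0.5 * log(2 * pi * exp(1) * v)
  }
  if (is.null(bands)) return(c(de = gauss_de(series)))
  if (is.null(rate)) .fail("rate is required for band-wise DE")
  nyq <- rate / 2
  out <- vapply(bands, function(b) {
    if (b[1] <= 0 || b[2] >= nyq || b[1] >= b[2])
      .fail("band (%g, %g) outside (0, Nyquist = %g)", b[1], b[2], nyq)
    flt <- signal::butter(2, b / nyq, type = "pass")
    gauss_de(signal::filtfilt(flt, series))
  }, 0)
  names(out) <- paste0("de_", names(bands))
  out
}

#' Extract the per-channel feature vectors of one window
#'
#' Runs the full per-channel pipeline on a windowed segment: delay
#' embedding ([reconstruct_phase_space()]), planar projection
#' ([lle_embed()]), the sixteen topological features ([topo_features()]),
#' and optionally band-wise differential entropy of the raw channel.
#'
#' @param segment an `eeg_window` from [segment_windows()].
#' @param params [embedding_params()] (default tau 1, dim 3).
#' @param p LLE neighbour count (default 4).
#' @param with_de if `TRUE`, append differential entropy per band.
#' @param de_bands bands for the DE features (see [default_bands()]).
#' @param channels optional subset of channel labels to process.
#' @return A data frame, one row per channel: metadata columns
#'   (`subject_id`, `group`, `trial_id`, `label`, `window_index`,
#'   `channel`) followed by the 16 feature columns (and `de_*` columns if
#'   requested).
#' @export
extract_feature_vector <- function(segment, params = embedding_params(),
                                   p = 4L, with_de = FALSE,
                                   de_bands = default_bands(),
                                   channels = NULL) {
  stopifnot(inherits(segment, "eeg_window"))
  sel <- if (is.null(channels)) seq_along(segment$channels)
         else match(channels, segment$channels)
  if (anyNA(sel)) .fail("unknown channel(s): %s",
                        paste(channels[is.na(sel)], collapse = ", "))
  rows <- lapply(sel, function(ci) {
    series <- segment$data[, ci]
    feats <- tryCatch({
      tr <- reconstruct_phase_space(series, params)
      emb <- lle_embed(tr, p = p)
      topo_features(emb)
    }, error = function(e) {
      .fail("channel %s, window %d: %s", segment$channels[ci],
            segment$window_index, conditionMessage(e))
    })
    if (with_de)
      feats <- c(feats, de_feature(series, de_bands, segment$rate))
    cbind(data.frame(subject_id = segment$subject_id, group = segment$group,
                     trial_id = segment$trial_id, label = segment$label,
                     window_index = segment$window_index,
                     channel = segment$channels[ci],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(feats)))
  })
  do.call(rbind, rows)
}

#' Extract features for a whole set of recordings
#'
#' Preprocess-free batch driver: each recording is windowed with
#' [segment_windows()] and every window is passed through
#' [extract_feature_vector()]. Recordings are assumed already conditioned
#' (see [preprocess()]).
#'
#' @param recordings list of [eeg_recording()]s.
#' @param window_seconds window length (default 9 s).
#' @param ... passed to [extract_feature_vector()].
#' @return One long data frame of feature rows (one per channel-window).
#' @export
extract_features <- function(recordings, window_seconds = 9, ...) {
  out <- lapply(recordings, function(rec) {
    wins <- segment_windows(rec, window_seconds)
    do.call(rbind, lapply(wins, extract_feature_vector, ...))
  })
  do.call(rbind, out)
}
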