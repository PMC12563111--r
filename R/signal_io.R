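#' Construct a multichannel EEG recording
#'
#' The basic container for a sampled multichannel signal: a numeric matrix in
#' samples x channels orientation, its sampling rate in Hz, and ordered
#' channel labels (10-20 montage names when available). Metadata fields tie
#' the recording to a subject, group and trial for the classification
#' protocols.
#'
#' @param data numeric matrix, samples x channels (microvolts).
#' @param rate sampling frequency in Hz, must be positive.
#' @param channels character vector of channel labels, one per column.
#' @param subject_id,group,trial_id,label optional metadata strings; `group`
#'   is conventionally `"normal_hearing"` or `"hearing_impaired"`, `label`
#'   the trial's emotion class.
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(400), 200, 2), rate = 100,
#'                      channels = c("C3", "C4"))
#' rec
#' @export
eeg_recording <- function(data, rate, channels,
                          subject_id = "", group = "", trial_id = "",
                          label = "") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  dimnames(data) <- NULL
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    .fail("rate must be a single positive number")
  if (length(channels) != ncol(data))
    .fail("channel count (%d) does not match label count (%d)",
          ncol(data), length(channels))
  .check_finite(data, "recording data")
  structure(list(data = data, rate = as.numeric(rate),
                 channels = as.character(channels),
                 subject_id = subject_id, group = group,
                 trial_id = trial_id, label = label),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, nrow(x$data) / x$rate))
  cat("  channels:", paste(x$channels, collapse = " "), "\n")
  if (nzchar(x$subject_id) || nzchar(x$trial_id))
    cat(sprintf("  subject=%s group=%s trial=%s label=%s\n",
                x$subject_id, x$group, x$trial_id, x$label))
  invisible(x)
}

#' Load a recording from a file or in-memory matrix
#'
#' Accepts a numeric matrix/data frame, a delimited text file (TSV/CSV with a
#' header row of channel labels), an EDF file, or an RDS file holding a
#' matrix or `eeg_recording`. Matrices are auto-transposed to samples x
#' channels when the number of rows equals the label count but the number of
#' columns does not; a square matrix without a clear orientation is an
#' error unless `orientation` is given.
#'
#' @param source matrix, data frame, or path to a `.csv`/`.tsv`/`.txt`,
#'   `.edf` or `.rds` file.
#' @param rate sampling rate in Hz. For EDF input the embedded rate is used
#'   and `rate`, if supplied, must agree.
#' @param channels channel labels; defaults to the file header (delimited),
#'   the embedded labels (EDF), or `ch1..chK`.
#' @param orientation `"samples_x_channels"` (default assumption) or
#'   `"channels_x_samples"`; required to disambiguate square matrices when
#'   labels do not settle it.
#' @param ... metadata passed to [eeg_recording()] (`subject_id`, `group`,
#'   `trial_id`, `label`).
#' @return An [eeg_recording()].
#' @export
load_recording <- function(source, rate = NULL, channels = NULL,
                           orientation = NULL, ...) {
  if (is.character(source) && length(source) == 1L) {
    ext <- tolower(tools::file_ext(source))
    if (ext == "edf") {
      edf <- read_edf(source)
      if (!is.null(rate) && !isTRUE(all.equal(rate, edf$rate)))
        .fail("rate argument (%g) disagrees with EDF embedded rate (%g)",
              rate, edf$rate)
      if (is.null(channels)) channels <- edf$channels
      return(eeg_recording(edf$data, edf$rate, channels, ...))
    }
    if (ext == "rds") {
      obj <- readRDS(source)
      if (inherits(obj, "eeg_recording")) return(obj)
      source <- obj
    } else {
      sep <- if (ext == "csv") "," else "\t"
      df <- utils::read.table(source, header = TRUE, sep = sep,
                              check.names = FALSE)
      if (is.null(channels)) channels <- colnames(df)
      source <- df
    }
  }
  m <- as.matrix(source)
  if (!is.numeric(m)) .fail("source is not numeric")
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(m)))
  k <- length(channels)
  if (!is.null(orientation)) {
    orientation <- match.arg(orientation,
                             c("samples_x_channels", "channels_x_samples"))
    if (orientation == "channels_x_samples") m <- t(m)
  } else if (nrow(m) == ncol(m) && nrow(m) == k) {
    .fail("square matrix: orientation is ambiguous, pass `orientation`")
  } else if (nrow(m) == k && ncol(m) != k) {
    m <- t(m)  # rows matched the labels: channels were in rows
  }
  if (is.null(rate)) .fail("rate is required for non-EDF input")
  eeg_recording(m, rate, channels, ...)
}

#' Write a recording as delimited text
#'
#' Tab-separated, header row of channel labels, full double precision (17
#' significant digits) so that a write/reload round trip is bit-identical.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  txt <- apply(rec$data, 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t"))
  writeLines(c(paste(rec$channels, collapse = "\t"), txt), path)
  invisible(path)
}

#' Resample, filter and trim a recording
#'
#' The standard conditioning chain: downsample to `target_rate` (polyphase,
#' anti-aliased), apply a zero-phase band-pass and a zero-phase band-stop
#' (notch) per channel, and keep only the trailing `keep_last` seconds.
#' Filters are forward-backward Butterworth (4th-order band-pass, 2nd-order
#' band-stop), preserving phase so trajectory geometry is not distorted.
#'
#' @param rec an [eeg_recording()].
#' @param target_rate output rate in Hz; upsampling is refused.
#' @param band band-pass edges `c(low, high)` in Hz, within (0, Nyquist);
#'   `NULL` skips the band-pass.
#' @param notch band-stop edges in Hz; `NULL` skips the notch.
#' @param keep_last trailing duration to retain, seconds. If the recording is
#'   shorter, everything is kept and a warning is issued.
#' @return The conditioned [eeg_recording()] at `target_rate`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2000), ncol = 2), 1000, c("C3", "C4"))
#' out <- preprocess(rec, target_rate = 200, keep_last = 2)
#' out$rate
#' @export
preprocess <- function(rec, target_rate = 200, band = c(1, 75),
                       notch = c(49, 51), keep_last = 180) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_rate > rec$rate)
    .fail("upsampling refused: target_rate %g > recording rate %g",
          target_rate, rec$rate)
  x <- rec$data
  if (target_rate < rec$rate) {
    ratio <- rec$rate / target_rate
    x <- apply(x, 2L, function(ch) {
      if (abs(ratio - round(ratio)) < 1e-9)
        as.numeric(signal::decimate(ch, round(ratio), ftype = "fir"))
      else
        as.numeric(signal::resample(ch, p = target_rate, q = rec$rate))
    })
  }
  nyq <- target_rate / 2
  if (!is.null(band)) {
    if (band[1] <= 0 || band[2] >= nyq)
      .fail("band-pass edges must lie inside (0, %g)", nyq)
    bp <- signal::butter(2, band / nyq, type = "pass")
    x <- apply(x, 2L, function(ch) signal::filtfilt(bp, ch))
  }
  if (!is.null(notch)) {
    if (notch[1] <= 0 || notch[2] >= nyq)
      .fail("notch edges must lie inside (0, %g)", nyq)
    bs <- signal::butter(1, notch / nyq, type = "stop")
    x <- apply(x, 2L, function(ch) signal::filtfilt(bs, ch))
  }
  n_keep <- round(keep_last * target_rate)
  if (n_keep < nrow(x)) {
    x <- x[(nrow(x) - n_keep + 1L):nrow(x), , drop = FALSE]
  } else if (n_keep > nrow(x)) {
    warning(sprintf("recording shorter than keep_last = %g s; keeping all %g s",
                    keep_last, nrow(x) / target_rate))
  }
  eeg_recording(x, target_rate, rec$channels, rec$subject_id, rec$group,
                rec$trial_id, rec$label)
}

#' Cut a recording into fixed non-overlapping windows
#'
#' Chronological, non-overlapping segments of `window_seconds` each; the
#' trailing remainder that does not fill a window is dropped.
#'
#' @param rec an [eeg_recording()].
#' @param window_seconds window length in seconds; `window_seconds * rate`
#'   must be an integer.
#' @return A list of `eeg_window` objects, each holding `data`
#'   (window_samples x channels), a 0-based `window_index`, and the
#'   recording's metadata (including its class `label`).
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2000 * 2), ncol = 2), 200, c("C3", "C4"))
#' length(segment_windows(rec, 9))  # 10 s -> 1 window of 9 s
#' @export
segment_windows <- function(rec, window_seconds = 9) {
  stopifnot(inherits(rec, "eeg_recording"))
  w <- window_seconds * rec$rate
  if (abs(w - round(w)) > 1e-9)
    .fail("window_seconds * rate must be an integer (got %g)", w)
  w <- as.integer(round(w))
  n <- nrow(rec$data)
  k <- n %/% w
  if (k < 1L)
    .fail("recording (%g s) shorter than one %g s window",
          n / rec$rate, window_seconds)
  lapply(seq_len(k) - 1L, function(i) {
    structure(list(data = rec$data[(i * w + 1L):((i + 1L) * w), , drop = FALSE],
                   rate = rec$rate, channels = rec$channels,
                   window_index = i, label = rec$label,
                   subject_id = rec$subject_id, group = rec$group,
                   trial_id = rec$trial_id),
              class = "eeg_window")
  })
}

#' @export
print.eeg_window <- function(x, ...) {
  cat(sprintf("<eeg_window> #%d, %d samples x %d channels @ %g Hz, label=%s\n",
              x$window_index, nrow(x$data), ncol(x$data), x$rate, x$label))
  invisible(x)
}

#' Read a dataset manifest
#'
#' One delimited table (TSV or CSV by extension) with columns
#' `source, subject_id, group, trial_id, label` mapping recording files to
#' their metadata. `(subject_id, trial_id)` pairs must be unique.
#'
#' @param path manifest file path.
#' @param class_set optional ordered label set; defaults to the sorted unique
#'   labels present. Labels outside `class_set` are an error.
#' @return A data frame with the five columns plus a `class_set` attribute.
#' @export
read_manifest <- function(path, class_set = NULL) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("source", "subject_id", "group", "trial_id", "label")
  if (!all(need %in% names(df)))
    .fail("manifest must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(df[c("subject_id", "trial_id")]))
    .fail("(subject_id, trial_id) pairs must be unique")
  if (is.null(class_set)) class_set <- sort(unique(df$label))
  if (!all(df$label %in% class_set))
    .fail("manifest labels outside the class set: %s",
          paste(setdiff(df$label, class_set), collapse = ", "))
  attr(df, "class_set") <- class_set
  df
}
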