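# Minimal continuous-EDF I/O. Covers the plain EDF layout used for
# uninterrupted multichannel recordings: one sampling rate shared by all
# signals, 16-bit samples, no annotations. Discontinuous EDF+ files are out
# of scope.

.edf_char <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

# format a number into <= 8 ASCII chars (EDF header numeric field)
.edf_fit_num <- function(v) {
  for (d in 6:1) {
    s <- formatC(v, digits = d, format = "g")
    if (nchar(s) <= 8L) return(s)
  }
  formatC(v, digits = 1, format = "e")
}
.edf_num  <- function(con, n) as.numeric(.edf_char(con, n))

#' Read a continuous EDF file
#'
#' @param path path to a `.edf` file.
#' @return A list with `data` (samples x channels, physical units), `rate`
#'   (Hz, common to all channels) and `channels` (labels).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  .edf_char(con, 8L)                      # version
  .edf_char(con, 80L); .edf_char(con, 80L)  # patient / recording id
  .edf_char(con, 8L); .edf_char(con, 8L)    # start date / time
  .edf_num(con, 8L)                       # header length
  .edf_char(con, 44L)                     # reserved
  n_rec <- .edf_num(con, 8L)
  rec_dur <- .edf_num(con, 8L)
  ns <- as.integer(.edf_num(con, 4L))
  if (is.na(ns) || ns < 1L) .fail("EDF: bad signal count")
  labels <- vapply(seq_len(ns), function(i) .edf_char(con, 16L), "")
  vapply(seq_len(ns), function(i) .edf_char(con, 80L), "")  # transducer
  vapply(seq_len(ns), function(i) .edf_char(con, 8L), "")   # physical dim
  pmin <- vapply(seq_len(ns), function(i) .edf_num(con, 8L), 0)
  pmax <- vapply(seq_len(ns), function(i) .edf_num(con, 8L), 0)
  dmin <- vapply(seq_len(ns), function(i) .edf_num(con, 8L), 0)
  dmax <- vapply(seq_len(ns), function(i) .edf_num(con, 8L), 0)
  vapply(seq_len(ns), function(i) .edf_char(con, 80L), "")  # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(.edf_num(con, 8L)), 0L)
  vapply(seq_len(ns), function(i) .edf_char(con, 32L), "")  # reserved
  if (length(unique(spr)) != 1L)
    .fail("EDF: signals with differing rates are not supported")
  rate <- spr[1] / rec_dur
  out <- matrix(0, nrow = n_rec * spr[1], ncol = ns)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2L,
                     signed = TRUE, endian = "little")
      out[((r - 1L) * spr[s] + 1L):(r * spr[s]), s] <-
        pmin[s] + (dig - dmin[s]) * scale[s]
    }
  }
  list(data = out, rate = rate, channels = labels)
}

#' Write a recording as a continuous EDF file
#'
#' 16-bit encoding with per-channel physical scaling; one-second data
#' records. The sample count must be a multiple of the rate. Intended for
#' fixture generation and interchange, not archival fidelity (quantisation
#' to 16 bits applies).
#'
#' @param rec an [eeg_recording()]; `rec$rate` must be a positive integer.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$data
  ns <- ncol(x)
  spr <- as.integer(round(rec$rate))
  if (abs(spr - rec$rate) > 1e-9) .fail("EDF writer needs an integer rate")
  if (nrow(x) %% spr != 0L)
    .fail("EDF writer needs a whole number of 1 s records")
  n_rec <- nrow(x) %/% spr
  pmin <- apply(x, 2, min); pmax <- apply(x, 2, max)
  too_flat <- (pmax - pmin) < 1e-12
  pmax[too_flat] <- pmin[too_flat] + 1
  dmin <- -32768; dmax <- 32767
  dig <- round(sweep(sweep(x, 2, pmin), 2, (pmax - pmin) / (dmax - dmin), "/")) + dmin
  pad <- function(s, n) formatC(substr(s, 1, n), width = n, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_len <- 256L + 256L * ns
  writeChar(paste0(pad("0", 8), pad("X", 80), pad("phasetopo", 80),
                   pad("01.01.26", 8), pad("00.00.00", 8),
                   pad(as.character(hdr_len), 8), pad("", 44),
                   pad(as.character(n_rec), 8), pad("1", 8),
                   pad(as.character(ns), 4)),
            con, eos = NULL)
  fields <- list(c(rec$channels, 16), c(rep("", ns), 80), c(rep("uV", ns), 8),
                 c(vapply(pmin, .edf_fit_num, ""), 8),
                 c(vapply(pmax, .edf_fit_num, ""), 8),
                 c(rep(as.character(dmin), ns), 8),
                 c(rep(as.character(dmax), ns), 8),
                 c(rep("", ns), 80), c(rep(as.character(spr), ns), 8),
                 c(rep("", ns), 32))
  for (f in fields) {
    w <- as.integer(f[length(f)])
    writeChar(paste(vapply(f[-length(f)], pad, "", n = w), collapse = ""),
              con, eos = NULL)
  }
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      writeBin(as.integer(dig[((r - 1L) * spr + 1L):(r * spr), s]),
               con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
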