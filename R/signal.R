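#' Continuous multi-channel recording container
#'
#' Channels-by-samples matrix with sampling-rate and channel metadata. Only
#' 500 and 512 Hz inputs are accepted; 512 Hz data are resampled to the
#' pipeline's working rate of 500 Hz by polyphase rational resampling.
#'
#' @param data Numeric matrix, channels x samples (uV).
#' @param sampling_rate_hz 500 or 512.
#' @param channel_names Character vector, one name per channel.
#' @param units Signal units label.
#' @return Object of class `fs_recording`.
#' @export
fs_recording <- function(data, sampling_rate_hz, channel_names = NULL,
                         units = "uV") {
  data <- as.matrix(data)
  stopifnot_finite(data, "recording")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(data)))
  if (!sampling_rate_hz %in% c(500, 512))
    stop("sampling rate must be 500 or 512 Hz")
  if (sampling_rate_hz == 512) {
    data <- t(apply(data, 1, function(x) signal::resample(x, 500, 512)))
    sampling_rate_hz <- 500
  }
  structure(list(data = data, sampling_rate_hz = sampling_rate_hz,
                 channel_names = channel_names, units = units),
            class = "fs_recording")
}

#' @export
print.fs_recording <- function(x, ...) {
  cat(sprintf("fs_recording: %d channels x %d samples at %g Hz (%s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate_hz, x$units))
  invisible(x)
}

#' Write / read a recording as a flat binary array with a JSON sidecar
#'
#' Stores samples as little-endian float64 (channels fastest) next to a JSON
#' file `{sampling_rate_hz, channel_names, units, n_samples}`.
#'
#' @param rec An [fs_recording()].
#' @param path Binary file path; sidecar is `<path>.json`.
#' @return `path` invisibly; the reader returns an `fs_recording`.
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  jsonlite::write_json(list(sampling_rate_hz = rec$sampling_rate_hz,
                            channel_names = rec$channel_names,
                            units = rec$units,
                            n_samples = ncol(rec$data)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n_ch <- length(meta$channel_names)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n_ch * meta$n_samples, size = 8,
               endian = "little")
  fs_recording(matrix(x, n_ch, meta$n_samples), meta$sampling_rate_hz,
               meta$channel_names, meta$units)
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean over intact channels from each intact
#' channel. Bad channels pass through unchanged and are excluded from the
#' mean; they are recorded in the `bad_channels` attribute.
#'
#' @param rec An [fs_recording()].
#' @param bad_channels Character vector of channel names to exclude.
#' @return A re-referenced `fs_recording`.
#' @export
common_average_reference <- function(rec, bad_channels = character(0)) {
  stopifnot(inherits(rec, "fs_recording"))
  if (!all(bad_channels %in% rec$channel_names))
    stop("bad_channels must be a subset of channel names")
  intact <- !(rec$channel_names %in% bad_channels)
  if (!any(intact)) stop("all channels flagged bad")
  car <- colMeans(rec$data[intact, , drop = FALSE])
  out <- rec
  out$data[intact, ] <- sweep(rec$data[intact, , drop = FALSE], 2, car)
  attr(out, "bad_channels") <- bad_channels
  out
}

#' Analytic-signal amplitude (Hilbert envelope)
#'
#' Instantaneous amplitude via the FFT construction of the analytic signal
#' (positive frequencies doubled, negative zeroed).
#'
#' @param x Numeric vector.
#' @return Non-negative envelope, same length as `x`.
#' @export
hilbert_amplitude <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

# Zero-phase band-pass: Hamming-window FIR (order ~ 3.3 / transition width),
# applied by FFT convolution with exact group-delay compensation and
# reflection padding. Equivalent to forward filtering with the symmetric
# linear-phase kernel and shifting back by half the order.
fir_bandpass_zerophase <- function(x, lo, hi, fs, trans_hz = 2) {
  n_ord <- ceiling(3.3 / (trans_hz / fs))
  n_ord <- n_ord + n_ord %% 2                    # even order, odd-length taps
  if (length(x) < n_ord %/% 2 + 2)
    stop("recording shorter than the filter transient")
  b <- signal::fir1(n_ord, c(lo, hi) / (fs / 2), type = "pass",
                    window = signal::hamming(n_ord + 1))
  np <- min(n_ord, length(x) - 1)
  xp <- c(2 * x[1] - x[(np + 1):2], x,
          2 * x[length(x)] - x[(length(x) - 1):(length(x) - np)])
  y <- signal::fftfilt(b, c(xp, numeric(n_ord)))
  y[(np + n_ord / 2 + 1):(np + n_ord / 2 + length(x))]
}

#' Default HFA frequency sub-bands
#'
#' Nine 10 Hz-wide bands spanning 48-154 Hz while avoiding the 59-61 and
#' 117-121 Hz line-noise ranges. Edges are configurable wherever the bands
#' are consumed.
#'
#' @return 9 x 2 matrix of band edges in Hz.
#' @export
hfa_bands <- function() {
  cbind(lo = c(48, 62, 72, 82, 92, 102, 122, 132, 144),
        hi = c(58, 72, 82, 92, 102, 112, 132, 142, 154))
}

#' Estimate the high-frequency amplitude (HFA) trace
#'
#' Per channel: band-pass each sub-band with a zero-phase Hamming FIR, take
#' the Hilbert envelope, divide each band's envelope by its own temporal mean
#' (equalizing the 1/f-driven contribution of lower bands), and average the
#' normalized envelopes. The result is a dimensionless amplitude trace with
#' temporal mean 1 per channel.
#'
#' @param rec An [fs_recording()] (sampling rate must exceed twice the top
#'   band edge).
#' @param bands Band-edge matrix as from [hfa_bands()].
#' @param trans_hz FIR transition width in Hz.
#' @return An `fs_recording` carrying the HFA trace (units `"HFA (a.u.)"`).
#' @export
estimate_hfa <- function(rec, bands = hfa_bands(), trans_hz = 2) {
  stopifnot(inherits(rec, "fs_recording"))
  if (rec$sampling_rate_hz < 2 * max(bands))
    stop("sampling rate below twice the highest band edge")
  out <- rec
  for (ch in seq_len(nrow(rec$data))) {
    acc <- numeric(ncol(rec$data))
    for (b in seq_len(nrow(bands))) {
      env <- hilbert_amplitude(
        fir_bandpass_zerophase(rec$data[ch, ], bands[b, 1], bands[b, 2],
                               rec$sampling_rate_hz, trans_hz))
      acc <- acc + env / mean(env)
    }
    out$data[ch, ] <- acc / nrow(bands)
  }
  out$units <- "HFA (a.u.)"
  out
}

#' Epoch a recording around stimulus onsets and normalize to baseline
#'
#' Cuts half-open `[window[1], window[2])` ms epochs around every retained
#' trial onset (the sample at t = 0 belongs to the response side), computes a
#' per-channel global baseline B as the mean over all retained trials'
#' baseline-window samples, and - when `percent_change` - maps every sample
#' to `100 * (x - B) / B`. Repeat trials (the 1-back targets, i.e. hit/miss
#' trials) are excluded by default, as is any trial flagged in an `excluded`
#' column of the protocol (false alarms).
#'
#' @param rec An [fs_recording()] (typically the HFA trace).
#' @param protocol A [task_protocol()] aligned with the recording.
#' @param window,baseline Half-open windows in ms relative to onset.
#' @param percent_change Normalize to percent signal change from B (requires
#'   B > 0; guaranteed for amplitude traces).
#' @param exclude_repeats Drop 1-back repeat trials.
#' @return Object of class `epoched_response`: array trials x channels x
#'   time, with `time_ms`, `trials` (retained protocol rows), baseline and
#'   unit metadata.
#' @export
epoch_and_normalize <- function(rec, protocol, window = c(-200, 500),
                                baseline = c(-200, 0), percent_change = TRUE,
                                exclude_repeats = TRUE) {
  stopifnot(inherits(rec, "fs_recording"))
  fs <- rec$sampling_rate_hz
  step <- 1000 / fs
  time_ms <- seq(window[1], window[2] - step, by = step)
  keep <- rep(TRUE, nrow(protocol))
  if (exclude_repeats) keep <- keep & !protocol$is_repeat
  if (!is.null(protocol$excluded)) keep <- keep & !protocol$excluded
  trials <- as.data.frame(protocol)[keep, , drop = FALSE]
  onset_idx <- round(trials$onset_ms * fs / 1000) + 1L
  off <- round(time_ms * fs / 1000)
  if (min(onset_idx) + off[1] < 1 ||
      max(onset_idx) + off[length(off)] > ncol(rec$data))
    stop("epoch window extends outside the recording")
  n_ch <- nrow(rec$data)
  ep <- array(NA_real_, c(nrow(trials), n_ch, length(time_ms)))
  for (tr in seq_len(nrow(trials)))
    ep[tr, , ] <- rec$data[, onset_idx[tr] + off, drop = FALSE]
  bl <- time_ms >= baseline[1] & time_ms < baseline[2]
  if (percent_change) {
    for (ch in seq_len(n_ch)) {
      b <- mean(ep[, ch, bl])
      if (!is.finite(b) || b <= 0)
        stop("non-positive global baseline in channel ", ch,
             "; percent change undefined")
      ep[, ch, ] <- 100 * (ep[, ch, ] - b) / b
    }
    units <- "% signal change"
  } else {
    units <- rec$units
  }
  structure(ep, time_ms = time_ms, trials = trials,
            baseline_window = baseline, units = units,
            channel_names = rec$channel_names,
            class = "epoched_response")
}

#' @export
print.epoched_response <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("epoched_response: %d trials x %d channels x %d samples (%s)\n",
              d[1], d[2], d[3], attr(x, "units")))
  invisible(x)
}

# repetition-average an epoched response per exemplar
average_by_exemplar <- function(ep) {
  trials <- attr(ep, "trials")
  ids <- sort(unique(trials$stimulus_id))
  out <- array(0, c(length(ids), dim(ep)[2], dim(ep)[3]))
  for (i in seq_along(ids)) {
    rows <- which(trials$stimulus_id == ids[i])
    out[i, , ] <- apply(ep[rows, , , drop = FALSE], c(2, 3), mean)
  }
  tr <- data.frame(stimulus_id = ids,
                   category = trials$category[match(ids,
                                                    trials$stimulus_id)],
                   n_reps = as.vector(table(trials$stimulus_id)[ids]))
  structure(out, time_ms = attr(ep, "time_ms"), trials = tr,
            baseline_window = attr(ep, "baseline_window"),
            units = attr(ep, "units"),
            channel_names = attr(ep, "channel_names"),
            averaged = TRUE, class = "epoched_response")
}

#' Event-related potentials from the common-referenced raw signal
#'
#' Epochs the (already common-average-referenced) raw signal around onsets
#' and averages across repetitions of each exemplar. The analysis window is
#' pre-defined at `[125, 250)` ms and recorded in the `analysis_window`
#' attribute.
#'
#' @param rec Common-referenced raw [fs_recording()].
#' @param protocol A [task_protocol()].
#' @param window Epoch window in ms.
#' @return Exemplar-averaged `epoched_response` in uV.
#' @export
extract_erp <- function(rec, protocol, window = c(-200, 500)) {
  ep <- epoch_and_normalize(rec, protocol, window = window,
                            percent_change = FALSE)
  out <- average_by_exemplar(ep)
  attr(out, "analysis_window") <- c(125, 250)
  out
}

#' Low-frequency band-limited power epochs
#'
#' Filters the common-referenced signal at 8-13 Hz, takes the Hilbert
#' envelope, and epochs it around onsets. Analysis window `[125, 250)` ms in
#' metadata.
#'
#' @param rec Common-referenced raw [fs_recording()].
#' @param protocol A [task_protocol()].
#' @param band Frequency band in Hz.
#' @param window Epoch window in ms.
#' @return Trial-level `epoched_response` of band-limited amplitude (uV).
#' @export
extract_low_freq_blp <- function(rec, protocol, band = c(8, 13),
                                 window = c(-200, 500)) {
  out <- rec
  for (ch in seq_len(nrow(rec$data)))
    out$data[ch, ] <- hilbert_amplitude(
      fir_bandpass_zerophase(rec$data[ch, ], band[1], band[2],
                             rec$sampling_rate_hz))
  ep <- epoch_and_normalize(out, protocol, window = window,
                            percent_change = FALSE)
  attr(ep, "analysis_window") <- c(125, 250)
  ep
}
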