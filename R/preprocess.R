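#' Resample a recording
#'
#' Polyphase resampling to a lower rate. Upsampling is refused: the analysis
#' chain only ever reduces mixed acquisition rates down to a common rate.
#'
#' @param rec An `eeg_recording`.
#' @param target_hz Target sampling rate (Hz), at most the current rate.
#' @return Resampled `eeg_recording`; duration preserved within one sample.
#' @export
resample_recording <- function(rec, target_hz) {
  stopifnot(inherits(rec, "eeg_recording"), target_hz > 0)
  if (target_hz > rec$sfreq + 1e-9) {
    stop("upsampling (", rec$sfreq, " -> ", target_hz, " Hz) is not supported",
      call. = FALSE
    )
  }
  if (abs(target_hz - rec$sfreq) < 1e-9) {
    return(rec)
  }
  frac <- ratio_approx(target_hz / rec$sfreq)
  n_out <- floor(ncol(rec$data) * target_hz / rec$sfreq)
  out <- t(apply(rec$data, 1, function(v) {
    y <- signal::resample(v, frac$p, frac$q)
    length(y) <- n_out # resample may over/undershoot by a sample
    y[is.na(y)] <- 0
    y
  }))
  eeg_recording(out, target_hz, rec$channels, rec$reference)
}

# small-denominator rational approximation of a resampling ratio
ratio_approx <- function(x, max_den = 1000L) {
  best <- c(1L, 1L)
  err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(x * q)
    if (p < 1) next
    e <- abs(x - p / q)
    if (e < err - 1e-15) {
      best <- c(p, q)
      err <- e
    }
    if (err < 1e-12) break
  }
  list(p = best[1], q = best[2])
}

butter_filtfilt <- function(m, sfreq, type, freq, order = 4) {
  flt <- signal::butter(order, freq / (sfreq / 2), type = type)
  t(apply(m, 1, function(v) signal::filtfilt(flt, v)))
}

#' Zero-phase band-pass filter
#'
#' Cascaded 4th-order Butterworth high-pass and low-pass, each applied
#' forward-backward (`filtfilt`), so the filter has zero phase and microstate
#' timing is not shifted. The cascade is more robust than a single band
#' design when the upper edge sits close to Nyquist (e.g. 60 Hz at 125 Hz).
#'
#' @param x An `eeg_recording` or `eeg_epochs`.
#' @param low_hz,high_hz Band edges, `0 < low < high < Nyquist`.
#' @param order Butterworth order of each cascade stage.
#' @return Filtered object of the same class.
#' @export
eeg_bandpass <- function(x, low_hz, high_hz, order = 4) {
  stopifnot(low_hz > 0, high_hz > low_hz)
  if (high_hz >= x$sfreq / 2) {
    stop(
      "band edge ", high_hz, " Hz is not below Nyquist (", x$sfreq / 2, " Hz)",
      call. = FALSE
    )
  }
  apply_channelwise(x, function(m) {
    # remove the channel mean first: the forward-backward filter's edge
    # transients handle a large DC offset poorly
    m <- m - rowMeans(m)
    m <- butter_filtfilt(m, x$sfreq, "high", low_hz, order)
    butter_filtfilt(m, x$sfreq, "low", high_hz, order)
  })
}

#' Zero-phase notch filter
#'
#' Narrow Butterworth band-stop (default +/- 2 Hz around the mains frequency)
#' applied forward-backward, removing power-line interference.
#'
#' @param x An `eeg_recording` or `eeg_epochs`.
#' @param freq_hz Mains frequency, below Nyquist. Default 50 Hz.
#' @param width_hz Half-width of the stop band.
#' @return Filtered object of the same class.
#' @export
eeg_notch <- function(x, freq_hz = 50, width_hz = 2) {
  if (freq_hz + width_hz >= x$sfreq / 2) {
    stop(
      "notch at ", freq_hz, " Hz infeasible: Nyquist is ", x$sfreq / 2, " Hz",
      call. = FALSE
    )
  }
  flt <- signal::butter(2, c(freq_hz - width_hz, freq_hz + width_hz) / (x$sfreq / 2),
    type = "stop"
  )
  apply_channelwise(x, function(m) {
    t(apply(m, 1, function(v) signal::filtfilt(flt, v)))
  })
}

apply_channelwise <- function(x, fn) {
  if (inherits(x, "eeg_recording")) {
    x$data <- fn(x$data)
    rownames(x$data) <- x$channels
    return(x)
  }
  if (inherits(x, "eeg_epochs")) {
    d <- dim(x$data)
    for (i in seq_len(d[3])) {
      x$data[, , i] <- fn(x$data[, , i, drop = TRUE])
    }
    return(x)
  }
  stop("expected eeg_recording or eeg_epochs", call. = FALSE)
}

#' Segment a recording into fixed-length epochs
#'
#' Non-overlapping consecutive epochs; any trailing remainder shorter than
#' one epoch is discarded.
#'
#' @param rec An `eeg_recording`.
#' @param epoch_ms Epoch length in milliseconds (default 2000).
#' @return An `eeg_epochs` object.
#' @export
segment_epochs <- function(rec, epoch_ms = 2000) {
  stopifnot(inherits(rec, "eeg_recording"), epoch_ms > 0)
  len <- as.integer(round(epoch_ms / 1000 * rec$sfreq))
  total <- ncol(rec$data)
  n_ep <- total %/% len
  if (n_ep < 1) {
    stop(
      "recording (", total, " samples) shorter than one ", epoch_ms, " ms epoch (",
      len, " samples)",
      call. = FALSE
    )
  }
  arr <- array(rec$data[, seq_len(n_ep * len)], dim = c(nrow(rec$data), len, n_ep))
  eeg_epochs(arr, rec$sfreq, rec$channels, rec$reference)
}

#' Keep the first n epochs
#'
#' @param ep An `eeg_epochs` object.
#' @param n Number of epochs to keep (default 20).
#' @return An `eeg_epochs` with the first `n` epochs in original order.
#' @export
select_epochs <- function(ep, n = 20) {
  stopifnot(inherits(ep, "eeg_epochs"), n >= 0)
  avail <- n_epochs(ep)
  if (avail < n) {
    stop("requested ", n, " epochs but only ", avail, " available", call. = FALSE)
  }
  ep$data <- ep$data[, , seq_len(n), drop = FALSE]
  ep
}

#' Standard preprocessing chain
#'
#' Runs the default resting-state chain on a loaded recording: resample,
#' band-pass, notch, segment into epochs, keep the first `n_epochs`, and
#' recompute against the average reference.
#'
#' @param rec An `eeg_recording` on the analysis montage.
#' @param resample_hz Target rate (default 125).
#' @param bp_low,bp_high Band-pass edges in Hz (defaults 1 and 60).
#' @param notch_hz Mains frequency (default 50); `NA` disables the notch.
#' @param epoch_ms Epoch length (default 2000 ms).
#' @param n_epochs Epochs retained (default 20).
#' @return An average-referenced `eeg_epochs` object.
#' @export
preprocess_recording <- function(rec, resample_hz = 125, bp_low = 1, bp_high = 60,
                                 notch_hz = 50, epoch_ms = 2000, n_epochs = 20) {
  rec <- resample_recording(rec, resample_hz)
  rec <- eeg_bandpass(rec, bp_low, bp_high)
  if (is.finite(notch_hz)) rec <- eeg_notch(rec, notch_hz)
  ep <- segment_epochs(rec, epoch_ms)
  ep <- select_epochs(ep, n_epochs)
  average_reference(ep)
}
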