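#' Continuous EEG recording
#'
#' Light container for a continuous multichannel recording: a channels x
#' samples voltage matrix (microvolts) plus sampling rate, channel names and
#' the current reference state.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param sfreq Sampling rate in Hz.
#' @param channels Character vector of channel names, one per row of `data`.
#' @param reference `"original"` or `"average"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sfreq, channels, reference = "original") {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), length(channels) == nrow(data), sfreq > 0)
  if (any(!is.finite(data))) {
    stop("recording contains non-finite samples", call. = FALSE)
  }
  reference <- match.arg(reference, c("original", "average"))
  rownames(data) <- channels
  structure(
    list(data = data, sfreq = sfreq, channels = as.character(channels),
         reference = reference),
    class = "eeg_recording"
  )
}

#' Epoched EEG
#'
#' Container for segmented EEG: a channels x samples x epochs array with
#' sampling rate, channel names and reference state.
#'
#' @param data Numeric 3-D array `[channel, sample, epoch]`.
#' @param sfreq Sampling rate in Hz.
#' @param channels Channel names, one per array row.
#' @param reference `"original"` or `"average"`.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, sfreq, channels, reference = "original") {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  stopifnot(length(channels) == dim(data)[1], sfreq > 0)
  if (any(!is.finite(data))) {
    stop("epochs contain non-finite samples", call. = FALSE)
  }
  reference <- match.arg(reference, c("original", "average"))
  dimnames(data) <- list(channels, NULL, NULL)
  structure(
    list(data = data, sfreq = sfreq, channels = as.character(channels),
         reference = reference),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %s reference\n",
    nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq, x$reference
  ))
  invisible(x)
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> %d epochs x %d channels x %d samples @ %g Hz, %s reference\n",
    d[3], d[1], d[2], x$sfreq, x$reference
  ))
  invisible(x)
}

n_epochs <- function(ep) dim(ep$data)[3]
n_samples <- function(x) if (inherits(x, "eeg_epochs")) dim(x$data)[2] else ncol(x$data)

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every sample, so the
#' channel mean is zero at every time point. Idempotent; a prerequisite for
#' topographic (microstate) analysis.
#'
#' @param x An `eeg_recording` or `eeg_epochs` object.
#' @return The same class of object with `reference = "average"`.
#' @export
average_reference <- function(x) {
  UseMethod("average_reference")
}

#' @export
average_reference.eeg_recording <- function(x) {
  if (nrow(x$data) < 2) stop("average reference needs >= 2 channels", call. = FALSE)
  x$data <- sweep(x$data, 2, colMeans(x$data))
  x$reference <- "average"
  x
}

#' @export
average_reference.eeg_epochs <- function(x) {
  d <- dim(x$data)
  if (d[1] < 2) stop("average reference needs >= 2 channels", call. = FALSE)
  m <- matrix(x$data, nrow = d[1])
  m <- sweep(m, 2, colMeans(m))
  x$data <- array(m, dim = d, dimnames = dimnames(x$data))
  x$reference <- "average"
  x
}

#' Coerce epoched EEG to a long tibble
#'
#' @param x An `eeg_epochs` object.
#' @param ... Unused.
#' @return Tibble with columns `epoch`, `channel`, `time_s`, `value`.
#' @export
as_tibble.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    epoch = rep(seq_len(d[3]), each = d[1] * d[2]),
    channel = rep(x$channels, times = d[2] * d[3]),
    time_s = rep(rep((seq_len(d[2]) - 1) / x$sfreq, each = d[1]), times = d[3]),
    value = as.vector(x$data)
  )
}

# one epoch as channels x samples matrix
epoch_matrix <- function(ep, i) {
  ep$data[, , i, drop = TRUE]
}
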