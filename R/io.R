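#' Load a recording and reduce it to a montage
#'
#' Reads an EDF file (by extension `.edf`) or a delimited text matrix
#' (channels as columns, header row of channel names), then subsets and
#' reorders the channels to the requested montage. Extra channels are
#' dropped; a missing montage channel is an error naming it.
#'
#' @param path Path to an EDF or delimited text file.
#' @param montage An `eeg_montage` tibble; defaults to [montage_1020()].
#' @return An `eeg_recording` with channels in montage order.
#' @export
load_recording <- function(path, montage = montage_1020()) {
  validate_montage(montage)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    read_edf(path)
  } else {
    read_eeg_delim(path)
  }
  missing <- setdiff(montage$channel, rec$channels)
  if (length(missing) > 0) {
    stop(
      "recording is missing montage channel(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  idx <- match(montage$channel, rec$channels)
  eeg_recording(rec$data[idx, , drop = FALSE], rec$sfreq, montage$channel,
    reference = rec$reference
  )
}

#' Read / write a delimited EEG matrix
#'
#' Plain-text interchange format: one column per channel (header row of
#' names), one row per sample. The sampling rate is carried in a
#' `# sfreq=<hz>` comment on the first line.
#'
#' @param path File path.
#' @return An `eeg_recording`.
#' @export
read_eeg_delim <- function(path) {
  first <- readLines(path, n = 1L)
  sfreq <- NA_real_
  skip <- 0L
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("sfreq=([0-9.]+)", first))[[1]]
    if (length(m) == 2) sfreq <- as.numeric(m[2])
    skip <- 1L
  }
  if (!is.finite(sfreq)) {
    stop("delimited EEG file must carry '# sfreq=<hz>' on its first line",
      call. = FALSE
    )
  }
  df <- utils::read.delim(path, skip = skip, check.names = FALSE)
  data <- t(as.matrix(df))
  eeg_recording(data, sfreq, colnames(df))
}

#' @rdname read_eeg_delim
#' @param rec An `eeg_recording` to write.
#' @export
write_eeg_delim <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sfreq=%.10g", rec$sfreq), con)
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channels
  utils::write.table(df, con,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Minimal EDF reader and writer
#'
#' Reads and writes European Data Format files with identical sampling rate
#' across signals and 16-bit sample quantization. Covers the plain EDF subset
#' used for resting-state exports (no annotations, no EDF+ discontinuities).
#' Round-tripping through [write_edf()] quantizes each channel to 16 bits of
#' its own physical range.
#'
#' @param path File path.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_chr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr_chr(8) # version
  hdr_chr(80); hdr_chr(80); hdr_chr(8); hdr_chr(8) # patient/recording/date/time
  hdr_chr(8) # header bytes
  hdr_chr(44) # reserved
  n_records <- as.integer(hdr_chr(8))
  rec_dur <- as.numeric(hdr_chr(8))
  ns <- as.integer(hdr_chr(4))
  per_sig <- function(width) vapply(seq_len(ns), function(i) hdr_chr(width), "")
  labels <- per_sig(16)
  per_sig(80) # transducer
  per_sig(8) # dimension
  phys_min <- as.numeric(per_sig(8))
  phys_max <- as.numeric(per_sig(8))
  dig_min <- as.numeric(per_sig(8))
  dig_max <- as.numeric(per_sig(8))
  per_sig(80) # prefilter
  spr <- as.integer(per_sig(8))
  per_sig(32) # reserved
  if (length(unique(spr)) != 1L) {
    stop("read_edf supports a single sampling rate across signals", call. = FALSE)
  }
  sfreq <- spr[1] / rec_dur
  out <- matrix(0, nrow = ns, ncol = n_records * spr[1])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
      out[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
        (dig - dig_min[s]) * scale[s] + phys_min[s]
    }
  }
  eeg_recording(out, sfreq, labels)
}

#' @rdname read_edf
#' @param rec An `eeg_recording` to write. The recording is split into
#'   1-second data records when the sampling rate is an integer (trailing
#'   partial seconds are an error); otherwise a single record holds the
#'   whole signal.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  total <- ncol(rec$data)
  if (abs(rec$sfreq - round(rec$sfreq)) < 1e-9 && total %% round(rec$sfreq) == 0) {
    spr <- as.integer(round(rec$sfreq))
    n_records <- total %/% spr
    rec_dur <- 1
  } else {
    spr <- total
    n_records <- 1L
    rec_dur <- total / rec$sfreq
  }
  rng <- apply(rec$data, 1, function(v) max(abs(v), 1e-6))
  phys_min <- -rng
  phys_max <- rng
  dig_min <- -32767
  dig_max <- 32767
  pad <- function(x, n) {
    x <- substr(format(x), 1, n)
    formatC(x, width = -n, flag = " ")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wchr <- function(x) writeBin(charToRaw(x), con)
  header_bytes <- 256L + 256L * ns
  wchr(pad("0", 8))
  wchr(pad("X", 80)); wchr(pad("X", 80))
  wchr(pad("01.01.00", 8)); wchr(pad("00.00.00", 8))
  wchr(pad(header_bytes, 8))
  wchr(pad("", 44))
  wchr(pad(n_records, 8))
  wchr(pad(format(rec_dur, digits = 7), 8))
  wchr(pad(ns, 4))
  wsig <- function(vals, width) for (v in vals) wchr(pad(v, width))
  wsig(rec$channels, 16)
  wsig(rep("", ns), 80)
  wsig(rep("uV", ns), 8)
  wsig(formatC(phys_min, digits = 6, format = "g"), 8)
  wsig(formatC(phys_max, digits = 6, format = "g"), 8)
  wsig(rep(dig_min, ns), 8)
  wsig(rep(dig_max, ns), 8)
  wsig(rep("", ns), 80)
  wsig(rep(spr, ns), 8)
  wsig(rep("", ns), 32)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (s in seq_len(ns)) {
      dig <- as.integer(round((rec$data[s, cols] - phys_min[s]) / scale[s] + dig_min))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
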