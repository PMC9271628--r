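# shared fixtures, all generated in code

mont19 <- montage_1020()

# multichannel recording carrying a named sinusoid per channel
make_sine_recording <- function(sfreq = 125, dur_s = 10, freqs = NULL,
                                channels = mont19$channel) {
  n <- round(sfreq * dur_s)
  t <- (seq_len(n) - 1) / sfreq
  if (is.null(freqs)) freqs <- seq(2, 40, length.out = length(channels))
  data <- t(vapply(freqs, function(f) sin(2 * pi * f * t), numeric(n)))
  eeg_recording(data, sfreq, channels)
}

# epochs whose every sample is a fixed map times a carrier value
map_epochs <- function(map, carrier, n_epochs = 1, sfreq = 125,
                       channels = mont19$channel) {
  nc <- length(map)
  len <- length(carrier)
  arr <- array(rep(outer(map, carrier), n_epochs), dim = c(nc, len, n_epochs))
  average_reference(eeg_epochs(arr, sfreq, channels))
}

# four mutually orthogonal zero-mean unit-GFP templates on the montage
orthogonal_templates <- function(seed = 99, channels = mont19$channel) {
  set.seed(seed)
  nc <- length(channels)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(nc * 4), nc))))[, 2:5]
  m <- microdyn:::normalize_maps(q)
  prototype_set(m, channels, labels = c("A", "B", "C", "D"), source = "synthetic")
}

# tiny generative spec for fast tests
tiny_spec <- function(...) {
  microstate_spec(n_epochs = 5, n_subjects_per_group = 2, ...)
}

# long-format outcome table for the mixed-design ANCOVA
make_rm_data <- function(n = 16, seed = 1, class_effect = 0.5,
                         interaction = 0, group_effect = 0) {
  set.seed(seed)
  long <- expand.grid(
    subject_id = sprintf("s%02d", seq_len(n)),
    class = c("A", "B", "C", "D"), stringsAsFactors = FALSE
  )
  info <- data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    group = rep(c("NC", "LLS"), each = n / 2),
    age = runif(n, 60, 90), stringsAsFactors = FALSE
  )
  long <- merge(long, info)
  ci <- as.numeric(factor(long$class))
  long$value <- rnorm(nrow(long)) + class_effect * ci +
    group_effect * (long$group == "LLS") +
    interaction * ci * (long$group == "LLS")
  long
}
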