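#' Generative specification for a synthetic microstate cohort
#'
#' Collects the ground-truth parameters of the semi-Markov microstate
#' emulator: per-class mean dwell times in the canonical 60-120 ms regime, a
#' zero-diagonal row-stochastic class transition matrix, an alpha-band
#' carrier, the target signal-to-noise ratio, and the rank structure of the
#' spatially correlated noise. Defaults mirror a 19-channel, 125 Hz,
#' twenty-epoch resting-state session of 2,000-ms epochs.
#'
#' @param mean_duration_ms Named per-class mean dwell time (ms); each must be
#'   at least 2 samples at `sampling_rate_hz`.
#' @param transition_matrix 4 x 4 row-stochastic matrix with zero diagonal
#'   (rows/cols in class order A-D).
#' @param carrier_freq_hz Oscillatory carrier frequency (default 10 Hz, the
#'   alpha band that dominates microstate dynamics).
#' @param snr Prototype signal power over noise power; must be positive
#'   (`Inf` = noiseless).
#' @param noise_spatial_rank Rank of the spatially correlated background
#'   noise covariance (1..19).
#' @param anterior_noise_rank Number of additional independent noise
#'   components confined to the anterior electrodes (0 disables; used to
#'   raise anterior spatial complexity in patient-like cohorts).
#' @param anterior_noise_power Power of the anterior-only components relative
#'   to the background noise.
#' @param n_subjects_per_group Cohort size per group.
#' @param epoch_length_ms,n_epochs,sampling_rate_hz Epoch geometry.
#' @param duration_jitter_sd Between-subject log-normal jitter (sdlog) on
#'   mean dwell times.
#' @param transition_jitter_sd Between-subject log-normal jitter on
#'   off-diagonal transition mass (renormalized per row).
#' @param prototype_jitter Smooth per-subject perturbation of the canonical
#'   prototype maps (see [generate_prototype_maps()]).
#' @param class_labels Class labels (fixed at A-D).
#' @return A validated `microstate_spec` object.
#' @export
microstate_spec <- function(mean_duration_ms = c(A = 80, B = 75, C = 90, D = 70),
                            transition_matrix = default_transitions("NC"),
                            carrier_freq_hz = 10,
                            snr = 10,
                            noise_spatial_rank = 6,
                            anterior_noise_rank = 0,
                            anterior_noise_power = 0.5,
                            n_subjects_per_group = 20,
                            epoch_length_ms = 2000,
                            n_epochs = 20,
                            sampling_rate_hz = 125,
                            duration_jitter_sd = 0.06,
                            transition_jitter_sd = 0.10,
                            prototype_jitter = 0.05,
                            class_labels = c("A", "B", "C", "D")) {
  spec <- structure(
    list(
      class_labels = class_labels,
      mean_duration_ms = mean_duration_ms,
      transition_matrix = transition_matrix,
      carrier_freq_hz = carrier_freq_hz,
      snr = snr,
      noise_spatial_rank = noise_spatial_rank,
      anterior_noise_rank = anterior_noise_rank,
      anterior_noise_power = anterior_noise_power,
      n_subjects_per_group = n_subjects_per_group,
      epoch_length_ms = epoch_length_ms,
      n_epochs = n_epochs,
      sampling_rate_hz = sampling_rate_hz,
      duration_jitter_sd = duration_jitter_sd,
      transition_jitter_sd = transition_jitter_sd,
      prototype_jitter = prototype_jitter
    ),
    class = "microstate_spec"
  )
  validate_spec(spec)
}

validate_spec <- function(spec) {
  k <- length(spec$class_labels)
  tm <- spec$transition_matrix
  stopifnot(is.matrix(tm), nrow(tm) == k, ncol(tm) == k)
  if (any(diag(tm) != 0)) {
    stop("transition matrix diagonal must be exactly zero (no self-transitions)",
      call. = FALSE
    )
  }
  if (any(abs(rowSums(tm) - 1) > 1e-12)) {
    stop("transition matrix rows must sum to 1", call. = FALSE)
  }
  if (any(tm < 0)) stop("transition probabilities must be non-negative", call. = FALSE)
  md <- spec$mean_duration_ms
  stopifnot(length(md) == k, all(md > 0))
  min_ms <- 2 / spec$sampling_rate_hz * 1000
  if (any(md < min_ms)) {
    stop("mean_duration_ms must be at least 2 samples (", round(min_ms, 2),
      " ms at ", spec$sampling_rate_hz, " Hz)",
      call. = FALSE
    )
  }
  if (!(spec$snr > 0)) stop("snr must be positive", call. = FALSE)
  stopifnot(
    spec$carrier_freq_hz > 0,
    spec$noise_spatial_rank >= 1, spec$noise_spatial_rank <= 19,
    spec$anterior_noise_rank >= 0, spec$anterior_noise_rank <= 7,
    spec$epoch_length_ms > 0, spec$n_epochs >= 1, spec$sampling_rate_hz > 0
  )
  spec
}

#' Built-in transition matrices for the two group archetypes
#'
#' `"NC"` is a near-uniform syntax with slightly elevated A->B and A->C
#' mass; `"LLS"` lowers the transitions out of A toward B and C and raises
#' the B<->D exchange, the qualitative syntax pattern of the patient group.
#'
#' @param group `"NC"` or `"LLS"`.
#' @return A 4 x 4 zero-diagonal row-stochastic matrix.
#' @export
default_transitions <- function(group = c("NC", "LLS")) {
  group <- match.arg(group)
  labs <- c("A", "B", "C", "D")
  m <- if (group == "NC") {
    rbind(
      c(0.00, 0.38, 0.38, 0.24),
      c(0.40, 0.00, 0.35, 0.25),
      c(0.40, 0.35, 0.00, 0.25),
      c(0.40, 0.25, 0.35, 0.00)
    )
  } else {
    rbind(
      c(0.00, 0.27, 0.27, 0.46),
      c(0.30, 0.00, 0.28, 0.42),
      c(0.40, 0.35, 0.00, 0.25),
      c(0.30, 0.44, 0.26, 0.00)
    )
  }
  dimnames(m) <- list(from = labs, to = labs)
  m
}

#' Default group generative specifications
#'
#' The control-like spec uses dwell times in the canonical regime and
#' moderate-rank background noise; the patient-like spec encodes the
#' qualitative group contrasts: longer dwell times (hence fewer onsets),
#' more B<->D transition mass, and extra anterior noise components raising
#' anterior spatial complexity.
#'
#' @return A `microstate_spec`.
#' @export
nc_spec_default <- function() {
  microstate_spec()
}

#' @rdname nc_spec_default
#' @export
lls_spec_default <- function() {
  microstate_spec(
    mean_duration_ms = c(A = 100, B = 80, C = 95, D = 110),
    transition_matrix = default_transitions("LLS"),
    noise_spatial_rank = 8,
    anterior_noise_rank = 4,
    anterior_noise_power = 0.6
  )
}

#' Sample a ground-truth microstate label sequence
#'
#' Semi-Markov emulation: within each epoch, dwell times are drawn per class
#' from a gamma distribution (shape 2, mean equal to the class's mean dwell
#' time) discretized to samples and truncated below at 2 samples; the
#' successor class is drawn from the corresponding transition-matrix row.
#' Runs never cross epoch boundaries (the final run of an epoch is truncated
#' by the boundary). The returned summary statistics are computed from the
#' realized sequence, not from the spec.
#'
#' @param spec A `microstate_spec`.
#' @param seed Integer seed.
#' @return A `ground_truth` object: `sequence` (a `label_sequence` tibble),
#'   `parameters` (realized per-class duration/occurrence/coverage),
#'   `transitions` (realized conditional transition matrix, with counts in
#'   its `counts` attribute), and the generating `spec`.
#' @export
sample_state_sequence <- function(spec, seed = 1) {
  validate_spec(spec)
  set.seed(as.integer(seed %% .Machine$integer.max))
  fs <- spec$sampling_rate_hz
  len <- as.integer(round(spec$epoch_length_ms / 1000 * fs))
  k <- length(spec$class_labels)
  # pre-drawn gamma dwell-time pools per class (shape 2, mean = class dwell),
  # discretized to samples and floored at 2; refilled if exhausted
  mean_run <- max(2, mean(spec$mean_duration_ms) / 1000 * fs)
  pool_n <- as.integer(ceiling(1.5 * spec$n_epochs * len / mean_run / k) + 20L)
  pools <- lapply(seq_len(k), function(ci) {
    ms <- stats::rgamma(pool_n, shape = 2, scale = spec$mean_duration_ms[ci] / 2)
    pmax(2L, as.integer(round(ms / 1000 * fs)))
  })
  used <- integer(k)
  draw_run <- function(ci) {
    used[ci] <<- used[ci] + 1L
    if (used[ci] > length(pools[[ci]])) {
      ms <- stats::rgamma(pool_n, shape = 2,
        scale = spec$mean_duration_ms[ci] / 2)
      pools[[ci]] <<- c(pools[[ci]], pmax(2L, as.integer(round(ms / 1000 * fs))))
    }
    pools[[ci]][used[ci]]
  }
  tm_cum <- t(apply(spec$transition_matrix, 1, cumsum))
  epochs <- lapply(seq_len(spec$n_epochs), function(e) {
    lab <- integer(len)
    pos <- 1L
    state <- sample.int(k, 1)
    while (pos <= len) {
      run <- min(draw_run(state), len - pos + 1L)
      lab[pos:(pos + run - 1L)] <- state
      pos <- pos + run
      state <- findInterval(stats::runif(1), tm_cum[state, ]) + 1L
    }
    lab
  })
  seq_tbl <- tibble::tibble(
    epoch = rep(seq_len(spec$n_epochs), each = len),
    sample = rep(seq_len(len), times = spec$n_epochs),
    label = spec$class_labels[unlist(epochs)],
    fit = NA_real_
  )
  attr(seq_tbl, "sfreq") <- fs
  attr(seq_tbl, "labels") <- spec$class_labels
  attr(seq_tbl, "n_zero_variance") <- 0L
  class(seq_tbl) <- c("label_sequence", class(seq_tbl))
  structure(
    list(
      sequence = seq_tbl,
      parameters = compute_parameters(seq_tbl),
      transitions = transition_probabilities(seq_tbl),
      spec = spec
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> realized microstate sequence\n")
  print(x$parameters)
  invisible(x)
}

# rank-structured noise: a random orthonormal basis with geometric eigenvalue
# decay down to the stated rank, plus optional anterior-only components
noise_model <- function(spec, montage) {
  nc <- nrow(montage)
  q <- qr.Q(qr(matrix(stats::rnorm(nc * nc), nc)))
  r <- spec$noise_spatial_rank
  ev <- 0.7^(seq_len(r) - 1)
  ev <- ev / sum(ev)
  base <- list(basis = q[, seq_len(r), drop = FALSE], sd = sqrt(ev))
  ant <- NULL
  if (spec$anterior_noise_rank > 0) {
    a_idx <- which(montage$region == "anterior")
    ra <- spec$anterior_noise_rank
    qa <- qr.Q(qr(matrix(stats::rnorm(length(a_idx) * ra), length(a_idx))))[, seq_len(ra), drop = FALSE]
    eva <- rep(1 / ra, ra) * spec$anterior_noise_power
    basis <- matrix(0, nc, ra)
    basis[a_idx, ] <- qa
    ant <- list(basis = basis, sd = sqrt(eva))
  }
  list(base = base, ant = ant)
}

draw_noise <- function(model, n_samples) {
  draw1 <- function(m) {
    m$basis %*% (matrix(stats::rnorm(ncol(m$basis) * n_samples), ncol(m$basis)) * m$sd)
  }
  out <- draw1(model$base)
  if (!is.null(model$ant)) out <- out + draw1(model$ant)
  out
}

#' Synthesize multichannel EEG from a ground-truth sequence
#'
#' Each sample's topography is the prototype of the active class modulated by
#' an alpha-band sinusoidal carrier whose polarity flips randomly per run
#' (phase 0 or pi, so polarity invariance of the analysis is genuinely
#' exercised), scaled against spatially correlated Gaussian noise of the
#' stated rank to the target signal-to-noise ratio. The output is
#' average-referenced.
#'
#' @param truth A `ground_truth` from [sample_state_sequence()].
#' @param spec The generating `microstate_spec` (defaults to `truth$spec`).
#' @param seed Integer seed for carrier phases and noise.
#' @param prototypes Optional `prototype_set`; defaults to seeded
#'   [generate_prototype_maps()] on the standard montage.
#' @param montage Montage (default [montage_1020()]).
#' @return An average-referenced `eeg_epochs` object; the prototypes used are
#'   attached as attribute `prototypes`.
#' @export
synthesize_eeg <- function(truth, spec = truth$spec, seed = 1,
                           prototypes = NULL, montage = montage_1020()) {
  stopifnot(inherits(truth, "ground_truth"))
  validate_spec(spec)
  if (!(spec$snr > 0)) stop("snr must be positive", call. = FALSE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  if (is.null(prototypes)) {
    prototypes <- generate_prototype_maps(montage,
      seed = seed + 1,
      jitter = spec$prototype_jitter
    )
  }
  fs <- spec$sampling_rate_hz
  len <- as.integer(round(spec$epoch_length_ms / 1000 * fs))
  nc <- nrow(montage)
  noise <- if (is.finite(spec$snr)) noise_model(spec, montage) else NULL
  arr <- array(0, dim = c(nc, len, spec$n_epochs))
  tvec <- (seq_len(len) - 1) / fs
  sig_pow <- 0
  for (e in seq_len(spec$n_epochs)) {
    lab <- truth$sequence$label[truth$sequence$epoch == e]
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    carrier <- numeric(len)
    for (j in seq_along(r$lengths)) {
      phi <- sample(c(0, pi), 1)
      span <- starts[j]:ends[j]
      carrier[span] <- sin(2 * pi * spec$carrier_freq_hz * tvec[span] + phi)
    }
    proto_idx <- match(lab, prototypes$labels)
    arr[, , e] <- prototypes$maps[, proto_idx, drop = FALSE] *
      rep(carrier, each = nc)
  }
  sig_pow <- mean(arr^2)
  if (!is.null(noise)) {
    target_noise_pow <- sig_pow / spec$snr
    nz <- array(0, dim = dim(arr))
    for (e in seq_len(spec$n_epochs)) nz[, , e] <- draw_noise(noise, len)
    nz <- nz * sqrt(target_noise_pow / mean(nz^2))
    arr <- arr + nz
  }
  ep <- eeg_epochs(arr, fs, montage$channel, reference = "original")
  ep <- average_reference(ep)
  attr(ep, "prototypes") <- prototypes
  ep
}

#' Generate a two-group synthetic cohort
#'
#' Draws `n_subjects_per_group` subjects per group from the two generative
#' specs, applying per-subject log-normal jitter to dwell times and
#' transition mass, a smooth per-subject perturbation to the prototype maps,
#' and ages from group-specific truncated normal models. Subject seeds are
#' derived from the master seed by a counter, so extending the cohort never
#' reshuffles existing subjects.
#'
#' @param nc_spec,lls_spec Group `microstate_spec`s (defaults
#'   [nc_spec_default()] / [lls_spec_default()]).
#' @param age_model Named list with per-group `c(mean, sd)` of the age
#'   distribution (years), truncated to 60-90.
#' @param seed Master integer seed.
#' @param synthesize Set `FALSE` to skip EEG synthesis and keep only the
#'   ground-truth sequences (fast path for calibration studies).
#' @return A tibble with one row per subject: `subject_id`, `group`, `age`,
#'   `seed`, list-columns `truth` (and `epochs` unless `synthesize = FALSE`).
#' @export
generate_group_cohort <- function(nc_spec = nc_spec_default(),
                                  lls_spec = lls_spec_default(),
                                  age_model = list(
                                    NC = c(mean = 69.3, sd = 6.93),
                                    LLS = c(mean = 68.23, sd = 5.43)
                                  ),
                                  seed = 1,
                                  synthesize = TRUE) {
  specs <- list(NC = validate_spec(nc_spec), LLS = validate_spec(lls_spec))
  montage <- montage_1020()
  rows <- list()
  counter <- 0L
  for (g in names(specs)) {
    spec <- specs[[g]]
    n <- spec$n_subjects_per_group
    if (n == 0) next
    for (i in seq_len(n)) {
      counter <- counter + 1L
      s_seed <- as.integer((as.numeric(seed) + 7919 * counter) %% 2147483647)
      set.seed(s_seed)
      age <- truncnorm1(age_model[[g]]["mean"], age_model[[g]]["sd"], 60, 90)
      sub_spec <- jitter_spec(spec)
      truth <- sample_state_sequence(sub_spec, seed = s_seed + 1)
      row <- tibble::tibble(
        subject_id = sprintf("%s%02d", tolower(g), i),
        group = g, age = age, seed = s_seed,
        truth = list(truth)
      )
      if (synthesize) {
        row$epochs <- list(synthesize_eeg(truth, sub_spec, seed = s_seed + 2,
          montage = montage
        ))
      }
      rows[[counter]] <- row
    }
  }
  if (length(rows) == 0) {
    out <- tibble::tibble(
      subject_id = character(), group = character(), age = numeric(),
      seed = integer(), truth = list()
    )
    if (synthesize) out$epochs <- list()
    return(out)
  }
  dplyr::bind_rows(rows)
}

truncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(unname(x))
  }
}

# per-subject jitter of dwell times and transition mass (uses the current RNG
# stream; called inside generate_group_cohort after set.seed)
jitter_spec <- function(spec) {
  md <- spec$mean_duration_ms *
    stats::rlnorm(length(spec$mean_duration_ms), 0, spec$duration_jitter_sd)
  tm <- spec$transition_matrix
  if (spec$transition_jitter_sd > 0) {
    jit <- matrix(stats::rlnorm(length(tm), 0, spec$transition_jitter_sd), nrow(tm))
    tm <- tm * jit
    diag(tm) <- 0
    tm <- tm / rowSums(tm)
  }
  spec$mean_duration_ms <- md
  spec$transition_matrix <- tm
  validate_spec(spec)
}

#' Realized ground-truth outcomes of a cohort
#'
#' Flattens each subject's realized (not nominal) parameters and transition
#' probabilities into the same long format as [cohort_outcomes()], for
#' recovery comparisons against back-fitted estimates.
#'
#' @param cohort Tibble from [generate_group_cohort()].
#' @return Long tibble: `subject_id`, `group`, `age`, `measure`, `class`,
#'   `value`.
#' @export
truth_outcomes <- function(cohort) {
  stopifnot(is.data.frame(cohort), "truth" %in% names(cohort))
  reports <- cohort
  reports$report <- lapply(cohort$truth, function(tr) {
    structure(
      list(parameters = tr$parameters, transitions = tr$transitions),
      class = "microstate_report"
    )
  })
  cohort_outcomes(reports)
}

#' Write a synthetic cohort to disk
#'
#' One EDF file per subject (epochs concatenated back to a continuous
#' recording), a cohort manifest CSV (`subject_id`, `group`, `age`, `seed`,
#' `edf`, `truth`), and one ground-truth JSON per subject holding the
#' realized parameters, the realized transition matrix, and a run-length
#' encoding of the label sequence per epoch.
#'
#' @param cohort Tibble from [generate_group_cohort()] (with `epochs`).
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly; written as `manifest.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(is.data.frame(cohort), all(c("epochs", "truth") %in% names(cohort)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(seq_len(nrow(cohort)), function(i) {
    ep <- cohort$epochs[[i]]
    d <- dim(ep$data)
    rec <- eeg_recording(matrix(ep$data, nrow = d[1]), ep$sfreq, ep$channels,
      reference = ep$reference
    )
    edf <- file.path(dir, paste0(cohort$subject_id[i], ".edf"))
    write_edf(rec, edf)
    tr <- cohort$truth[[i]]
    rle_epochs <- lapply(split(tr$sequence$label, tr$sequence$epoch), function(lab) {
      r <- rle(lab)
      list(lengths = r$lengths, values = r$values)
    })
    tj <- file.path(dir, paste0(cohort$subject_id[i], "_truth.json"))
    jsonlite::write_json(
      list(
        subject_id = cohort$subject_id[i],
        parameters = tr$parameters,
        transitions = as.data.frame(unclass(tr$transitions)),
        sequence_rle = rle_epochs
      ),
      tj,
      auto_unbox = TRUE, digits = NA
    )
    tibble::tibble(
      subject_id = cohort$subject_id[i], group = cohort$group[i],
      age = cohort$age[i], seed = cohort$seed[i],
      edf = basename(edf), truth = basename(tj)
    )
  })
  manifest <- dplyr::bind_rows(manifest)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}
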