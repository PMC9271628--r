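#' Per-epoch channel covariance matrices
#'
#' Sample covariance across an epoch's time samples (per-channel time mean
#' removed), for the full montage or an electrode subset.
#'
#' @param ep An `eeg_epochs` object.
#' @param channels Optional character vector selecting an electrode subset;
#'   `NULL` uses all channels.
#' @return List of symmetric positive semidefinite matrices, one per epoch.
#' @export
build_covariance <- function(ep, channels = NULL) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (is.null(channels)) channels <- ep$channels
  if (length(channels) == 0) stop("empty electrode subset", call. = FALSE)
  unknown <- setdiff(channels, ep$channels)
  if (length(unknown) > 0) {
    stop("unknown electrode(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  idx <- match(channels, ep$channels)
  d <- dim(ep$data)
  if (d[2] <= length(idx)) {
    stop("epoch length (", d[2], ") must exceed subset size (", length(idx), ")",
      call. = FALSE
    )
  }
  lapply(seq_len(d[3]), function(e) {
    x <- t(ep$data[idx, , e, drop = TRUE])
    cv <- stats::cov(x)
    dimnames(cv) <- list(channels, channels)
    cv
  })
}

#' Eigenvalue spectrum of a covariance matrix
#'
#' Real eigenvalues in descending order. Tiny negative values from floating
#' point (above `-1e-10 * max`) are clipped to zero; anything more negative
#' is an error because the input was not positive semidefinite.
#'
#' @param cov A symmetric matrix.
#' @return An `eigen_spectrum`: numeric vector of eigenvalues, descending,
#'   with attribute `k` (its length).
#' @export
eigen_spectrum <- function(cov) {
  cov <- as.matrix(cov)
  if (!isSymmetric(unname(cov), tol = 1e-8)) {
    stop("covariance matrix must be symmetric", call. = FALSE)
  }
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(abs(ev), 0)
  if (any(ev < -1e-10 * max(mx, 1))) {
    stop("matrix has a substantially negative eigenvalue; not a covariance",
      call. = FALSE
    )
  }
  ev[ev < 0] <- 0
  ev <- sort(ev, decreasing = TRUE)
  structure(ev, k = length(ev), class = "eigen_spectrum")
}

#' Normalize an eigenvalue spectrum to unit sum
#'
#' Each eigenvalue is divided by the total, so the spectrum becomes a
#' probability distribution over components.
#'
#' @param s An `eigen_spectrum` (or non-negative numeric vector).
#' @return The normalized `eigen_spectrum`; attribute `normalized = TRUE`.
#' @export
normalize_spectrum <- function(s) {
  v <- as.numeric(s)
  if (any(v < 0)) stop("eigenvalues must be non-negative", call. = FALSE)
  tot <- sum(v)
  if (tot <= 0) stop("cannot normalize an all-zero spectrum", call. = FALSE)
  out <- structure(v / tot,
    k = length(v), normalized = TRUE,
    class = "eigen_spectrum"
  )
  out
}

#' Omega spatial complexity of a normalized spectrum
#'
#' The exponential of the Shannon entropy (natural log) of the normalized
#' eigenvalue spectrum: `exp(-sum(l' * log(l')))` with the `0 * log 0 := 0`
#' convention. Ranges from 1 (rank-1 covariance: one global synchronized
#' process) to k, the number of electrodes (perfectly uniform spectrum: k
#' independent processes).
#'
#' @param s A normalized `eigen_spectrum` (sums to 1 within 1e-9).
#' @return A single number in `[1, k]`.
#' @export
omega_complexity <- function(s) {
  v <- as.numeric(s)
  if (abs(sum(v) - 1) > 1e-9) {
    stop("spectrum is not normalized; call normalize_spectrum() first",
      call. = FALSE
    )
  }
  nz <- v[v > 0]
  exp(-sum(nz * log(nz)))
}

# covariance matrix -> omega in one step
omega_of_cov <- function(cov) {
  omega_complexity(normalize_spectrum(eigen_spectrum(cov)))
}

#' Subject-level omega complexity
#'
#' Computes omega complexity per epoch for the global 19-channel set and the
#' anterior/posterior 7-electrode subsets, then aggregates across epochs
#' (mean by default; a concatenated mode pools all epochs into one
#' covariance).
#'
#' @param ep Preprocessed `eeg_epochs` on the full montage.
#' @param montage The montage defining the regional subsets (default
#'   [montage_1020()]).
#' @param mode `"per_epoch_mean"` (default) or `"concatenated"`.
#' @param matrix_type `"covariance"` (default) or `"correlation"`.
#' @return A one-row tibble of class `omega_result`: `omega_global`,
#'   `omega_anterior`, `omega_posterior`, `n_epochs`, `mode`; the per-epoch
#'   values are in attribute `per_epoch`.
#' @export
subject_omega <- function(ep, montage = montage_1020(),
                          mode = c("per_epoch_mean", "concatenated"),
                          matrix_type = c("covariance", "correlation")) {
  mode <- match.arg(mode)
  matrix_type <- match.arg(matrix_type)
  subsets <- list(
    global = montage$channel,
    anterior = anterior_channels(montage),
    posterior = posterior_channels(montage)
  )
  to_corr <- function(cv) stats::cov2cor(cv)
  if (mode == "per_epoch_mean") {
    per_epoch <- lapply(subsets, function(chs) {
      covs <- build_covariance(ep, chs)
      if (matrix_type == "correlation") covs <- lapply(covs, to_corr)
      vapply(covs, omega_of_cov, 0)
    })
    vals <- vapply(per_epoch, mean, 0)
    pe <- tibble::tibble(
      epoch = seq_len(n_epochs(ep)),
      omega_global = per_epoch$global,
      omega_anterior = per_epoch$anterior,
      omega_posterior = per_epoch$posterior
    )
  } else {
    d <- dim(ep$data)
    flat <- eeg_epochs(
      array(ep$data, dim = c(d[1], d[2] * d[3], 1)),
      ep$sfreq, ep$channels, ep$reference
    )
    vals <- vapply(subsets, function(chs) {
      cv <- build_covariance(flat, chs)[[1]]
      if (matrix_type == "correlation") cv <- to_corr(cv)
      omega_of_cov(cv)
    }, 0)
    pe <- NULL
  }
  out <- tibble::tibble(
    omega_global = vals[["global"]],
    omega_anterior = vals[["anterior"]],
    omega_posterior = vals[["posterior"]],
    n_epochs = n_epochs(ep),
    mode = mode
  )
  attr(out, "per_epoch") <- pe
  class(out) <- c("omega_result", class(out))
  out
}

#' Omega complexity for every subject of a cohort
#'
#' @param cohort Data frame with an `epochs` list-column plus identifying
#'   columns (`subject_id`, `group`, `age` are carried through).
#' @param ... Passed to [subject_omega()].
#' @return Tibble, one row per subject.
#' @export
cohort_omega <- function(cohort, ...) {
  stopifnot(is.data.frame(cohort), "epochs" %in% names(cohort))
  keep <- intersect(c("subject_id", "group", "age"), names(cohort))
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    om <- subject_omega(cohort$epochs[[i]], ...)
    for (col in rev(keep)) om[[col]] <- cohort[[col]][[i]]
    om[, c(keep, "omega_global", "omega_anterior", "omega_posterior", "n_epochs")]
  })
  dplyr::bind_rows(rows)
}
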