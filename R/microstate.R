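#' Global field power
#'
#' GFP at a time point is the spatial standard deviation of the
#' average-referenced potential across electrodes (population form, dividing
#' by the channel count). Its peaks carry the topographies with the highest
#' signal-to-noise ratio.
#'
#' @param ep An average-referenced `eeg_epochs` object.
#' @return A tibble of class `gfp_series` with columns `epoch`, `sample`,
#'   `time_s`, `gfp`; the sampling rate is carried in attribute `sfreq`.
#' @export
compute_gfp <- function(ep) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (ep$reference != "average") {
    stop("GFP requires average-referenced epochs; call average_reference() first",
      call. = FALSE
    )
  }
  d <- dim(ep$data)
  m <- matrix(ep$data, nrow = d[1]) # channels x (samples*epochs)
  g <- sqrt(colMeans(sweep(m, 2, colMeans(m))^2))
  out <- tibble::tibble(
    epoch = rep(seq_len(d[3]), each = d[2]),
    sample = rep(seq_len(d[2]), times = d[3]),
    time_s = rep((seq_len(d[2]) - 1) / ep$sfreq, times = d[3]),
    gfp = g
  )
  attr(out, "sfreq") <- ep$sfreq
  class(out) <- c("gfp_series", class(out))
  out
}

#' Extract topographies at GFP peaks
#'
#' A peak is a strict local maximum of the GFP curve within an epoch
#' (`gfp[t-1] < gfp[t] > gfp[t+1]`); epoch-boundary samples are never peaks,
#' and on a plateau of equal values the first sample counts as the peak.
#'
#' @param ep Average-referenced `eeg_epochs`.
#' @param gfp Optional precomputed [compute_gfp()] result for `ep`.
#' @return A `topography_set`: list with `maps` (channels x peaks matrix),
#'   `gfp` (peak GFP values), `channels`, and `index` (tibble of epoch/sample
#'   of each peak).
#' @export
extract_gfp_peaks <- function(ep, gfp = NULL) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (is.null(gfp)) gfp <- compute_gfp(ep)
  d <- dim(ep$data)
  peaks_ep <- lapply(seq_len(d[3]), function(e) {
    g <- gfp$gfp[gfp$epoch == e]
    local_peaks(g)
  })
  n_pk <- sum(lengths(peaks_ep))
  maps <- matrix(0, nrow = d[1], ncol = n_pk)
  gvals <- numeric(n_pk)
  idx <- vector("list", d[3])
  at <- 0L
  for (e in seq_len(d[3])) {
    pk <- peaks_ep[[e]]
    if (length(pk) == 0) next
    maps[, at + seq_along(pk)] <- ep$data[, pk, e]
    gvals[at + seq_along(pk)] <- gfp$gfp[gfp$epoch == e][pk]
    idx[[e]] <- tibble::tibble(epoch = e, sample = pk)
    at <- at + length(pk)
  }
  rownames(maps) <- ep$channels
  structure(
    list(
      maps = maps, gfp = gvals, channels = ep$channels,
      index = dplyr::bind_rows(idx)
    ),
    class = "topography_set"
  )
}

#' @export
print.topography_set <- function(x, ...) {
  cat(sprintf(
    "<topography_set> %d maps x %d channels\n", ncol(x$maps), nrow(x$maps)
  ))
  invisible(x)
}

# strict local maxima; plateaus count once at their first sample;
# boundary samples excluded
local_peaks <- function(g) {
  n <- length(g)
  if (n < 3) return(integer(0))
  # collapse plateaus: keep positions where value differs from predecessor
  keep <- c(TRUE, diff(g) != 0)
  pos <- which(keep)
  v <- g[pos]
  m <- length(v)
  if (m < 3) return(integer(0))
  core <- which(v[2:(m - 1)] > v[1:(m - 2)] & v[2:(m - 1)] > v[3:m]) + 1L
  out <- pos[core]
  out[out > 1 & out < n]
}

#' Cluster topographies with T-AAHC
#'
#' Bottom-up atomize-and-agglomerate clustering: every map starts as its own
#' cluster; at each step the cluster contributing least global explained
#' variance (GFP-squared-weighted squared polarity-invariant correlation to
#' its prototype) is dissolved and its members are reassigned to the
#' surviving cluster of highest absolute spatial correlation; a cluster's
#' prototype is the sign-aligned first principal component of its members.
#' Stops when `k` clusters remain.
#'
#' @param maps A `topography_set` (from [extract_gfp_peaks()]) or a channels x
#'   maps numeric matrix of zero-mean maps.
#' @param k Number of clusters to retain (default 4).
#' @param weights Optional per-map weights; defaults to squared map GFP.
#' @return An unlabeled `prototype_set` (unit-GFP prototypes, ordered by
#'   descending explained variance) with attributes `assignment` (cluster per
#'   input map), `fit` (per-map |correlation| to its prototype) and `gev`
#'   (per-cluster explained-variance share).
#' @export
taahc_cluster <- function(maps, k = 4, weights = NULL) {
  if (inherits(maps, "topography_set")) {
    m <- maps$maps
    channels <- maps$channels
    if (is.null(weights)) weights <- maps$gfp^2
  } else {
    m <- as.matrix(maps)
    channels <- rownames(m)
    if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(m)))
    if (is.null(weights)) weights <- apply(m, 2, map_gfp)^2
  }
  if (ncol(m) < k) {
    stop("need at least k = ", k, " maps, got ", ncol(m), call. = FALSE)
  }
  stopifnot(k >= 1, length(weights) == ncol(m))
  norm <- normalize_maps(m) # zero-mean columns
  norm <- sweep(norm, 2, sqrt(colSums(norm^2)), "/") # unit L2 for the core
  res <- .taahc_core(norm, as.numeric(weights), as.integer(k))
  protos <- normalize_maps(res$prototypes) # unit GFP
  out <- prototype_set(protos, channels, labels = NULL, source = "group")
  attr(out, "assignment") <- as.integer(res$assignment)
  attr(out, "fit") <- as.numeric(res$fit)
  attr(out, "gev") <- as.numeric(res$gev) / sum(weights)
  out
}

#' Label clustered prototypes against canonical templates
#'
#' Assigns class labels A-D by the one-to-one mapping that maximizes the sum
#' of absolute spatial correlations over all permutations (exhaustive over
#' the 4! = 24 assignments).
#'
#' @param p An unlabeled (or to-be-relabeled) `prototype_set` with as many
#'   maps as `canon`.
#' @param canon A labeled reference `prototype_set`, e.g. [canonical_maps()].
#' @return `p` with labels attached, plus attributes `label_mapping` (tibble
#'   of label, matched map index, |correlation|) and `label_total_corr`.
#' @export
label_prototypes <- function(p, canon) {
  stopifnot(inherits(p, "prototype_set"), inherits(canon, "prototype_set"))
  k <- ncol(p$maps)
  if (ncol(canon$maps) != k) {
    stop("prototype sets must have the same number of maps", call. = FALSE)
  }
  if (!identical(p$channels, canon$channels)) {
    stop("prototype sets are on different montages", call. = FALSE)
  }
  cc <- matrix(0, k, k) # [canon, p]
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      cc[i, j] <- spatial_correlation(canon$maps[, i], p$maps[, j])
    }
  }
  perms <- permutations(k)
  tot <- apply(perms, 1, function(pr) sum(cc[cbind(seq_len(k), pr)]))
  best <- perms[which.max(tot), ]
  labels <- canon$labels
  ord <- best # canon label i matched to p map best[i]
  maps <- p$maps[, ord, drop = FALSE]
  colnames(maps) <- labels
  out <- prototype_set(maps, p$channels, labels = labels, source = p$source)
  attr(out, "label_mapping") <- tibble::tibble(
    label = labels,
    map_index = ord,
    correlation = cc[cbind(seq_len(k), ord)]
  )
  attr(out, "label_total_corr") <- max(tot)
  # carry the relabeled assignment through if present
  asg <- attr(p, "assignment")
  if (!is.null(asg)) {
    attr(out, "assignment") <- labels[match(asg, ord)]
  }
  out
}

permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- permutations(k - 1)
  out <- matrix(0L, nrow = factorial(k), ncol = k)
  r <- 1L
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    for (j in seq_len(nrow(sub))) {
      out[r, ] <- c(i, rest[sub[j, ]])
      r <- r + 1L
    }
  }
  out
}

#' Back-fit prototypes to epoched EEG
#'
#' Assigns every sample to the prototype with maximal absolute spatial
#' correlation. Assignment is independent per sample (no temporal smoothing
#' by default); an optional minimum-duration post-pass reassigns segments
#' shorter than `min_duration_ms` to the neighboring label with the higher
#' fit. Zero-variance samples inherit the label of the nearest labeled
#' neighbor within the epoch and are counted in attribute
#' `n_zero_variance`.
#'
#' @param ep Average-referenced `eeg_epochs` (band-pass the microstate band,
#'   2-20 Hz, upstream).
#' @param p A labeled `prototype_set`.
#' @param min_duration_ms Minimum segment duration; 0 (default) disables the
#'   post-pass.
#' @return A tibble of class `label_sequence` with columns `epoch`, `sample`,
#'   `label`, `fit`; attributes `sfreq`, `labels`, `n_zero_variance`.
#' @export
backfit <- function(ep, p, min_duration_ms = 0) {
  stopifnot(inherits(ep, "eeg_epochs"), inherits(p, "prototype_set"))
  if (is.null(p$labels)) stop("prototypes must be labeled first", call. = FALSE)
  if (ep$reference != "average") {
    stop("back-fitting requires average-referenced epochs", call. = FALSE)
  }
  if (!identical(ep$channels, p$channels)) {
    stop("epochs and prototypes are on different montages", call. = FALSE)
  }
  d <- dim(ep$data)
  m <- matrix(ep$data, nrow = d[1])
  m <- sweep(m, 2, colMeans(m))
  nrm <- sqrt(colSums(m^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  m <- sweep(m, 2, nrm, "/")
  pm <- p$maps
  pm <- sweep(pm, 2, colMeans(pm))
  pm <- sweep(pm, 2, sqrt(colSums(pm^2)), "/")
  cc <- abs(crossprod(pm, m)) # k x (samples*epochs)
  lab_idx <- max.col(t(cc), ties.method = "first")
  fit <- cc[cbind(lab_idx, seq_along(lab_idx))]
  labels <- p$labels[lab_idx]
  fit[zero] <- NA_real_
  epoch_of <- rep(seq_len(d[3]), each = d[2])
  if (any(zero)) {
    labels <- fill_nearest(labels, zero, epoch_of)
  }
  out <- tibble::tibble(
    epoch = epoch_of,
    sample = rep(seq_len(d[2]), times = d[3]),
    label = labels,
    fit = fit
  )
  attr(out, "sfreq") <- ep$sfreq
  attr(out, "labels") <- p$labels
  attr(out, "n_zero_variance") <- sum(zero)
  class(out) <- c("label_sequence", class(out))
  if (min_duration_ms > 0) out <- enforce_min_duration(out, min_duration_ms)
  out
}

# assign zero-variance samples the label of the nearest labeled neighbor
# within the same epoch
fill_nearest <- function(labels, zero, epoch_of) {
  for (e in unique(epoch_of[zero])) {
    in_ep <- which(epoch_of == e)
    lab <- labels[in_ep]
    z <- zero[in_ep]
    good <- which(!z)
    if (length(good) == 0) next # fully degenerate epoch stays as-is
    for (i in which(z)) {
      lab[i] <- lab[good[which.min(abs(good - i))]]
    }
    labels[in_ep] <- lab
  }
  labels
}

enforce_min_duration <- function(seq, min_duration_ms) {
  sfreq <- attr(seq, "sfreq")
  min_len <- ceiling(min_duration_ms / 1000 * sfreq)
  for (e in unique(seq$epoch)) {
    idx <- which(seq$epoch == e)
    lab <- seq$label[idx]
    fit <- seq$fit[idx]
    repeat {
      r <- rle(lab)
      short <- which(r$lengths < min_len)
      if (length(short) == 0 || length(r$lengths) == 1) break
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      # reassign the shortest offending run to the better-fitting neighbor
      s <- short[which.min(r$lengths[short])]
      span <- starts[s]:ends[s]
      left <- if (s > 1) r$values[s - 1] else NA
      right <- if (s < length(r$values)) r$values[s + 1] else NA
      pick <- if (is.na(left)) right else if (is.na(right)) left else {
        lf <- mean(fit[span][!is.na(fit[span])], na.rm = TRUE)
        if (is.na(lf)) left else if (mean_run_fit(fit, starts, ends, s - 1) >=
          mean_run_fit(fit, starts, ends, s + 1)) left else right
      }
      lab[span] <- pick
    }
    seq$label[idx] <- lab
  }
  seq
}

mean_run_fit <- function(fit, starts, ends, i) {
  v <- fit[starts[i]:ends[i]]
  m <- mean(v, na.rm = TRUE)
  if (is.na(m)) -Inf else m
}

# segments (maximal runs of one label) per epoch with truncation flags
segment_table <- function(seq) {
  sfreq <- attr(seq, "sfreq")
  eps <- unique(seq$epoch)
  lab_l <- vector("list", length(eps))
  len_l <- vector("list", length(eps))
  ep_l <- vector("list", length(eps))
  trunc_l <- vector("list", length(eps))
  for (j in seq_along(eps)) {
    r <- rle(seq$label[seq$epoch == eps[j]])
    n <- length(r$lengths)
    lab_l[[j]] <- r$values
    len_l[[j]] <- r$lengths
    ep_l[[j]] <- rep(eps[j], n)
    trunc_l[[j]] <- seq_len(n) == 1L | seq_len(n) == n
  }
  lens <- unlist(len_l)
  tibble::tibble(
    epoch = unlist(ep_l),
    label = unlist(lab_l),
    n_samples = lens,
    duration_ms = lens / sfreq * 1000,
    truncated = unlist(trunc_l)
  )
}

#' Microstate temporal parameters
#'
#' Computes the three canonical parameters per class from a back-fitted label
#' sequence. Duration is the mean length of uninterrupted runs of a class;
#' occurrence is the number of onsets per second; coverage is the percentage
#' of total time spent in the class. Runs touching an epoch boundary are
#' truncated by segmentation, so they are excluded from the duration mean and
#' the occurrence count but still counted in coverage (which remains a true
#' time fraction).
#'
#' @param seq A `label_sequence` from [backfit()].
#' @return A tibble with one row per class: `class`, `duration_ms`
#'   (`NA` when a class has no complete run), `occurrence_per_s`,
#'   `coverage_pct`, `n_segments`.
#' @export
compute_parameters <- function(seq) {
  stopifnot(inherits(seq, "label_sequence"))
  labels <- attr(seq, "labels")
  sfreq <- attr(seq, "sfreq")
  total_s <- nrow(seq) / sfreq
  segs <- segment_table(seq)
  full <- segs[!segs$truncated, , drop = FALSE]
  f <- factor(full$label, levels = labels)
  n_seg <- as.integer(table(f))
  dur <- as.numeric(tapply(full$duration_ms, f, mean))
  cov <- as.integer(table(factor(seq$label, levels = labels)))
  tibble::tibble(
    class = labels,
    duration_ms = dur,
    occurrence_per_s = n_seg / total_s,
    coverage_pct = cov / nrow(seq) * 100,
    n_segments = n_seg
  )
}

#' Microstate syntax: transition probabilities
#'
#' Counts transitions between consecutive distinct labels (segment
#' boundaries) within epochs — never across epoch boundaries — and
#' row-normalizes the counts from each source class. The diagonal is zero by
#' construction; a source class with no outgoing transitions yields an
#' all-`NA` row (undefined, not zero).
#'
#' @param seq A `label_sequence`.
#' @return A k x k matrix of conditional transition probabilities with the
#'   raw counts in attribute `counts`.
#' @export
transition_probabilities <- function(seq) {
  stopifnot(inherits(seq, "label_sequence"))
  labels <- attr(seq, "labels")
  k <- length(labels)
  counts <- matrix(0, k, k, dimnames = list(from = labels, to = labels))
  for (e in unique(seq$epoch)) {
    lab <- seq$label[seq$epoch == e]
    r <- rle(lab)$values
    if (length(r) < 2) next
    from <- match(r[-length(r)], labels)
    to <- match(r[-1], labels)
    idx <- (to - 1L) * k + from
    tab <- tabulate(idx, nbins = k * k)
    counts <- counts + matrix(tab, k, k)
  }
  probs <- counts
  rs <- rowSums(counts)
  for (i in seq_len(k)) {
    probs[i, ] <- if (rs[i] > 0) counts[i, ] / rs[i] else NA_real_
  }
  attr(probs, "counts") <- counts
  probs
}

#' Full per-subject microstate report
#'
#' @param seq A `label_sequence`.
#' @return A `microstate_report`: list with `parameters` (tibble from
#'   [compute_parameters()]) and `transitions` (matrix from
#'   [transition_probabilities()]).
#' @export
microstate_report <- function(seq) {
  structure(
    list(
      parameters = compute_parameters(seq),
      transitions = transition_probabilities(seq)
    ),
    class = "microstate_report"
  )
}

#' @export
print.microstate_report <- function(x, ...) {
  cat("<microstate_report>\n")
  print(x$parameters)
  cat("transitions:\n")
  print(round(x$transitions, 3))
  invisible(x)
}

#' Tidy a microstate report
#'
#' @param x A `microstate_report`.
#' @param ... Unused.
#' @return Long tibble: parameters rows (`measure` in duration/occurrence/
#'   coverage) and transition rows (`measure = "transition"`, `class` =
#'   `"X->Y"`).
#' @export
tidy.microstate_report <- function(x, ...) {
  p <- x$parameters
  meas <- c("duration_ms", "occurrence_per_s", "coverage_pct")
  tr <- x$transitions
  labs <- rownames(tr)
  ij <- which(row(tr) != col(tr), arr.ind = TRUE)
  tibble::tibble(
    class = c(rep(p$class, times = length(meas)),
              paste0(labs[ij[, 1]], "->", labs[ij[, 2]])),
    measure = c(rep(meas, each = nrow(p)), rep("transition", nrow(ij))),
    value = c(p$duration_ms, p$occurrence_per_s, p$coverage_pct, tr[ij])
  )
}

#' Group-level microstate analysis
#'
#' Pools GFP-peak topographies across all subjects of a group, clusters them
#' once with T-AAHC, labels the group prototypes against canonical templates,
#' then back-fits the labeled group prototypes to every subject and reports
#' per-subject parameters and syntax.
#'
#' @param cohort A data frame with one row per subject, holding at least an
#'   `epochs` list-column of `eeg_epochs` and a `subject_id` column. Epochs
#'   are expected already band-passed to the microstate band and
#'   average-referenced.
#' @param canon Labeling reference; defaults to [canonical_maps()] on the
#'   standard montage.
#' @param k Number of clusters (default 4).
#' @param min_duration_ms Back-fit minimum-duration option (default 0).
#' @return A list: `prototypes` (labeled group `prototype_set`) and `reports`
#'   (the cohort tibble with list-columns `sequence`, `report` and an
#'   unnested parameter summary accessible via [cohort_outcomes()]).
#' @export
run_group_microstate <- function(cohort, canon = NULL, k = 4,
                                 min_duration_ms = 0) {
  stopifnot(is.data.frame(cohort), "epochs" %in% names(cohort))
  if (nrow(cohort) == 0) stop("empty group", call. = FALSE)
  peaks <- lapply(cohort$epochs, extract_gfp_peaks)
  maps <- do.call(cbind, lapply(peaks, function(p) p$maps))
  gfps <- unlist(lapply(peaks, function(p) p$gfp))
  channels <- peaks[[1]]$channels
  ts <- structure(
    list(maps = maps, gfp = gfps, channels = channels, index = NULL),
    class = "topography_set"
  )
  protos <- taahc_cluster(ts, k = k)
  if (is.null(canon)) canon <- canonical_maps(montage_1020())
  protos <- label_prototypes(protos, canon)
  seqs <- lapply(cohort$epochs, backfit, p = protos,
    min_duration_ms = min_duration_ms
  )
  reports <- lapply(seqs, microstate_report)
  cohort$sequence <- seqs
  cohort$report <- reports
  list(prototypes = protos, reports = cohort)
}

#' Flatten per-subject microstate reports into an outcome table
#'
#' @param reports The `reports` tibble returned by [run_group_microstate()]
#'   (must contain `subject_id` and a `report` list-column; `group` and `age`
#'   are carried through when present).
#' @return Long tibble: `subject_id`, (`group`, `age`,) `measure`, `class`,
#'   `value`.
#' @export
cohort_outcomes <- function(reports) {
  stopifnot(is.data.frame(reports), "report" %in% names(reports))
  keep <- intersect(c("subject_id", "group", "age"), names(reports))
  out <- lapply(seq_len(nrow(reports)), function(i) {
    td <- tidy.microstate_report(reports$report[[i]])
    for (col in rev(keep)) td[[col]] <- reports[[col]][[i]]
    td[, c(keep, "measure", "class", "value")]
  })
  dplyr::bind_rows(out)
}
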