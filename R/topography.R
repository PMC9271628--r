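# Scalp topography utilities: canonical template maps, GFP normalization,
# spatial correlation.

map_gfp <- function(v) {
  sqrt(mean((v - mean(v))^2))
}

# zero-mean, unit-GFP normalization of a map (columns of a matrix)
normalize_maps <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  g <- sqrt(colMeans(m^2))
  if (any(g <= 0)) stop("cannot normalize a zero-variance map", call. = FALSE)
  sweep(m, 2, g, "/")
}

# the four canonical dipolar axis fields on 2-D electrode positions:
# A right-frontal <-> left-occipital, B left-frontal <-> right-occipital,
# C prefrontal <-> occipital, D frontocentral focus vs occipital
canonical_fields <- function(x, y) {
  cbind(
    A = (x + y) / sqrt(2),
    B = (-x + y) / sqrt(2),
    C = y,
    D = exp(-(x^2 + (y - 0.2)^2) / (2 * 0.35^2)) -
      0.7 * exp(-(x^2 + (y + 0.95)^2) / (2 * 0.45^2))
  )
}

#' Prototype set container
#'
#' Bundles the four prototype topographies with their labels and provenance.
#'
#' @param maps Channels x classes numeric matrix of zero-mean maps.
#' @param channels Channel names.
#' @param labels Class labels (one per map column); `NULL` for an unlabeled
#'   set fresh out of clustering.
#' @param source One of `"canonical"`, `"synthetic"`, `"group_NC"`,
#'   `"group_LLS"`, `"group"`.
#' @return A `prototype_set` object.
#' @export
prototype_set <- function(maps, channels, labels = NULL,
                          source = c("group", "canonical", "synthetic",
                                     "group_NC", "group_LLS")) {
  maps <- as.matrix(maps)
  stopifnot(nrow(maps) == length(channels))
  source <- match.arg(source)
  if (!is.null(labels)) {
    stopifnot(length(labels) == ncol(maps), !anyDuplicated(labels))
    colnames(maps) <- labels
  }
  rownames(maps) <- channels
  structure(
    list(maps = maps, channels = as.character(channels), labels = labels,
         source = source),
    class = "prototype_set"
  )
}

#' @export
print.prototype_set <- function(x, ...) {
  lab <- if (is.null(x$labels)) "unlabeled" else paste(x$labels, collapse = ",")
  cat(sprintf(
    "<prototype_set> %d maps x %d channels (%s, source=%s)\n",
    ncol(x$maps), nrow(x$maps), lab, x$source
  ))
  invisible(x)
}

#' Canonical microstate template maps
#'
#' Deterministic template topographies for the four canonical microstate
#' classes, built from the montage's 2-D electrode positions: class A runs
#' right-frontal to left-occipital, class B left-frontal to right-occipital,
#' class C prefrontal to occipital, and class D sets a frontocentral focus
#' against the occiput. Used as the labeling reference for clustered
#' prototypes; replaceable by any user-supplied `prototype_set`.
#'
#' @param montage An `eeg_montage`.
#' @return A labeled `prototype_set` with `source = "canonical"`.
#' @export
canonical_maps <- function(montage) {
  generate_prototype_maps(montage, seed = NULL, jitter = 0, source = "canonical")
}

#' Generate four dipolar prototype maps
#'
#' Builds zero-mean, unit-GFP maps along the four canonical topographic axes,
#' optionally perturbed by a small seeded smooth random field so repeated
#' cohorts do not share bit-identical prototypes. Pairwise absolute spatial
#' correlation of the returned maps is checked to stay below 0.8.
#'
#' @param montage An `eeg_montage` with positions for all channels.
#' @param seed Integer seed for the perturbation; ignored when `jitter = 0`.
#' @param jitter Standard deviation of the smooth perturbation relative to
#'   map scale (default 0: exact canonical axes).
#' @param source Provenance tag stored on the returned set.
#' @return A labeled `prototype_set` (classes A-D).
#' @export
generate_prototype_maps <- function(montage, seed = NULL, jitter = 0,
                                    source = "synthetic") {
  validate_montage(montage)
  base <- canonical_fields(montage$x, montage$y)
  if (jitter > 0 && !is.null(seed)) {
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  basis <- scale(cbind(montage$x, montage$y, montage$x * montage$y,
    montage$x^2 - montage$y^2))
  # redraw the smooth perturbation (bounded) if it pushes a pair past the
  # collinearity limit; deterministic given the seed
  for (attempt in seq_len(20L)) {
    m <- base
    if (jitter > 0) {
      for (j in seq_len(ncol(m))) {
        m[, j] <- m[, j] / stats::sd(m[, j]) +
          jitter * as.vector(basis %*% stats::rnorm(ncol(basis)))
      }
    }
    m <- normalize_maps(m)
    cc <- abs(stats::cor(m))
    diag(cc) <- 0
    if (max(cc) < 0.8) break
    if (attempt == 20L || jitter == 0) {
      stop("generated prototype maps are too collinear (|corr| >= 0.8)",
        call. = FALSE
      )
    }
  }
  prototype_set(m, montage$channel, labels = c("A", "B", "C", "D"),
    source = source
  )
}

#' Spatial correlation between two topographies
#'
#' Pearson correlation across channels of the two zero-meaned maps. With
#' `polarity_invariant = TRUE` (the microstate convention; a map and its
#' polarity flip describe the same field configuration) the absolute value is
#' returned.
#'
#' @param a,b Numeric vectors over the same channel set, in the same order.
#' @param polarity_invariant Return `|r|` instead of `r` (default `TRUE`).
#' @return A single correlation value.
#' @export
spatial_correlation <- function(a, b, polarity_invariant = TRUE) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  stopifnot(length(a) == length(b))
  a <- a - mean(a)
  b <- b - mean(b)
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("spatial correlation undefined for a zero-variance map", call. = FALSE)
  }
  r <- sum(a * b) / (na * nb)
  if (polarity_invariant) abs(r) else r
}
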