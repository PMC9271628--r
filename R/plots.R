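# ggplot2 display methods for topographies, microstate reports and omega
# results.

#' Plot a scalp topography
#'
#' Inverse-distance-weighted interpolation of the map onto a grid inside the
#' head circle, drawn with `geom_raster` plus electrode positions.
#'
#' @param values Named numeric vector (names = channels) or plain vector in
#'   montage order.
#' @param montage An `eeg_montage`.
#' @param grid_n Interpolation grid resolution per axis.
#' @return A ggplot object.
#' @export
plot_topography <- function(values, montage = montage_1020(), grid_n = 60) {
  validate_montage(montage)
  v <- if (!is.null(names(values))) values[montage$channel] else values
  stopifnot(length(v) == nrow(montage))
  gx <- seq(-1.1, 1.1, length.out = grid_n)
  grid <- expand.grid(x = gx, y = gx)
  grid <- grid[grid$x^2 + grid$y^2 <= 1.1^2, ]
  interp <- vapply(seq_len(nrow(grid)), function(i) {
    d2 <- (montage$x - grid$x[i])^2 + (montage$y - grid$y[i])^2
    if (any(d2 < 1e-12)) return(v[which.min(d2)])
    w <- 1 / d2^1.5
    sum(w * v) / sum(w)
  }, 0)
  grid$value <- interp
  circ <- data.frame(
    x = cos(seq(0, 2 * pi, length.out = 200)),
    y = sin(seq(0, 2 * pi, length.out = 200))
  )
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_path(data = circ, linewidth = 0.3) +
    ggplot2::geom_point(
      data = montage, ggplot2::aes(x = .data$x, y = .data$y),
      size = 0.8
    ) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = NULL)
}

#' Plot the four prototype maps of a set
#'
#' @param object A `prototype_set`.
#' @param montage Montage for electrode positions.
#' @param ... Unused.
#' @return A patchwork-free single ggplot using facets.
#' @export
autoplot.prototype_set <- function(object, montage = montage_1020(), ...) {
  labs <- object$labels %||% paste0("cluster ", seq_len(ncol(object$maps)))
  gx <- seq(-1.1, 1.1, length.out = 50)
  base <- expand.grid(x = gx, y = gx)
  base <- base[base$x^2 + base$y^2 <= 1.1^2, ]
  all_grid <- dplyr::bind_rows(lapply(seq_along(labs), function(j) {
    v <- object$maps[, j]
    val <- vapply(seq_len(nrow(base)), function(i) {
      d2 <- (montage$x - base$x[i])^2 + (montage$y - base$y[i])^2
      if (any(d2 < 1e-12)) return(v[which.min(d2)])
      w <- 1 / d2^1.5
      sum(w * v) / sum(w)
    }, 0)
    data.frame(base, value = val, class = labs[j])
  }))
  ggplot2::ggplot(all_grid, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::facet_wrap(~class, nrow = 1) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = NULL)
}

#' Plot microstate parameters
#'
#' @param object A `microstate_report`.
#' @param ... Unused.
#' @return A ggplot of duration/occurrence/coverage per class.
#' @export
autoplot.microstate_report <- function(object, ...) {
  td <- tidy.microstate_report(object)
  td <- td[td$measure != "transition", ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$class, y = .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "microstate class", y = NULL)
}

#' Plot omega complexity per region
#'
#' @param object An `omega_result` (one subject) or the tibble from
#'   [cohort_omega()] with a `group` column.
#' @param ... Unused.
#' @return A ggplot of omega by region (and group when present).
#' @export
autoplot.omega_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    dplyr::all_of(c("omega_global", "omega_anterior", "omega_posterior")),
    names_to = "region", values_to = "omega"
  )
  long$region <- factor(sub("^omega_", "", long$region),
    levels = c("global", "anterior", "posterior")
  )
  if ("group" %in% names(long)) {
    ggplot2::ggplot(long, ggplot2::aes(
      x = .data$region, y = .data$omega,
      fill = .data$group
    )) +
      ggplot2::geom_boxplot() +
      ggplot2::theme_minimal() +
      ggplot2::labs(x = NULL, y = "omega complexity")
  } else {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$region, y = .data$omega)) +
      ggplot2::geom_col(fill = "grey35") +
      ggplot2::theme_minimal() +
      ggplot2::labs(x = NULL, y = "omega complexity")
  }
}
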