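#' Standard 19-channel 10-20 montage
#'
#' Builds the 19-electrode international 10-20 montage used throughout the
#' package, with approximate 2-D scalp-projection coordinates (unit head
#' radius, +x toward the right ear, +y toward the nasion) and the
#' anterior/posterior electrode subsets used for regional spatial-complexity
#' analysis.
#'
#' @return A tibble of class `eeg_montage` with columns `channel`, `x`, `y`
#'   and `region` (`"anterior"`, `"posterior"` or `"central"`).
#' @examples
#' montage_1020()
#' @export
montage_1020 <- function() {
  pos <- tibble::tribble(
    ~channel,      ~x,     ~y,
    "FP1",      -0.31,   0.95,
    "FP2",       0.31,   0.95,
    "F3",       -0.45,   0.55,
    "F4",        0.45,   0.55,
    "Fz",        0.00,   0.50,
    "F7",       -0.81,   0.59,
    "F8",        0.81,   0.59,
    "C3",       -0.50,   0.00,
    "C4",        0.50,   0.00,
    "Cz",        0.00,   0.00,
    "P3",       -0.45,  -0.55,
    "P4",        0.45,  -0.55,
    "Pz",        0.00,  -0.50,
    "O1",       -0.31,  -0.95,
    "O2",        0.31,  -0.95,
    "T3",       -1.00,   0.00,
    "T4",        1.00,   0.00,
    "T5",       -0.81,  -0.59,
    "T6",        0.81,  -0.59
  )
  anterior <- c("FP1", "FP2", "F3", "F4", "Fz", "F7", "F8")
  posterior <- c("O1", "O2", "P3", "P4", "Pz", "T5", "T6")
  pos$region <- ifelse(pos$channel %in% anterior, "anterior",
    ifelse(pos$channel %in% posterior, "posterior", "central")
  )
  structure(pos, class = c("eeg_montage", class(pos)))
}

#' Electrode subsets of a montage
#'
#' @param montage An `eeg_montage` tibble (see [montage_1020()]).
#' @return Character vector of channel names.
#' @export
anterior_channels <- function(montage) {
  montage$channel[montage$region == "anterior"]
}

#' @rdname anterior_channels
#' @export
posterior_channels <- function(montage) {
  montage$channel[montage$region == "posterior"]
}

validate_montage <- function(montage) {
  stopifnot(is.data.frame(montage), all(c("channel", "x", "y") %in% names(montage)))
  if (anyDuplicated(montage$channel) > 0) {
    stop("montage channel names must be unique", call. = FALSE)
  }
  if (any(!is.finite(montage$x)) || any(!is.finite(montage$y))) {
    bad <- montage$channel[!is.finite(montage$x) | !is.finite(montage$y)]
    stop("montage is missing positions for: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(montage)
}
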