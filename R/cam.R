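#' ERB_N-number (Cam) scale transforms
#'
#' The auditory periphery is modelled on a perceptual frequency axis, the
#' ERB_N-number scale, with units Cams. One Cam corresponds to one
#' equivalent rectangular bandwidth (ERB_N) of the normal auditory filter,
#' and the scale is approximately proportional to distance along the
#' basilar membrane. `cam_from_frequency()` maps frequency in Hz to Cams
#' using the standard formula `21.4 * log10(0.00437 * f + 1)`;
#' `frequency_from_cam()` is its exact inverse.
#'
#' @param f frequency in Hz (vectorised, must be `>= 0`).
#' @param cam ERB_N-number in Cams (vectorised, must be `>= 0`).
#' @return `cam_from_frequency()` returns Cams; `frequency_from_cam()`
#'   returns Hz.
#' @examples
#' cam_from_frequency(1000)              # about 15.62 Cams
#' cam_from_frequency(400) - cam_from_frequency(200)   # an octave ~ 3.6 Cams
#' frequency_from_cam(cam_from_frequency(250))
#' @export
cam_from_frequency <- function(f) {
  if (any(!is.finite(f)) || any(f < 0)) {
    stop("frequencies must be finite and non-negative")
  }
  21.4 * log10(0.00437 * f + 1)
}

#' @rdname cam_from_frequency
#' @export
frequency_from_cam <- function(cam) {
  if (any(!is.finite(cam)) || any(cam < 0)) {
    stop("Cam values must be finite and non-negative")
  }
  (10^(cam / 21.4) - 1) / 0.00437
}

#' Equivalent rectangular bandwidth of the normal auditory filter
#'
#' @param f centre frequency in Hz.
#' @return ERB_N in Hz: `24.7 * (0.00437 * f + 1)`.
#' @export
erb_bandwidth <- function(f) {
  if (any(!is.finite(f)) || any(f < 0)) {
    stop("frequencies must be finite and non-negative")
  }
  24.7 * (0.00437 * f + 1)
}
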