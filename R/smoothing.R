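#' Attack/release smoother configuration
#'
#' Coefficients of the two cascaded asymmetric one-pole smoothers of the
#' TVL model, per 1-ms step: the short-term stage tracks word-level
#' loudness, the long-term stage sentence-level loudness. Attack (input
#' above state) must be faster than release.
#'
#' @param attack_short,release_short short-term stage coefficients.
#' @param attack_long,release_long long-term stage coefficients.
#' @return an object of class `smoother_config`.
#' @export
smoother_config <- function(attack_short = 0.045, release_short = 0.02,
                            attack_long = 0.01, release_long = 0.0005) {
  cfg <- list(attack_short = attack_short, release_short = release_short,
              attack_long = attack_long, release_long = release_long)
  vals <- unlist(cfg)
  if (any(vals <= 0 | vals >= 1)) stop("coefficients must lie in (0, 1)")
  if (attack_short <= release_short || attack_long <= release_long) {
    stop("attack coefficient must exceed release coefficient for each stage")
  }
  structure(cfg, class = "smoother_config")
}

#' Temporal smoothing of an instantaneous loudness series
#'
#' Applies the TVL model's two cascaded asymmetric one-pole smoothers to a
#' 1-ms instantaneous loudness series. Smoothing operates in the sone
#' domain (the linear loudness scale); the result is converted back to
#' phons, clipped at 0 for reporting.
#'
#' @param instantaneous numeric vector of instantaneous loudness levels in
#'   phons at 1-ms spacing (non-empty).
#' @param teacher a [tvl_teacher()] providing the phon/sone mapping.
#' @param cfg a [smoother_config()].
#' @param times optional vector of frame times in seconds (defaults to
#'   0, 0.001, ...).
#' @return a `loudness_trace`: a data frame with columns `time_s`,
#'   `instantaneous_phon`, `short_term_phon`, `long_term_phon`.
#' @export
smooth_trace <- function(instantaneous, teacher,
                         cfg = smoother_config(), times = NULL) {
  if (length(instantaneous) == 0) stop("empty loudness series")
  stopifnot(inherits(teacher, "tvl_teacher"), inherits(cfg, "smoother_config"))
  if (is.null(times)) times <- (seq_along(instantaneous) - 1) * 1e-3
  sones <- phon_to_sone(instantaneous, teacher)
  st <- .ar_smooth_cpp(sones, cfg$attack_short, cfg$release_short)
  lt <- .ar_smooth_cpp(st, cfg$attack_long, cfg$release_long)
  out <- data.frame(
    time_s = times,
    instantaneous_phon = pmax(instantaneous, 0),
    short_term_phon = sone_to_phon(st, teacher),
    long_term_phon = sone_to_phon(lt, teacher)
  )
  class(out) <- c("loudness_trace", "data.frame")
  out
}

#' Overall loudness of a trace
#'
#' The maximum of the long-term loudness series, the model's single-number
#' summary of how loud a whole sound is.
#'
#' @param trace a `loudness_trace` from [smooth_trace()].
#' @return overall loudness level in phons.
#' @export
overall_loudness <- function(trace) {
  stopifnot(inherits(trace, "loudness_trace"), nrow(trace) >= 1)
  max(trace$long_term_phon)
}

#' Write a loudness trace as CSV
#'
#' Columns: `time_s, instantaneous_phon, short_term_phon, long_term_phon`.
#' A comment line records the configuration hash when one is supplied.
#'
#' @param trace a `loudness_trace`.
#' @param path output path.
#' @param hash optional configuration hash to embed.
#' @export
write_trace_csv <- function(trace, path, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(sprintf("# config_hash: %s", hash), con)
  write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}
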