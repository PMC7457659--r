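#' Calibrated mono audio signal
#'
#' Container for a calibrated digital waveform. The calibration states the
#' sound pressure level (dB SPL) produced by a signal with unit RMS
#' amplitude, so `SPL = calibration + 20*log10(rms)`. The toolkit operates
#' exclusively at 16 kHz mono; other rates are rejected rather than
#' resampled.
#'
#' @param samples numeric vector of waveform amplitudes (finite).
#' @param sample_rate sampling rate in Hz; must be 16000.
#' @param calibration dB SPL of a unit-RMS signal (default 94, the standard
#'   microphone reference).
#' @return an object of class `audio_signal`.
#' @export
audio_signal <- function(samples, sample_rate = 16000, calibration = 94) {
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    stop("samples must be a finite numeric vector")
  }
  if (length(sample_rate) != 1 || sample_rate != 16000) {
    stop("sample_rate must be 16000 Hz (resampling is out of scope)")
  }
  if (length(calibration) != 1 || !is.finite(calibration)) {
    stop("calibration must be a single finite dB SPL value")
  }
  structure(
    list(samples = as.numeric(samples), sample_rate = 16000,
         calibration = calibration),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("audio_signal: %d samples (%.3f s) at %d Hz, %.1f dB SPL RMS\n",
              length(x$samples), length(x$samples) / x$sample_rate,
              x$sample_rate, rms_level(x)))
  invisible(x)
}

#' Measured RMS level of a signal in dB SPL
#'
#' @param signal an [audio_signal()].
#' @return RMS level in dB SPL under the signal's calibration.
#' @export
rms_level <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  r <- sqrt(mean(signal$samples^2))
  if (r <= 0) return(-Inf)
  signal$calibration + 20 * log10(r)
}

#' Scale a signal to a target RMS level
#'
#' Applies the scalar gain that brings the measured RMS level to `target`
#' dB SPL under the signal's calibration. Idempotent: re-scaling to the same
#' target is a no-op.
#'
#' @param signal an [audio_signal()] with non-zero RMS.
#' @param target target RMS level in dB SPL.
#' @return the scaled [audio_signal()].
#' @export
scale_to_rms_level <- function(signal, target) {
  stopifnot(inherits(signal, "audio_signal"))
  r <- sqrt(mean(signal$samples^2))
  if (r <= 0) stop("cannot scale an all-zero signal to a target level")
  gain <- 10^((target - (signal$calibration + 20 * log10(r))) / 20)
  audio_signal(signal$samples * gain, signal$sample_rate, signal$calibration)
}

#' Design the 61-band DFT bin grouping
#'
#' Groups the bins of an N-point DFT into the banded spectral representation
#' used throughout the toolkit: one bin per band while band centres stay at
#' or below 0.2 kHz, then a ladder of 1/9th-octave bands (successive edges
#' in the ratio `2^(1/9)`) up to `f_max`. The ladder is anchored at the DFT
#' bin edge nearest below 200 Hz so that the boundary bin falls in the first
#' ninth-octave band and the canonical configuration (1024-point DFT at
#' 16 kHz, `f_max` 8 kHz) yields exactly 61 bands. The DC bin is excluded;
#' the last band is truncated at `f_max`.
#'
#' @param dft_size DFT length in samples (even; canonical 1024).
#' @param sample_rate sampling rate in Hz (canonical 16000).
#' @param f_max highest analysed frequency in Hz (canonical 8000; must not
#'   exceed the Nyquist frequency).
#' @return an object of class `band_definition`: a list with `dft_size`,
#'   `sample_rate`, `f_max`, and a data frame `bands` with columns
#'   `bin_lo`, `bin_hi` (inclusive DFT bin indices, bin 1 = `fs/N` Hz),
#'   `edge_lo`, `edge_hi`, and `center_hz`.
#' @examples
#' bands <- design_bands(1024, 16000, 8000)
#' nrow(bands$bands)  # 61
#' @export
design_bands <- function(dft_size, sample_rate, f_max) {
  if (dft_size %% 2 != 0 || dft_size < 4) stop("dft_size must be even")
  if (f_max > sample_rate / 2) stop("f_max exceeds the Nyquist frequency")
  df <- sample_rate / dft_size
  n_bins <- floor(f_max / df)            # usable bins 1..n_bins (DC excluded)
  if (n_bins < 2) stop("f_max too low for this DFT resolution")

  # one-bin bands: bin centres at or below 200 Hz
  narrow <- which((1:n_bins) * df <= 200)
  # ninth-octave ladder anchored at the upper edge of the last one-bin band
  anchor <- (max(narrow) + 0.5) * df
  ratio <- 2^(1 / 9)
  edges <- anchor * ratio^(0:ceiling(log(f_max / anchor, ratio)))
  lo <- edges[edges < f_max]
  hi <- pmin(lo * ratio, f_max)

  bin_freq <- (1:n_bins) * df
  rows <- lapply(seq_along(lo), function(k) {
    idx <- which(bin_freq >= lo[k] & bin_freq < hi[k] |
                   (k == length(lo) & bin_freq == f_max))
    if (length(idx) == 0) return(NULL)
    data.frame(bin_lo = min(idx), bin_hi = max(idx),
               edge_lo = lo[k], edge_hi = hi[k],
               center_hz = sqrt(lo[k] * hi[k]))
  })
  wide <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  narrow_df <- data.frame(
    bin_lo = narrow, bin_hi = narrow,
    edge_lo = (narrow - 0.5) * df, edge_hi = (narrow + 0.5) * df,
    center_hz = narrow * df
  )
  bands <- rbind(narrow_df, wide)
  rownames(bands) <- NULL

  # invariants: contiguous non-overlapping coverage, increasing centres
  stopifnot(all(bands$bin_lo[-1] == bands$bin_hi[-nrow(bands)] + 1),
            bands$bin_lo[1] == 1, bands$bin_hi[nrow(bands)] == n_bins,
            all(diff(bands$center_hz) > 0),
            max(bands$center_hz) <= f_max)

  structure(list(dft_size = dft_size, sample_rate = sample_rate,
                 f_max = f_max, bands = bands),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf(
    "band_definition: %d bands over %d DFT bins (%g Hz resolution), up to %g Hz\n",
    nrow(x$bands), x$bands$bin_hi[nrow(x$bands)],
    x$sample_rate / x$dft_size, x$f_max))
  invisible(x)
}

# periodic Hann window
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' Slice a signal into windowed analysis frames
#'
#' Frames of `window_len` samples are taken every `hop` samples and
#' multiplied by a periodic Hann window. The canonical hops are 560 samples
#' (35 ms, corpus generation) and 16 samples (1 ms, loudness traces).
#'
#' @param signal an [audio_signal()] at least `window_len` samples long.
#' @param window_len frame length in samples (canonical 1024).
#' @param hop frame advance in samples.
#' @return a `window_len` x `n_frames` matrix of windowed frames, with the
#'   frame-centre times (seconds) in attribute `frame_time`.
#' @export
frame_signal <- function(signal, window_len = 1024, hop = 560) {
  stopifnot(inherits(signal, "audio_signal"))
  n <- length(signal$samples)
  if (n < window_len) stop("signal shorter than one analysis window")
  if (hop < 1) stop("hop must be at least 1 sample")
  n_frames <- floor((n - window_len) / hop) + 1
  starts <- (seq_len(n_frames) - 1) * hop
  w <- hann_window(window_len)
  idx <- outer(seq_len(window_len), starts, `+`)
  frames <- matrix(signal$samples[idx], nrow = window_len) * w
  attr(frames, "frame_time") <- (starts + window_len / 2) / signal$sample_rate
  frames
}

#' Banded dB spectrum of windowed frames
#'
#' Computes the one-sided power spectrum of each windowed frame, groups bin
#' powers into the bands of a [design_bands()] definition, and expresses the
#' result in dB SPL. Normalisation is energy-preserving (window-corrected
#' Parseval), so the power sum over all bands matches the frame's RMS level
#' for broadband signals and an on-bin sinusoid's banded level matches its
#' calibrated SPL. Levels are floored at `floor_db` (default -30 dB SPL).
#'
#' @param frames matrix from [frame_signal()] (or a single frame vector).
#' @param bands a [design_bands()] definition matching the frame length.
#' @param calibration dB SPL of a unit-RMS waveform.
#' @param floor_db silence floor in dB SPL per band.
#' @return a 61 x `n_frames` matrix of band levels in dB SPL, with
#'   `frame_time` carried through as an attribute when present.
#' @export
band_spectrum <- function(frames, bands, calibration = 94, floor_db = -30) {
  stopifnot(inherits(bands, "band_definition"))
  if (is.null(dim(frames))) frames <- matrix(frames, ncol = 1)
  if (nrow(frames) != bands$dft_size) {
    stop("frame length does not match the band definition's DFT size")
  }
  n <- bands$dft_size
  w2 <- sum(hann_window(n)^2)
  spec <- stats::mvfft(frames)
  n_bins <- bands$bands$bin_hi[nrow(bands$bands)]
  # one-sided bin powers normalised so their sum estimates mean(x^2)
  p <- (Mod(spec[2:(n_bins + 1), , drop = FALSE])^2) * (2 / (n * w2))
  if (n_bins == n / 2) p[n_bins, ] <- p[n_bins, ] / 2  # Nyquist bin not doubled
  bd <- bands$bands
  group <- rep.int(seq_len(nrow(bd)), bd$bin_hi - bd$bin_lo + 1)
  band_pow <- rowsum(p, group = group, reorder = TRUE)
  levels <- 10 * log10(pmax(band_pow, 1e-300)) + calibration
  levels <- pmax(levels, floor_db)
  dimnames(levels) <- NULL
  attr(levels, "frame_time") <- attr(frames, "frame_time")
  attr(levels, "floor_db") <- floor_db
  levels
}

#' Export a band-spectrum sequence as CSV
#'
#' Writes columns `frame_time_s, band_01..band_61`.
#'
#' @param levels matrix from [band_spectrum()] (bands x frames).
#' @param path output file path.
#' @export
write_band_spectrum_csv <- function(levels, path) {
  times <- attr(levels, "frame_time")
  if (is.null(times)) times <- seq_len(ncol(levels)) - 1
  df <- data.frame(frame_time_s = times, t(levels))
  names(df)[-1] <- sprintf("band_%02d", seq_len(nrow(levels)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
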