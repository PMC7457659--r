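#' Load the outer/middle-ear transfer tables
#'
#' The free-field-to-eardrum transfer (frontal incidence) and the middle-ear
#' transfer are shipped as a plain-text table with the package and
#' interpolated linearly on a log-frequency axis.
#'
#' @return a data frame with columns `frequency_hz`, `outer_db`, `middle_db`.
#' @export
ear_transfer_tables <- function() {
  if (is.null(.tvlnet_cache$ear)) {
    path <- system.file("extdata", "ear_transfer.csv", package = "tvlnet")
    .tvlnet_cache$ear <- read.csv(path)
  }
  .tvlnet_cache$ear
}

# interpolate combined outer+middle ear gain (dB) at given frequencies
ear_gain_db <- function(f) {
  tab <- ear_transfer_tables()
  if (any(f < min(tab$frequency_hz) | f > max(tab$frequency_hz))) {
    stop("frequency outside the ear-transfer table range")
  }
  outer <- approx(log(tab$frequency_hz), tab$outer_db, xout = log(f))$y
  middle <- approx(log(tab$frequency_hz), tab$middle_db, xout = log(f))$y
  outer + middle
}

#' Construct the TVL teacher model
#'
#' Builds the reference loudness model that labels training data and serves
#' as the accuracy yardstick for the distilled network. The teacher consumes
#' the same 61-band dB spectra as the student; each band is treated as a
#' sinusoidal component at the band centre. Construction precomputes the
#' auditory-channel layout (150 channels at Cams 1.75 to 39 in 0.25 steps),
#' the per-channel roex filter and specific-loudness coefficients, the ear
#' transfer gains at the band centres, and the sone-to-phon calibration
#' obtained by running the model on 1-kHz pure tones from 0 to 110 dB SPL in
#' 0.25-dB steps and inverting the resulting loudness curve. By construction
#' a 1-kHz tone at L dB SPL is assigned a loudness level of L phons.
#'
#' @param bands a [design_bands()] definition (canonical 61-band layout).
#' @param calibration dB SPL of a unit-RMS waveform.
#' @param floor_db per-band silence floor in dB SPL.
#' @return an object of class `tvl_teacher`.
#' @export
tvl_teacher <- function(bands = design_bands(1024, 16000, 8000),
                        calibration = 94, floor_db = -30) {
  stopifnot(inherits(bands, "band_definition"))
  centers <- bands$bands$center_hz

  cams <- seq(1.75, 39, by = 0.25)
  fc <- frequency_from_cam(cams)
  p51 <- 4 * fc / erb_bandwidth(fc)
  p51_1k <- 4 * 1000 / erb_bandwidth(1000)

  thr <- read.csv(system.file("extdata", "threshold_excitation.csv",
                              package = "tvlnet"))
  ethrq_db <- approx(log(thr$frequency_hz), thr$ethrq_db, xout = log(fc),
                     rule = 2)$y
  g_db <- pmin(0, pmax(-25, 2.31 - ethrq_db))
  coef <- read.csv(system.file("extdata", "specific_loudness_coefficients.csv",
                               package = "tvlnet"))
  alpha <- approx(coef$g_db, coef$alpha, xout = g_db)$y
  a_coef <- approx(coef$g_db, coef$a, xout = g_db)$y

  teacher <- structure(list(
    bands = bands,
    calibration = calibration,
    floor_db = floor_db,
    ear_gain = ear_gain_db(centers),
    channels = list(cam = cams, fc = fc, p51 = p51, p51_1k = p51_1k,
                    ethrq = 10^(ethrq_db / 10),
                    g = 10^(pmin(0, 2.31 - ethrq_db) / 10),
                    alpha = alpha, a = a_coef),
    c_const = 0.046871,
    sone_phon = NULL
  ), class = "tvl_teacher")

  teacher$sone_phon <- calibrate_sone_to_phon(teacher)
  teacher
}

#' @export
print.tvl_teacher <- function(x, ...) {
  cat(sprintf(paste0(
    "tvl_teacher: %d input bands -> %d auditory channels ",
    "(Cam %.2f..%.2f), calibrated 0..110 phons at 1 kHz\n"),
    nrow(x$bands$bands), length(x$channels$cam),
    min(x$channels$cam), max(x$channels$cam)))
  invisible(x)
}

#' Outer- and middle-ear filtering of a band spectrum
#'
#' Shifts each band level by the combined free-field-to-eardrum and
#' middle-ear gain interpolated at the band centre. Bands at the silence
#' floor stay at the floor.
#'
#' @param spectrum 61 x n matrix (or vector) of band levels in dB SPL.
#' @param teacher a [tvl_teacher()].
#' @return matrix of effective levels at the cochlea, same shape.
#' @export
ear_filter <- function(spectrum, teacher) {
  stopifnot(inherits(teacher, "tvl_teacher"))
  if (is.null(dim(spectrum))) spectrum <- matrix(spectrum, ncol = 1)
  if (nrow(spectrum) != length(teacher$ear_gain)) {
    stop("spectrum rows do not match the teacher's band definition")
  }
  fl <- teacher$floor_db
  out <- pmax(spectrum + teacher$ear_gain, fl)
  out[spectrum <= fl] <- fl
  out
}

#' Excitation pattern from an effective spectrum
#'
#' Power-sums the contribution of every spectral component through the
#' level-dependent rounded-exponential auditory filter centred on each of
#' the 150 channels (Cams 1.75 to 39, 0.25-Cam spacing). The lower filter
#' skirt broadens with component level; the upper skirt is fixed.
#'
#' @param effective_spectrum 61 x n matrix (or vector) of post-ear-filter
#'   levels in dB.
#' @param teacher a [tvl_teacher()].
#' @return 150 x n matrix of excitation levels in dB.
#' @export
excitation_pattern <- function(effective_spectrum, teacher) {
  stopifnot(inherits(teacher, "tvl_teacher"))
  if (is.null(dim(effective_spectrum))) {
    effective_spectrum <- matrix(effective_spectrum, ncol = 1)
  }
  if (nrow(effective_spectrum) != nrow(teacher$bands$bands)) {
    stop("spectrum rows do not match the teacher's band definition")
  }
  ch <- teacher$channels
  .excitation_matrix_cpp(effective_spectrum, teacher$bands$bands$center_hz,
                         ch$fc, ch$p51, ch$p51_1k, teacher$floor_db)
}

#' Specific loudness from an excitation pattern
#'
#' Channel-wise compressive transform of excitation into loudness density
#' (sones per Cam). Three regimes: a threshold-weighted low-level branch for
#' excitation at or below the channel threshold, the mid-level compressive
#' power law, and a square-root branch above 100 dB of excitation.
#'
#' @param e 150 x n matrix (or vector) of excitation levels in dB.
#' @param teacher a [tvl_teacher()].
#' @return matrix of specific loudness (sones/Cam), same shape, all `>= 0`.
#' @export
specific_loudness <- function(e, teacher) {
  stopifnot(inherits(teacher, "tvl_teacher"))
  if (is.null(dim(e))) e <- matrix(e, ncol = 1)
  ch <- teacher$channels
  if (nrow(e) != length(ch$fc)) stop("excitation rows must match channels")
  E <- 10^(e / 10)
  G <- ch$g; A <- ch$a; al <- ch$alpha; Et <- ch$ethrq; C <- teacher$c_const
  core <- C * ((G * E + A)^al - A^al)
  low <- E <= Et
  if (any(low)) {
    wt <- (2 * E / (E + Et))^1.5
    core[low] <- (wt * core)[low]
  }
  high <- E > 1e10
  if (any(high)) core[high] <- (C * (E / 1.04e6)^0.5)[high]
  pmax(core, 0)
}

#' Instantaneous loudness from a specific-loudness pattern
#'
#' Integrates loudness density over the Cam axis (rectangle rule, 0.25-Cam
#' steps) to give loudness in sones, then converts to loudness level in
#' phons through the teacher's 1-kHz calibration.
#'
#' @param n 150 x n matrix (or vector) of specific loudness (sones/Cam).
#' @param teacher a [tvl_teacher()].
#' @return a list with numeric vectors `sones` and `phons` (one per frame).
#' @export
instantaneous_loudness <- function(n, teacher) {
  stopifnot(inherits(teacher, "tvl_teacher"))
  if (is.null(dim(n))) n <- matrix(n, ncol = 1)
  sones <- 0.25 * colSums(n)
  list(sones = sones, phons = sone_to_phon(sones, teacher))
}

# full chain: band spectra -> sones (no phon conversion)
teacher_sones <- function(spectra, teacher) {
  eff <- ear_filter(spectra, teacher)
  e <- excitation_pattern(eff, teacher)
  0.25 * colSums(specific_loudness(e, teacher))
}

#' Teacher loudness level for band spectra
#'
#' Runs the full reference pipeline (ear filtering, excitation, specific
#' loudness, summation, phon conversion) on a sequence of band spectra.
#'
#' @param teacher a [tvl_teacher()].
#' @param spectra 61 x n matrix (or vector) of band levels in dB SPL.
#' @return numeric vector of instantaneous loudness levels in phons.
#' @export
teacher_phons <- function(teacher, spectra) {
  sone_to_phon(teacher_sones(spectra, teacher), teacher)
}

#' Build the sone-to-phon calibration of a teacher
#'
#' Runs the model end to end on 1-kHz pure tones from 0 to 110 dB SPL in
#' 0.25-dB steps (through the spectral front-end, so windowing leakage is
#' part of the calibration) and inverts the strictly monotone sone-versus-
#' level curve. A non-monotone curve signals a model defect and raises an
#' error.
#'
#' @param teacher a [tvl_teacher()] (the `sone_phon` slot may still be
#'   empty).
#' @return a list with `sones` and `phons` grids defining the mapping.
#' @export
calibrate_sone_to_phon <- function(teacher) {
  bands <- teacher$bands
  n <- bands$dft_size
  t_axis <- (0:(n - 1)) / bands$sample_rate
  ref_level <- 60
  amp <- sqrt(2) * 10^((ref_level - teacher$calibration) / 20)
  frame <- amp * sin(2 * pi * 1000 * t_axis) * hann_window(n)
  base <- band_spectrum(frame, bands, calibration = teacher$calibration,
                        floor_db = teacher$floor_db)[, 1]
  levels <- seq(0, 110, by = 0.25)
  specs <- pmax(outer(base, levels - ref_level, `+`), teacher$floor_db)
  sones <- teacher_sones(specs, teacher)
  if (any(diff(sones) <= 0)) {
    stop("sone-versus-level curve is not strictly increasing; teacher defect")
  }
  list(sones = sones, phons = levels)
}

#' Convert between sones and phons under a teacher's calibration
#'
#' The mapping is the inverted 1-kHz loudness-growth curve of the teacher.
#' Phons are clipped at 0 for reporting; above the calibrated range the
#' mapping is extended linearly in log-sones.
#'
#' @param sones loudness in sones (vectorised).
#' @param phons loudness level in phons (vectorised).
#' @param teacher a [tvl_teacher()].
#' @return the converted values.
#' @export
sone_to_phon <- function(sones, teacher) {
  map <- teacher$sone_phon
  ls <- log(pmax(sones, 1e-12))
  lg <- log(map$sones)
  out <- approx(lg, map$phons, xout = ls, rule = 2)$y
  hi <- ls > lg[length(lg)]
  if (any(hi)) {
    k <- length(lg)
    slope <- (map$phons[k] - map$phons[k - 1]) / (lg[k] - lg[k - 1])
    out[hi] <- map$phons[k] + slope * (ls[hi] - lg[k])
  }
  pmax(out, 0)
}

#' @rdname sone_to_phon
#' @export
phon_to_sone <- function(phons, teacher) {
  map <- teacher$sone_phon
  lg <- log(map$sones)
  out <- approx(map$phons, lg, xout = pmax(phons, 0), rule = 2)$y
  hi <- phons > map$phons[length(map$phons)]
  if (any(hi)) {
    k <- length(lg)
    slope <- (lg[k] - lg[k - 1]) / (map$phons[k] - map$phons[k - 1])
    out[hi] <- lg[k] + slope * (phons[hi] - map$phons[k])
  }
  exp(out)
}
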