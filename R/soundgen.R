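#' Specification of a synthetic sound
#'
#' Describes one seeded synthetic stimulus: a pure tone (optionally in
#' white or pink background noise), a bandpass or spectrally notched noise
#' with an optional spectral slope, a broadband white/pink noise, or a
#' speech-like surrogate. All stimuli are generated deterministically from
#' the embedded seed.
#'
#' @param kind one of `"tone"`, `"tone_in_noise"`, `"bandpass_noise"`,
#'   `"notched_noise"`, `"white_noise"`, `"pink_noise"`,
#'   `"speech_surrogate"`.
#' @param level RMS level in dB SPL (0 to 110). For `tone_in_noise` this is
#'   the tone component's level.
#' @param duration duration in seconds.
#' @param seed integer seed for this sound.
#' @param frequency tone frequency in Hz (20 to 8000).
#' @param noise_color `"white"` or `"pink"` background for `tone_in_noise`.
#' @param noise_level background-noise RMS level in dB SPL; must be at
#'   least 10 dB below the tone level.
#' @param center geometric centre frequency in Hz for bandpass/notched
#'   noise.
#' @param bandwidth_oct bandwidth in octaves (bandpass noise).
#' @param notch_oct notch width in octaves (notched noise).
#' @param slope_db_oct spectral slope in dB/octave applied across the
#'   passband.
#' @return an object of class `sound_spec`.
#' @export
sound_spec <- function(kind, level, duration = 0.5, seed = 1,
                       frequency = 1000, noise_color = c("white", "pink"),
                       noise_level = NULL, center = 1000,
                       bandwidth_oct = 1, notch_oct = 1, slope_db_oct = 0) {
  kind <- match.arg(kind, c("tone", "tone_in_noise", "bandpass_noise",
                            "notched_noise", "white_noise", "pink_noise",
                            "speech_surrogate"))
  noise_color <- match.arg(noise_color)
  if (level < 0 || level > 110) stop("level must lie in 0..110 dB SPL")
  if (duration <= 0) stop("duration must be positive")
  if (kind %in% c("tone", "tone_in_noise") &&
      (frequency < 20 || frequency > 8000)) {
    stop("tone frequency must lie in 20..8000 Hz")
  }
  if (kind == "tone_in_noise") {
    if (is.null(noise_level)) stop("tone_in_noise requires noise_level")
    if (noise_level > level - 10) {
      stop("background noise must stay at least 10 dB below the tone")
    }
  }
  if (kind == "bandpass_noise" && bandwidth_oct < 0) {
    stop("bandwidth must be non-negative")
  }
  if (kind == "notched_noise" && (notch_oct < 0 || notch_oct > 8)) {
    stop("notch width out of range")
  }
  structure(list(kind = kind, level = level, duration = duration,
                 seed = as.integer(seed), frequency = frequency,
                 noise_color = noise_color, noise_level = noise_level,
                 center = center, bandwidth_oct = bandwidth_oct,
                 notch_oct = notch_oct, slope_db_oct = slope_db_oct),
            class = "sound_spec")
}

# Gaussian noise with a prescribed one-sided spectral amplitude envelope,
# built in the frequency domain for exact, seeded spectral shaping.
spectral_noise <- function(n_samples, envelope, sample_rate = 16000) {
  n <- n_samples + n_samples %% 2  # even length; truncate below if needed
  half <- n %/% 2
  f <- (1:(half - 1)) * sample_rate / n
  amp <- envelope(f)
  re <- rnorm(half - 1); im <- rnorm(half - 1)
  spec <- complex(real = c(0, amp * re, 0),
                  imaginary = c(0, amp * im, 0))
  full <- c(spec, Conj(rev(spec[2:half])))
  (Re(stats::fft(full, inverse = TRUE)) / n)[seq_len(n_samples)]
}

#' Synthesize a sound from its specification
#'
#' Deterministic given the spec's seed; the result is RMS-scaled so the
#' measured level matches the spec (total level for single-component kinds,
#' per-component levels for `tone_in_noise`).
#'
#' @param spec a [sound_spec()].
#' @param calibration dB SPL of a unit-RMS waveform.
#' @return an [audio_signal()].
#' @export
synthesize <- function(spec, calibration = 94) {
  stopifnot(inherits(spec, "sound_spec"))
  fs <- 16000
  n <- round(spec$duration * fs)
  if (spec$kind == "speech_surrogate") {
    return(speech_surrogate(spec$seed, spec$duration, spec$level,
                            calibration = calibration))
  }
  with_seed(spec$seed, {
    if (spec$kind == "tone_in_noise") {
      phase <- runif(1, 0, 2 * pi)
      tone <- sin(2 * pi * spec$frequency * (0:(n - 1)) / fs + phase)
      tone <- tone / sqrt(mean(tone^2)) * 10^((spec$level - calibration) / 20)
      noise <- if (spec$noise_color == "white") rnorm(n) else {
        spectral_noise(n, function(f) ifelse(f >= 20, 1 / sqrt(f), 0))
      }
      noise <- noise / sqrt(mean(noise^2)) *
        10^((spec$noise_level - calibration) / 20)
      audio_signal(tone + noise, fs, calibration)
    } else {
      sig <- switch(spec$kind,
        tone = {
          phase <- runif(1, 0, 2 * pi)
          sin(2 * pi * spec$frequency * (0:(n - 1)) / fs + phase)
        },
        white_noise = rnorm(n),
        pink_noise = spectral_noise(n, function(f) {
          ifelse(f >= 20, 1 / sqrt(f), 0)
        }),
        bandpass_noise = {
          f1 <- max(20, spec$center / 2^(spec$bandwidth_oct / 2))
          f2 <- min(8000, spec$center * 2^(spec$bandwidth_oct / 2))
          s <- spec$slope_db_oct
          fc <- spec$center
          x <- spectral_noise(n, function(f) {
            ifelse(f >= f1 & f <= f2, 10^(s * log2(f / fc) / 20), 0)
          })
          if (sqrt(mean(x^2)) == 0) {
            # degenerate bandwidth: collapse to a component at the centre
            x <- sin(2 * pi * fc * (0:(n - 1)) / fs + runif(1, 0, 2 * pi))
          }
          x
        },
        notched_noise = {
          f1 <- spec$center / 2^(spec$notch_oct / 2)
          f2 <- spec$center * 2^(spec$notch_oct / 2)
          s <- spec$slope_db_oct
          fc <- spec$center
          spectral_noise(n, function(f) {
            ifelse(f >= 20 & f <= 8000 & !(f > f1 & f < f2),
                   10^(s * log2(f / fc) / 20), 0)
          })
        }
      )
      scale_to_rms_level(audio_signal(sig, fs, calibration), spec$level)
    }
  })
}

#' Speech-like surrogate signal
#'
#' A stand-in for recorded speech: a sequence of syllable-length segments
#' of amplitude-modulated harmonic complexes with a gliding fundamental and
#' randomly placed formant-like spectral resonances, interleaved with
#' unvoiced noise bursts and silent gaps. The long-term spectrum is
#' broadband below 8 kHz and the instantaneous-loudness distribution is
#' broad, spanning near-silence in the gaps up to the syllable peaks.
#'
#' @param seed integer seed.
#' @param duration duration in seconds (at least 0.5).
#' @param level overall RMS level in dB SPL (gaps included).
#' @param calibration dB SPL of a unit-RMS waveform.
#' @return an [audio_signal()].
#' @export
speech_surrogate <- function(seed, duration, level, calibration = 94) {
  if (duration < 0.5) stop("surrogate duration must be at least 0.5 s")
  fs <- 16000
  n_total <- round(duration * fs)
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n_total) {
      seg_dur <- runif(1, 0.12, 0.3)
      m <- round(seg_dur * fs)
      t_seg <- (0:(m - 1)) / fs
      u <- runif(1)
      if (u < 0.18) {                       # silent gap
        seg <- numeric(m)
      } else if (u < 0.30) {                # unvoiced burst
        f1 <- runif(1, 1200, 3000)
        f2 <- f1 * runif(1, 1.5, 2.5)
        seg <- spectral_noise(m, function(f) {
          ifelse(f >= f1 & f <= min(f2, 7800), 1, 0)
        })
        seg <- 0.3 * seg / max(sqrt(mean(seg^2)), 1e-12)
      } else {                              # voiced syllable
        f0 <- runif(1, 90, 220)
        glide <- runif(1, 0.85, 1.2)
        formants <- c(runif(1, 300, 800), runif(1, 900, 2200),
                      runif(1, 2400, 3400))
        bw <- c(90, 120, 160)
        inst_f0 <- f0 * seq(1, glide, length.out = m)
        phase0 <- 2 * pi * cumsum(inst_f0) / fs
        n_harm <- floor(7800 / (f0 * max(1, glide)))
        seg <- numeric(m)
        for (k in seq_len(n_harm)) {
          fk <- k * f0
          res <- sum(1 / (1 + ((fk - formants) / bw)^2))
          a <- (1 / k) * (0.2 + res)        # -6 dB/oct source x formants
          seg <- seg + a * sin(k * phase0 + runif(1, 0, 2 * pi))
        }
        seg <- seg / max(sqrt(mean(seg^2)), 1e-12)
      }
      # raised-cosine 20-ms onset/offset ramps; syllabic modulation
      ramp <- pmin(1, pmin(t_seg, rev(t_seg)) / 0.02)
      seg <- seg * (0.5 - 0.5 * cos(pi * ramp)) *
        (0.6 + 0.4 * sin(2 * pi * runif(1, 2, 6) * t_seg))
      out <- c(out, seg)
    }
    out <- out[seq_len(n_total)]
    scale_to_rms_level(audio_signal(out, fs, calibration), level)
  })
}

#' Idealized band spectrum of a synthetic sound
#'
#' Computes the deterministic (expected) 61-band spectrum of a sound
#' specification directly in the spectral domain, without synthesizing a
#' waveform: a tone contributes its windowed line spectrum, a noise its
#' band-integrated power envelope, and composites power-add. This mirrors
#' training material composed as generated spectra rather than recorded
#' frames: the resulting spectra are free of single-frame periodogram
#' scatter. Not defined for `speech_surrogate` (use framed audio).
#'
#' @param spec a [sound_spec()].
#' @param bands a [design_bands()] definition.
#' @param calibration dB SPL of a unit-RMS waveform.
#' @param floor_db per-band silence floor.
#' @return a length-61 vector of band levels in dB SPL.
#' @export
expected_band_spectrum <- function(spec, bands, calibration = 94,
                                   floor_db = -30) {
  stopifnot(inherits(spec, "sound_spec"), inherits(bands, "band_definition"))
  if (spec$kind == "speech_surrogate") {
    stop("speech surrogates have no idealized spectrum; frame the audio")
  }
  bd <- bands$bands
  n_bins <- bd$bin_hi[nrow(bd)]
  bin_f <- (1:n_bins) * bands$sample_rate / bands$dft_size
  group <- rep.int(seq_len(nrow(bd)), bd$bin_hi - bd$bin_lo + 1)

  tone_bands <- function(freq, level) {
    n <- bands$dft_size
    phase <- with_seed(spec$seed, runif(1, 0, 2 * pi))
    amp <- sqrt(2) * 10^((level - calibration) / 20)
    frame <- amp * sin(2 * pi * freq * (0:(n - 1)) / bands$sample_rate +
                         phase) * hann_window(n)
    10^(band_spectrum(frame, bands, calibration, -400)[, 1] / 10)
  }
  env_bands <- function(env, level) {
    p <- env(bin_f)^2
    if (sum(p) == 0) p[which.min(abs(bin_f - spec$center))] <- 1
    bp <- rowsum(matrix(p, ncol = 1), group)[, 1]
    (bp / sum(bp)) * 10^(level / 10)
  }
  noise_env <- function(color) {
    if (color == "white") function(f) ifelse(f >= 20, 1, 0)
    else function(f) ifelse(f >= 20, 1 / sqrt(f), 0)
  }

  pow <- switch(spec$kind,
    tone = tone_bands(spec$frequency, spec$level),
    tone_in_noise = tone_bands(spec$frequency, spec$level) +
      env_bands(noise_env(spec$noise_color), spec$noise_level),
    white_noise = env_bands(noise_env("white"), spec$level),
    pink_noise = env_bands(noise_env("pink"), spec$level),
    bandpass_noise = {
      f1 <- max(20, spec$center / 2^(spec$bandwidth_oct / 2))
      f2 <- min(8000, spec$center * 2^(spec$bandwidth_oct / 2))
      s <- spec$slope_db_oct; fc <- spec$center
      env_bands(function(f) {
        ifelse(f >= f1 & f <= f2, 10^(s * log2(f / fc) / 20), 0)
      }, spec$level)
    },
    notched_noise = {
      f1 <- spec$center / 2^(spec$notch_oct / 2)
      f2 <- spec$center * 2^(spec$notch_oct / 2)
      s <- spec$slope_db_oct; fc <- spec$center
      env_bands(function(f) {
        ifelse(f >= 20 & f <= 8000 & !(f > f1 & f < f2),
               10^(s * log2(f / fc) / 20), 0)
      }, spec$level)
    }
  )
  pmax(10 * log10(pmax(pow, 1e-30)), floor_db)
}

#' Corpus manifest
#'
#' A seeded, fully reproducible description of a synthetic corpus: the list
#' of sound specifications plus the split fractions used after the row-level
#' shuffle.
#'
#' @param specs list of [sound_spec()] objects (non-empty).
#' @param seed global seed controlling the shuffle.
#' @param split named fractions summing to 1 (default 90% train, 10%
#'   validation).
#' @param classes optional character vector of class labels, one per spec.
#' @return an object of class `corpus_manifest`.
#' @export
corpus_manifest <- function(specs, seed,
                            split = c(train = 0.9, validation = 0.1),
                            classes = NULL) {
  if (length(specs) == 0) stop("manifest must contain at least one sound")
  if (abs(sum(split) - 1) > 1e-9) stop("split fractions must sum to 1")
  if (is.null(classes)) {
    classes <- vapply(specs, function(s) s$kind, character(1))
  }
  stopifnot(length(classes) == length(specs))
  structure(list(specs = specs, seed = as.integer(seed), split = split,
                 classes = classes),
            class = "corpus_manifest")
}

#' @export
print.corpus_manifest <- function(x, ...) {
  cat(sprintf("corpus_manifest: %d sounds, seed %d\n",
              length(x$specs), x$seed))
  print(table(x$classes))
  invisible(x)
}

# deterministic per-sound seed derived from a global seed
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

#' Default manifests emulating the training material
#'
#' `manifest_tones_noises()` mixes pure tones (levels 15 to 110 dB SPL,
#' frequencies log-uniform 50 Hz to 7.5 kHz, half with white or pink
#' background noise up to 10 dB below the tone) with bandpass and notched
#' noises (levels 20 to 100 dB SPL, bandwidths log-uniform 0.1 to 5
#' octaves, notch widths 0 to 2 octaves, spectral slopes -6 to +6
#' dB/octave) in the 7:5 proportion of the original material.
#' `manifest_speech()` generates speech surrogates at a 60 dB SPL file
#' level. `manifest_mixed()` combines tones+noises and speech surrogates in
#' the original 12:5 proportion.
#'
#' Each tone/noise sound is one independent parameter draw lasting a
#' single analysis frame (0.07 s), mirroring training material generated
#' as independent spectra; speech surrogates are sentence-length (2 s)
#' with correlated successive frames.
#'
#' @param n_rows approximate number of labelled spectra the corpus should
#'   yield at the default 560-sample hop.
#' @param seed global seed.
#' @param duration per-sound duration in seconds (tones/noises).
#' @return a [corpus_manifest()].
#' @export
manifest_tones_noises <- function(n_rows = 30000, seed = 1,
                                  duration = 0.07) {
  rows_per <- floor((duration * 16000 - 1024) / 560) + 1
  n_sounds <- ceiling(n_rows / rows_per)
  n_tone <- round(n_sounds * 7 / 12)
  with_seed(seed, {
    specs <- vector("list", n_sounds)
    classes <- character(n_sounds)
    for (i in seq_len(n_sounds)) {
      s_i <- derive_seed(seed, i)
      if (i <= n_tone) {
        lev <- runif(1, 15, 110)
        freq <- exp(runif(1, log(50), log(7500)))
        if (runif(1) < 0.5 && lev >= 12) {
          nl <- max(0, lev - runif(1, 10, 40))
          specs[[i]] <- sound_spec("tone_in_noise", lev, duration, s_i,
                                   frequency = freq,
                                   noise_color = sample(c("white", "pink"), 1),
                                   noise_level = nl)
          classes[i] <- "tone"
        } else {
          specs[[i]] <- sound_spec("tone", lev, duration, s_i,
                                   frequency = freq)
          classes[i] <- "tone"
        }
      } else {
        lev <- runif(1, 20, 100)
        ctr <- exp(runif(1, log(150), log(5000)))
        slope <- runif(1, -6, 6)
        if (runif(1) < 0.5) {
          bw <- exp(runif(1, log(0.1), log(5)))
          specs[[i]] <- sound_spec("bandpass_noise", lev, duration, s_i,
                                   center = ctr, bandwidth_oct = bw,
                                   slope_db_oct = slope)
        } else {
          nw <- runif(1, 0, 2)
          specs[[i]] <- sound_spec("notched_noise", lev, duration, s_i,
                                   center = ctr, notch_oct = nw,
                                   slope_db_oct = slope)
        }
        classes[i] <- "noise"
      }
    }
    corpus_manifest(specs, seed, classes = classes)
  })
}

#' @rdname manifest_tones_noises
#' @export
manifest_speech <- function(n_rows = 30000, seed = 1, duration = 2) {
  rows_per <- floor((duration * 16000 - 1024) / 560) + 1
  n_sounds <- ceiling(n_rows / rows_per)
  specs <- lapply(seq_len(n_sounds), function(i) {
    sound_spec("speech_surrogate", 60, duration, derive_seed(seed, 10000 + i))
  })
  corpus_manifest(specs, seed, classes = rep("speech", n_sounds))
}

#' @rdname manifest_tones_noises
#' @export
manifest_mixed <- function(n_rows = 30000, seed = 1) {
  tn <- manifest_tones_noises(round(n_rows * 12 / 17), seed)
  sp <- manifest_speech(round(n_rows * 5 / 17), seed + 1)
  corpus_manifest(c(tn$specs, sp$specs), seed,
                  classes = c(tn$classes, sp$classes))
}

#' Build a labelled corpus from a manifest
#'
#' Synthesizes every sound in the manifest, frames it (560-sample hop by
#' default), computes the 61-band spectra, labels each frame with the
#' teacher's instantaneous loudness level, shuffles the rows with the
#' manifest seed, and assigns the train/validation split.
#'
#' @param manifest a [corpus_manifest()].
#' @param teacher a [tvl_teacher()].
#' @param hop frame advance in samples (default 560).
#' @param representation `"framed"` (default) synthesizes every sound and
#'   frames the waveform; `"idealized"` uses [expected_band_spectrum()]
#'   for the artificial kinds (one deterministic spectrum per parameter
#'   draw, the representation the distillation protocol trains on) while
#'   speech surrogates are always framed audio.
#' @return a `labelled_dataset`: list with `inputs` (rows x 61 matrix of dB
#'   levels), `labels` (phons), `split` (factor `train`/`validation`),
#'   `class` and `sound_id` per row, plus the `manifest` and its hash.
#' @export
build_corpus <- function(manifest, teacher, hop = 560,
                         representation = c("framed", "idealized")) {
  stopifnot(inherits(manifest, "corpus_manifest"),
            inherits(teacher, "tvl_teacher"))
  representation <- match.arg(representation)
  bands <- teacher$bands
  parts <- vector("list", length(manifest$specs))
  for (i in seq_along(manifest$specs)) {
    spec <- manifest$specs[[i]]
    if (representation == "idealized" && spec$kind != "speech_surrogate") {
      x <- matrix(expected_band_spectrum(spec, bands, teacher$calibration,
                                         teacher$floor_db), nrow = 1)
      spectra <- t(x)
    } else {
      sig <- synthesize(spec, calibration = teacher$calibration)
      frames <- frame_signal(sig, bands$dft_size, hop)
      spectra <- band_spectrum(frames, bands, teacher$calibration,
                               teacher$floor_db)
    }
    parts[[i]] <- list(x = t(spectra), y = teacher_phons(teacher, spectra),
                       class = manifest$classes[i], id = i)
  }
  inputs <- do.call(rbind, lapply(parts, `[[`, "x"))
  labels <- unlist(lapply(parts, `[[`, "y"))
  cls <- unlist(lapply(parts, function(p) rep(p$class, length(p$y))))
  sid <- unlist(lapply(parts, function(p) rep(p$id, length(p$y))))
  stopifnot(nrow(inputs) == length(labels), all(is.finite(labels)))

  n <- nrow(inputs)
  ord <- with_seed(manifest$seed, sample.int(n))
  n_train <- round(n * manifest$split[["train"]])
  split <- factor(rep("validation", n), levels = c("train", "validation"))
  split[seq_len(n_train)] <- "train"

  structure(list(
    inputs = inputs[ord, , drop = FALSE],
    labels = labels[ord],
    split = split,
    class = cls[ord],
    sound_id = sid[ord],
    manifest = manifest,
    manifest_hash = config_hash(manifest)
  ), class = "labelled_dataset")
}

#' @export
print.labelled_dataset <- function(x, ...) {
  cat(sprintf(
    "labelled_dataset: %d rows x %d bands, labels %.1f..%.1f phons\n",
    nrow(x$inputs), ncol(x$inputs), min(x$labels), max(x$labels)))
  print(table(x$class, x$split))
  invisible(x)
}

#' Save or load a labelled dataset
#'
#' Single-file container (RDS) holding the input matrix, labels, split
#' mask, and the generating manifest, with a format version checked on
#' load.
#'
#' @param dataset a `labelled_dataset`.
#' @param path file path.
#' @return `load_dataset()` returns the `labelled_dataset`.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "labelled_dataset"))
  saveRDS(list(format = "tvlnet-dataset", version = 1L, data = dataset),
          path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "tvlnet-dataset") || obj$version != 1L) {
    stop("not a tvlnet dataset file (or unsupported version): ", path)
  }
  obj$data
}
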