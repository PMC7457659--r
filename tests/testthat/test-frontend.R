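test_that("canonical band design has 61 bands with the stated structure", {
  b <- test_bands()
  bd <- b$bands
  expect_identical(nrow(bd), 61L)
  # one-bin bands with centres at or below 200 Hz, 15.625 Hz apart
  narrow <- bd[bd$center_hz <= 200, ]
  expect_true(all(narrow$bin_lo == narrow$bin_hi))
  expect_equal(diff(narrow$center_hz), rep(16000 / 1024, nrow(narrow) - 1))
  # ninth-octave edge ratio above, except the band truncated at f_max
  wide <- bd[bd$bin_lo != bd$bin_hi | bd$center_hz > 200, ]
  full <- wide[wide$edge_hi < 8000, ]
  expect_equal(full$edge_hi / full$edge_lo, rep(2^(1 / 9), nrow(full)),
               tolerance = 1e-12)
  # bins partition (0, 8000]: contiguous, non-overlapping, complete
  expect_identical(bd$bin_lo[1], 1L)
  expect_identical(bd$bin_hi[61], 512L)
  expect_true(all(bd$bin_lo[-1] == bd$bin_hi[-61] + 1))
  expect_true(all(diff(bd$center_hz) > 0))
  expect_lte(max(bd$center_hz), 8000)
})

test_that("band design rejects invalid configurations", {
  expect_error(design_bands(1023, 16000, 8000), "even")
  expect_error(design_bands(1024, 16000, 9000), "Nyquist")
})

test_that("frame count follows the hop formula", {
  sig <- audio_signal(rep(0.1, 16000))
  expect_identical(ncol(frame_signal(sig, 1024, 560)), 27L)
  expect_identical(ncol(frame_signal(sig, 1024, 16)), 937L)
  one <- audio_signal(rep(0.1, 1024))
  expect_identical(ncol(frame_signal(one, 1024, 560)), 1L)
  expect_identical(ncol(frame_signal(one, 1024, 9999)), 1L)
  expect_error(frame_signal(audio_signal(rep(0.1, 100)), 1024, 16),
               "shorter")
})

test_that("band spectrum is calibrated for tones and floored for silence", {
  b <- test_bands()
  silence <- band_spectrum(matrix(0, 1024, 2), b)
  expect_true(all(silence == -30))

  sp <- tone_spectrum(1000, 60)[, 1]
  peak_band <- which.max(sp)
  expect_true(b$bands$edge_lo[peak_band] <= 1000 &&
                b$bands$edge_hi[peak_band] > 1000)
  expect_equal(sp[peak_band], 60, tolerance = 1)
  # bands at least a third octave away are far down the window skirt
  far <- b$bands$center_hz < 1000 / 2^(1 / 3) |
    b$bands$center_hz > 1000 * 2^(1 / 3)
  expect_true(all(sp[far] <= 20))
})

test_that("banded power agrees with time-domain power for broadband noise", {
  sig <- synthesize(sound_spec("white_noise", 60, 0.3, seed = 2))
  sp <- band_spectrum(frame_signal(sig), test_bands())
  total <- 10 * log10(mean(colSums(10^(sp / 10))))
  expect_equal(total, 60, tolerance = 1)
})

test_that("waveform gain shifts every band above the floor by that gain", {
  sig <- synthesize(sound_spec("pink_noise", 60, 0.2, seed = 3))
  sp1 <- band_spectrum(frame_signal(sig), test_bands())
  sp2 <- band_spectrum(frame_signal(
    audio_signal(sig$samples * 10^(7 / 20))), test_bands())
  above <- sp1 > -20  # clear of the floor in both
  expect_equal(sp2[above], sp1[above] + 7, tolerance = 0.01)
})

test_that("RMS scaling is exact, idempotent and composable", {
  sig <- synthesize(sound_spec("white_noise", 70, 0.2, seed = 4))
  s60 <- scale_to_rms_level(sig, 60)
  expect_equal(rms_level(s60), 60, tolerance = 1e-9)
  expect_equal(scale_to_rms_level(s60, 60)$samples, s60$samples)
  via70 <- scale_to_rms_level(scale_to_rms_level(sig, 70), 60)
  expect_equal(via70$samples, s60$samples, tolerance = 1e-12)
  # closed-form gain: unit RMS at 94 dB calibration scaled to 60
  unit <- audio_signal(sin(2 * pi * 440 * (0:15999) / 16000) * sqrt(2))
  expect_equal(rms_level(unit), 94, tolerance = 1e-6)
  scaled <- scale_to_rms_level(unit, 60)
  expect_equal(scaled$samples, unit$samples * 10^((60 - 94) / 20),
               tolerance = 1e-9)
  expect_error(scale_to_rms_level(audio_signal(numeric(100)), 60),
               "all-zero")
})

test_that("WAV round trip preserves samples; bad files are rejected", {
  sig <- synthesize(sound_spec("white_noise", 60, 0.1, seed = 5))
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(sig, f, format = "float")
  back <- read_wav(f)
  expect_equal(back$samples, sig$samples, tolerance = 1e-7)
  write_wav(sig, f, format = "pcm16")
  back16 <- read_wav(f)
  expect_equal(back16$samples, sig$samples, tolerance = 1e-3)
  writeBin(as.raw(1:64), f)
  expect_error(read_wav(f), "RIFF")
})

test_that("band spectra export to the documented CSV layout", {
  sp <- tone_spectrum(500, 50)
  f <- withr::local_tempfile(fileext = ".csv")
  write_band_spectrum_csv(sp, f)
  df <- read.csv(f)
  expect_identical(names(df)[1:3], c("frame_time_s", "band_01", "band_02"))
  expect_identical(ncol(df), 62L)
  expect_equal(unname(as.matrix(df[, -1])), unname(t(sp)),
               tolerance = 1e-6, ignore_attr = TRUE)
})
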