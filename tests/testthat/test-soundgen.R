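test_that("synthesis is deterministic given the seed", {
  s1 <- synthesize(sound_spec("notched_noise", 65, 0.2, seed = 7,
                              center = 1500, notch_oct = 1))
  s2 <- synthesize(sound_spec("notched_noise", 65, 0.2, seed = 7,
                              center = 1500, notch_oct = 1))
  expect_identical(s1$samples, s2$samples)
  s3 <- synthesize(sound_spec("notched_noise", 65, 0.2, seed = 8,
                              center = 1500, notch_oct = 1))
  expect_false(identical(s1$samples, s3$samples))
})

test_that("synthesized sounds hit their RMS level and spectral shape", {
  for (kind in c("tone", "white_noise", "pink_noise", "bandpass_noise",
                 "notched_noise")) {
    sig <- synthesize(sound_spec(kind, 63, 0.2, seed = 2))
    expect_equal(rms_level(sig), 63, tolerance = 0.1)
  }
  b <- test_bands()
  sp <- band_spectrum(frame_signal(
    synthesize(sound_spec("tone", 60, 0.2, seed = 2, frequency = 1000))), b)
  peak <- which.max(rowMeans(sp))
  expect_true(b$bands$edge_lo[peak] <= 1000 && b$bands$edge_hi[peak] > 1000)
  expect_equal(max(rowMeans(sp)), 60, tolerance = 1)
  # notched noise has a hole at the notch
  spn <- rowMeans(band_spectrum(frame_signal(
    synthesize(sound_spec("notched_noise", 70, 0.3, seed = 3,
                          center = 1000, notch_oct = 1))), b))
  inside <- b$bands$center_hz > 1000 / 2^0.4 & b$bands$center_hz < 1000 * 2^0.4
  near <- b$bands$center_hz > 250 & b$bands$center_hz < 4000
  expect_lt(max(spn[inside]), max(spn[near & !inside]) - 15)
})

test_that("vanishing bandwidth degenerates to a tone at the centre", {
  b <- test_bands()
  sig <- synthesize(sound_spec("bandpass_noise", 60, 0.2, seed = 4,
                               center = 1000, bandwidth_oct = 1e-6))
  sp <- rowMeans(band_spectrum(frame_signal(sig), b))
  peak <- which.max(sp)
  expect_true(b$bands$edge_lo[peak] <= 1000 && b$bands$edge_hi[peak] > 1000)
  expect_equal(rms_level(sig), 60, tolerance = 0.1)
})

test_that("tone-in-noise respects component levels and their spacing rule", {
  spec <- sound_spec("tone_in_noise", 70, 0.2, seed = 5, frequency = 2000,
                     noise_level = 50)
  sig <- synthesize(spec)
  # total power is the sum of the component powers
  expect_equal(rms_level(sig), 10 * log10(10^7 + 10^5), tolerance = 0.5)
  expect_error(sound_spec("tone_in_noise", 70, noise_level = 65),
               "10 dB below")
})

test_that("speech surrogate is broad in loudness with near-silent gaps", {
  teach <- test_teacher()
  sig <- speech_surrogate(3, duration = 3, level = 60)
  expect_equal(rms_level(sig), 60, tolerance = 0.1)
  ph <- teacher_phons(teach, band_spectrum(frame_signal(sig), teach$bands))
  expect_gte(diff(range(ph)), 40)
  expect_lte(min(ph), 15)
  sig2 <- speech_surrogate(4, duration = 3, level = 60)
  expect_false(identical(sig$samples, sig2$samples))
  expect_error(speech_surrogate(1, duration = 0.2, level = 60), "0.5")
})

test_that("corpus building frames, labels and splits as documented", {
  teach <- test_teacher()
  one <- corpus_manifest(list(sound_spec("tone", 60, 1, seed = 1,
                                         frequency = 1000)), seed = 1)
  ds <- build_corpus(one, teach)
  expect_identical(nrow(ds$inputs), 27L)
  # steady 1-kHz tone frames carry the phon-identity label
  expect_true(all(abs(ds$labels - 60) < 0.5))

  man <- manifest_tones_noises(1000, seed = 3)
  ds2 <- build_corpus(man, teach)
  n <- nrow(ds2$inputs)
  expect_equal(sum(ds2$split == "train"), round(0.9 * n))
  expect_equal(sum(ds2$split == "validation"), n - round(0.9 * n))
  expect_error(corpus_manifest(list(), seed = 1), "at least one")
})

test_that("identical manifest and seed reproduce the dataset exactly", {
  teach <- test_teacher()
  man <- manifest_tones_noises(300, seed = 9)
  d1 <- build_corpus(man, teach)
  d2 <- build_corpus(manifest_tones_noises(300, seed = 9), teach)
  expect_identical(d1$inputs, d2$inputs)
  expect_identical(d1$labels, d2$labels)
  expect_identical(d1$split, d2$split)
  expect_identical(d1$manifest_hash, d2$manifest_hash)
})

test_that("default mixed manifest covers all classes and a wide label span", {
  teach <- test_teacher()
  man <- manifest_mixed(2000, seed = 5)
  expect_setequal(unique(man$classes), c("tone", "noise", "speech"))
  kinds <- vapply(man$specs, function(s) s$kind, character(1))
  expect_true(all(c("tone", "bandpass_noise", "notched_noise",
                    "speech_surrogate") %in% kinds))
  tone_levels <- vapply(man$specs[kinds %in% c("tone", "tone_in_noise")],
                        function(s) s$level, numeric(1))
  expect_lt(min(tone_levels), 25)
  expect_gt(max(tone_levels), 100)
  ds <- build_corpus(man, teach)
  expect_gt(diff(range(ds$labels)), 60)
})

test_that("dataset container round-trips and rejects foreign files", {
  teach <- test_teacher()
  ds <- build_corpus(manifest_tones_noises(100, seed = 2), teach)
  f <- withr::local_tempfile(fileext = ".rds")
  save_dataset(ds, f)
  back <- load_dataset(f)
  expect_identical(back$inputs, ds$inputs)
  expect_identical(back$labels, ds$labels)
  saveRDS(list(format = "other"), f)
  expect_error(load_dataset(f), "not a tvlnet dataset")
})
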