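test_that("ear transfer shows canal resonance and low-frequency rolloff", {
  teach <- test_teacher()
  flat <- matrix(50, 61, 1)
  out <- ear_filter(flat, teach)
  gain <- out[, 1] - 50
  centers <- teach$bands$bands$center_hz
  g_at <- function(f) gain[which.min(abs(centers - f))]
  expect_gt(g_at(3000), g_at(1000))   # ear-canal resonance
  expect_lt(g_at(100), g_at(1000))    # middle-ear attenuation
  # linearity: shape identical up to the additive input level
  out2 <- ear_filter(flat + 20, teach)
  expect_equal(out2[, 1] - out[, 1], rep(20, 61))
  # floor bands stay at the floor
  mixed <- matrix(-30, 61, 1); mixed[30] <- 60
  outm <- ear_filter(mixed, teach)
  expect_true(all(outm[-30] == -30))
})

test_that("excitation pattern matches a direct filter-bank oracle", {
  teach <- test_teacher()
  set.seed(42)
  for (k in 1:3) {
    levels <- pmax(runif(61, -30, 90), -30)
    levels[sample(61, 20)] <- -30
    got <- excitation_pattern(levels, teach)[, 1]
    expect_equal(got, oracle_excitation(levels, teach), tolerance = 1e-10)
  }
})

test_that("excitation peaks at the channel nearest the component's Cam", {
  teach <- test_teacher()
  sp <- rep(-30, 61)
  idx <- which(teach$bands$bands$edge_lo <= 1000 &
                 teach$bands$bands$edge_hi > 1000)
  sp[idx] <- 60
  e <- excitation_pattern(ear_filter(sp, teach), teach)[, 1]
  peak_cam <- teach$channels$cam[which.max(e)]
  expect_equal(peak_cam, 15.6, tolerance = 0.3)
})

test_that("excitation is additive in power for remote components", {
  teach <- test_teacher()
  centers <- teach$bands$bands$center_hz
  i <- which.min(abs(centers - 300))   # ~7.6 Cams
  j <- which.min(abs(centers - 4000))  # ~27 Cams
  single <- function(k) {
    sp <- rep(-30, 61); sp[k] <- 70
    10^(excitation_pattern(sp, teach)[, 1] / 10)
  }
  both <- rep(-30, 61); both[c(i, j)] <- 70
  e_both <- excitation_pattern(both, teach)[, 1]
  e_sum <- 10 * log10(single(i) + single(j))
  expect_equal(e_both, e_sum, tolerance = 0.1)
})

test_that("all-floor input excites no channel above the floor equivalent", {
  teach <- test_teacher()
  e <- excitation_pattern(rep(-30, 61), teach)[, 1]
  expect_true(all(e <= -30 + 10 * log10(61) + 1))
})

test_that("specific loudness is compressive, monotone and channel-wise", {
  teach <- test_teacher()
  # sub-threshold excitation gives near-zero loudness density
  low <- specific_loudness(rep(-20, 150), teach)
  expect_true(all(low < 1e-3))
  # 10 dB more excitation at moderate level grows N' by less than 10x
  n60 <- specific_loudness(rep(60, 150), teach)
  n70 <- specific_loudness(rep(70, 150), teach)
  expect_true(all(n70 / n60 < 10))
  expect_true(all(n70 > n60))
  # monotone non-decreasing per channel over a wide range
  grid <- seq(-10, 110, by = 5)
  nn <- specific_loudness(matrix(rep(grid, each = 150), 150), teach)
  expect_true(all(diff(t(nn)) >= 0))
  # channel-wise map: perturbing one channel leaves the others untouched
  e0 <- rep(60, 150)
  e1 <- e0; e1[75] <- 80
  d <- specific_loudness(e1, teach) - specific_loudness(e0, teach)
  expect_true(all(d[-75] == 0))
  expect_gt(d[75], 0)
})

test_that("instantaneous loudness integrates density linearly", {
  teach <- test_teacher()
  expect_equal(instantaneous_loudness(rep(0, 150), teach)$sones, 0)
  n <- runif(150, 0, 2)
  expect_equal(instantaneous_loudness(2 * n, teach)$sones,
               2 * instantaneous_loudness(n, teach)$sones)
  expect_equal(instantaneous_loudness(n, teach)$sones, 0.25 * sum(n))
})

test_that("1-kHz tones are assigned their physical level as loudness level", {
  teach <- test_teacher()
  for (L in seq(20, 100, by = 10)) {
    ph <- teacher_phons(teach, tone_spectrum(1000, L)[, 1])
    expect_equal(ph, L, tolerance = 0.5)
  }
})

test_that("loudness level grows monotonically with level at fixed shape", {
  teach <- test_teacher()
  base <- tone_spectrum(2000, 60)[, 1]
  phons <- sapply(seq(-40, 40, by = 10), function(g) {
    teacher_phons(teach, pmax(base + g, -30))
  })
  expect_true(all(diff(phons) > 0))
})

test_that("broadband noise shows spectral summation that shrinks at high level", {
  teach <- test_teacher()
  noise_phon <- function(L) {
    sig <- synthesize(sound_spec("white_noise", L, 0.3, seed = 11))
    mean(teacher_phons(teach, band_spectrum(frame_signal(sig), teach$bands)))
  }
  tone60 <- teacher_phons(teach, tone_spectrum(1000, 60)[, 1])
  expect_gt(noise_phon(60), tone60)
  excess80 <- noise_phon(80) - 80
  excess100 <- noise_phon(100) - 100
  expect_gt(excess80, excess100)
})

test_that("fixed-level noise gets louder as bandwidth grows beyond an ERB", {
  teach <- test_teacher()
  phons <- sapply(c(0.25, 1, 2, 4), function(bw) {
    sig <- synthesize(sound_spec("bandpass_noise", 60, 0.3, seed = 3,
                                 center = 1000, bandwidth_oct = bw,
                                 slope_db_oct = -3))
    mean(teacher_phons(teach, band_spectrum(frame_signal(sig), teach$bands)))
  })
  expect_true(all(diff(phons) >= 0))
})

test_that("sone/phon mapping is strictly monotone and self-inverse", {
  teach <- test_teacher()
  map <- teach$sone_phon
  expect_true(all(diff(map$sones) > 0))
  ph <- seq(1, 109, by = 1.7)
  expect_equal(sone_to_phon(phon_to_sone(ph, teach), teach), ph,
               tolerance = 1e-6)
})

test_that("smoothers hold fixed points and attack faster than they release", {
  teach <- test_teacher()
  cfg <- smoother_config()
  const <- rep(70, 4000)
  tr <- smooth_trace(const, teach, cfg)
  expect_equal(tail(tr$short_term_phon, 1), 70, tolerance = 0.1)
  expect_equal(tail(tr$long_term_phon, 1), 70, tolerance = 0.5)
  # step up then down: 90% rise is faster than decay to 10%
  step_sone <- c(rep(0, 100), rep(1, 1500), rep(0, 3000))
  st <- oracle_smooth(step_sone, cfg$attack_short, cfg$release_short)
  rise <- which(st[101:1600] >= 0.9)[1]
  fall <- which(st[1601:4600] <= 0.1)[1]
  expect_lt(rise, fall)
  # implementation agrees with the recursion oracle
  x <- abs(sin(seq(0, 20, length.out = 500))) * 3
  got <- tvlnet:::.ar_smooth_cpp(x, 0.045, 0.02)
  expect_equal(got, oracle_smooth(x, 0.045, 0.02), tolerance = 1e-12)
  expect_error(smooth_trace(numeric(0), teach), "empty")
})

test_that("long-term loudness is smoother than short-term", {
  teach <- test_teacher()
  set.seed(9)
  for (k in 1:3) {
    inst <- runif(2000, 0, 90)
    tr <- smooth_trace(inst, teach)
    expect_lte(mean(abs(diff(tr$long_term_phon))),
               mean(abs(diff(tr$short_term_phon))))
  }
})

test_that("overall loudness is the maximum of the long-term series", {
  teach <- test_teacher()
  rising <- smooth_trace(seq(0, 80, length.out = 1000), teach)
  expect_equal(overall_loudness(rising), tail(rising$long_term_phon, 1))
  const <- smooth_trace(rep(55, 3000), teach)
  expect_equal(overall_loudness(const), 55, tolerance = 0.5)
  spike <- smooth_trace(c(rep(40, 500), 95, rep(40, 500)), teach)
  expect_lt(overall_loudness(spike), 95)
  expect_equal(overall_loudness(spike), max(spike$long_term_phon))
})

test_that("smoother configuration is validated", {
  expect_error(smoother_config(attack_short = 0.01, release_short = 0.02),
               "attack")
  expect_error(smoother_config(attack_long = 1.5), "in \\(0, 1\\)")
})
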