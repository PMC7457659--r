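# tvlnet

Perceived loudness is not sound pressure level: the auditory system filters
sound through the outer and middle ear, splits it across cochlear channels,
compresses each channel, and integrates the result over frequency and time.
The time-varying loudness (TVL) model of Glasberg and Moore captures this
chain and emits an "instantaneous loudness" every millisecond, smoothed
into short-term (word-level) and long-term (sentence-level) loudness — but
its excitation-pattern stage is far too slow for real-time metering.

`tvlnet` is an R toolkit for *distilling* that model into a fast surrogate:

* a **reference teacher** — the TVL stages driven by a 61-band short-term
  spectrum: outer/middle-ear transfer, level-dependent rounded-exponential
  (roex) auditory filters on the ERB_N (Cam) scale (150 channels, Cams
  1.75–39 in 0.25 steps), compressive specific loudness
  `N' = C[(G·E + A)^α − A^α]`, loudness summation, and a 1-kHz
  self-calibration so a 1-kHz tone at L dB SPL is assigned L phons;
* a calibrated **16-kHz spectral front-end** (1024-point DFT, Hann window,
  one bin per band up to 0.2 kHz then 1/9th-octave bands, 61 bands total);
* seeded **synthetic-sound generators** (tones 15–110 dB SPL with optional
  white/pink background noise, bandpass and notched noises with variable
  bandwidth, notch width and spectral slope, and a speech-like surrogate)
  plus corpus builders that label every spectrum with the teacher;
* a **student network** — a 61→150→150→150→1 rectified-linear perceptron
  trained with Adam to emit instantaneous loudness level in phons, over
  100× cheaper per frame than the teacher;
* an **evaluation suite**: five error measures (RMS, mean absolute, 99th
  percentile, maximum, bias), bias-corrected A-weighted SPL and
  stationary-loudness-from-average-spectrum baselines, cross-training
  matrices, and 1-ms loudness traces with attack/release smoothing.

## Worked example

```r
library(tvlnet)

teacher <- tvl_teacher()           # builds bands + 1-kHz calibration

# phon identity: a 1-kHz tone at 60 dB SPL is 60 phons by definition
tone <- synthesize(sound_spec("tone", 60, duration = 1, seed = 1,
                              frequency = 1000))
spectra <- band_spectrum(frame_signal(tone, hop = 16), teacher$bands)
trace <- smooth_trace(teacher_phons(teacher, spectra), teacher,
                      times = attr(spectra, "frame_time"))
overall_loudness(trace)
#> [1] 59.99846

# spectral loudness summation: equal-level white noise is much louder
noise <- synthesize(sound_spec("white_noise", 60, duration = 1, seed = 2))
sp_n <- band_spectrum(frame_signal(noise, hop = 16), teacher$bands)
mean(teacher_phons(teacher, sp_n))
#> [1] 81.4529

# distil a small student and check it against the teacher
ds <- build_corpus(manifest_tones_noises(3000, seed = 3), teacher)
fit <- train_mlp(ds, train_config(epochs = 500, seed = 3))
val <- ds$split == "validation"
sqrt(mean((mlp_forward(fit$params, ds$inputs[val, ]) - ds$labels[val])^2))
#> [1] 5.073093     # shrinks steeply as the corpus grows; see the vignette
```

The first number is the maximum long-term loudness of the tone (the phon
identity holds to well under 0.5 phons); the second shows ~21 phons of
spectral summation for broadband noise at the same SPL; the third is the
held-out distillation error in phons of a deliberately tiny 3k-row student.

A shell pipeline (generate → train → analyze → evaluate) is provided at
`inst/scripts/tvlnet`; configuration is YAML (see `?read_run_config`).

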