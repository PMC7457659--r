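# Shared fixtures, memoised so expensive objects are built once per run.

.fixtures <- new.env()

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

test_bands <- function() fixture("bands", function() {
  design_bands(1024, 16000, 8000)
})

test_teacher <- function() fixture("teacher", function() {
  tvl_teacher(test_bands())
})

# steady banded spectrum of a pure tone, via the front-end
tone_spectrum <- function(freq, level, seed = 1) {
  sig <- synthesize(sound_spec("tone", level, 0.2, seed, frequency = freq))
  band_spectrum(frame_signal(sig), test_bands())
}

# independent R oracle for the MLP forward pass: explicit per-unit loops,
# no matrix algebra shared with the implementation
oracle_forward <- function(params, x) {
  h <- as.numeric(x)
  for (l in seq_along(params$weights)) {
    W <- params$weights[[l]]
    z <- numeric(ncol(W))
    for (j in seq_len(ncol(W))) {
      s <- params$biases[[l]][j]
      for (i in seq_len(nrow(W))) s <- s + h[i] * W[i, j]
      z[j] <- s
    }
    h <- if (params$activations[l] == "relu") ifelse(z > 0, z, 0) else z
  }
  h
}

# independent R oracle for the asymmetric one-pole smoother
oracle_smooth <- function(x, a_attack, a_release) {
  s <- 0
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    a <- if (x[i] > s) a_attack else a_release
    s <- s + a * (x[i] - s)
    out[i] <- s
  }
  out
}

# independent excitation oracle for a single spectrum: direct roex
# filter-bank evaluation written separately from the compiled kernel
oracle_excitation <- function(levels, teacher) {
  ch <- teacher$channels
  comp_f <- teacher$bands$bands$center_hz
  sapply(seq_along(ch$fc), function(i) {
    fc <- ch$fc[i]
    e <- 0
    for (j in seq_along(comp_f)) {
      L <- levels[j]
      if (L <= teacher$floor_db) next
      g <- min(abs(comp_f[j] - fc) / fc, 4)
      p <- if (comp_f[j] >= fc) ch$p51[i] else {
        max(0.1, ch$p51[i] * (1 - 0.35 * (L - 51) / ch$p51_1k))
      }
      e <- e + (1 + p * g) * exp(-p * g) * 10^(L / 10)
    }
    if (e > 1e-10) 10 * log10(e) else -100
  })
}
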