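#' Error report between two phon series
#'
#' The five error measures used throughout the assessment tables:
#' root-mean-square error, mean absolute error, 99th percentile of the
#' absolute error (linear interpolation between order statistics), maximum
#' absolute error, and prediction bias (mean of prediction minus
#' reference). All in phons.
#'
#' @param pred predicted loudness levels (phons).
#' @param ref reference loudness levels (phons), same length.
#' @return an object of class `error_report`: named list with `rms`,
#'   `mean_absolute`, `p99_absolute`, `max_absolute`, `bias`, `n`.
#' @export
error_report <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("pred and ref lengths differ")
  if (length(pred) < 1) stop("empty series")
  d <- pred - ref
  structure(list(
    rms = sqrt(mean(d^2)),
    mean_absolute = mean(abs(d)),
    p99_absolute = unname(quantile(abs(d), 0.99, type = 7)),
    max_absolute = max(abs(d)),
    bias = mean(d),
    n = length(d)
  ), class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "error_report (n=%d): rms %.3f, mean |e| %.3f, p99 |e| %.3f, max |e| %.3f, bias %+.3f phons\n",
    x$n, x$rms, x$mean_absolute, x$p99_absolute, x$max_absolute, x$bias))
  invisible(x)
}

#' @export
as.data.frame.error_report <- function(x, ...) {
  data.frame(rms = x$rms, mean_absolute = x$mean_absolute,
             p99_absolute = x$p99_absolute, max_absolute = x$max_absolute,
             bias = x$bias)
}

#' Standard A-weighting gain
#'
#' Evaluates the analytic A-weighting transfer magnitude (the sound-level-
#' meter standard's pole formula), normalised to 0 dB at 1 kHz.
#'
#' @param f frequency in Hz.
#' @return weighting in dB (vectorised).
#' @export
a_weighting_db <- function(f) {
  f2 <- f^2
  ra <- (12194^2 * f2^2) /
    ((f2 + 20.6^2) * sqrt((f2 + 107.7^2) * (f2 + 737.9^2)) * (f2 + 12194^2))
  ra1k <- (12194^2 * 1000^4) /
    ((1000^2 + 20.6^2) * sqrt((1000^2 + 107.7^2) * (1000^2 + 737.9^2)) *
       (1000^2 + 12194^2))
  20 * log10(ra) - 20 * log10(ra1k)
}

#' A-weighted level of band spectra
#'
#' Applies the A-weighting curve at the band centres and power-sums across
#' bands: the conventional cheap loudness proxy against which the student
#' is compared.
#'
#' @param spectrum 61 x n matrix (or vector) of band levels in dB SPL.
#' @param bands the [design_bands()] definition the spectra were computed
#'   with.
#' @param floor_db bands at or below this level are ignored.
#' @return numeric vector of A-weighted levels in dBA (one per frame).
#' @export
a_weighted_level <- function(spectrum, bands, floor_db = -30) {
  stopifnot(inherits(bands, "band_definition"))
  if (is.null(dim(spectrum))) spectrum <- matrix(spectrum, ncol = 1)
  if (nrow(spectrum) != nrow(bands$bands)) {
    stop("spectrum rows do not match the band definition")
  }
  wdb <- a_weighting_db(bands$bands$center_hz)
  p <- 10^((spectrum + wdb) / 10)
  p[spectrum <= floor_db] <- 0
  10 * log10(pmax(colSums(p), 1e-30))
}

#' Baseline error reports on a labelled dataset
#'
#' `tag = "a_weighted"`: predicts each row's loudness level by its
#' bias-corrected A-weighted SPL (the mean difference between dBA and the
#' teacher label over the set is subtracted before computing the errors).
#' `tag = "stationary_average_spectrum"`: re-synthesizes each sound in the
#' dataset's manifest, power-averages its band spectra over time, runs the
#' teacher once on the average spectrum, and compares against the overall
#' loudness (maximum long-term loudness of the 1-ms teacher trace) of the
#' time-varying run. `tag = "student_dnn"` scores a trained student's
#' per-row predictions.
#'
#' @param test a `labelled_dataset` from [build_corpus()].
#' @param tag one of `"a_weighted"`, `"stationary_average_spectrum"`,
#'   `"student_dnn"`.
#' @param teacher the [tvl_teacher()] that labelled the dataset.
#' @param params trained [init_params()] object (required for
#'   `"student_dnn"`).
#' @param max_sounds cap on the number of sounds re-synthesized for the
#'   stationary baseline.
#' @return an [error_report()].
#' @export
baseline_error <- function(test, tag, teacher = NULL, params = NULL,
                           max_sounds = 50) {
  stopifnot(inherits(test, "labelled_dataset"))
  tag <- match.arg(tag, c("a_weighted", "stationary_average_spectrum",
                          "student_dnn"))
  if (tag == "a_weighted") {
    stopifnot(inherits(teacher, "tvl_teacher"))
    dba <- a_weighted_level(t(test$inputs), teacher$bands,
                            teacher$floor_db)
    bias <- mean(dba - test$labels)
    return(error_report(dba - bias, test$labels))
  }
  if (tag == "student_dnn") {
    stopifnot(inherits(params, "mlp_params"))
    return(error_report(mlp_forward(params, test$inputs), test$labels))
  }
  # stationary baseline: teacher on the power-averaged spectrum per sound
  stopifnot(inherits(teacher, "tvl_teacher"))
  manifest <- test$manifest
  if (is.null(manifest)) stop("dataset has no manifest; cannot re-synthesize")
  ids <- unique(test$sound_id)
  if (length(ids) > max_sounds) ids <- ids[seq_len(max_sounds)]
  stat_phon <- numeric(length(ids))
  overall <- numeric(length(ids))
  for (k in seq_along(ids)) {
    sig <- synthesize(manifest$specs[[ids[k]]],
                      calibration = teacher$calibration)
    frames <- frame_signal(sig, teacher$bands$dft_size, 16)
    spectra <- band_spectrum(frames, teacher$bands, teacher$calibration,
                             teacher$floor_db)
    avg <- 10 * log10(rowMeans(10^(spectra / 10)))
    avg <- pmax(avg, teacher$floor_db)
    stat_phon[k] <- teacher_phons(teacher, avg)
    trace <- smooth_trace(teacher_phons(teacher, spectra), teacher,
                          times = attr(spectra, "frame_time"))
    overall[k] <- overall_loudness(trace)
  }
  error_report(stat_phon, overall)
}

#' Compare student and teacher loudness traces
#'
#' Runs both engines at the 1-ms hop on each sound, applies the identical
#' attack/release smoothing to both instantaneous series, and reports the
#' five error measures for instantaneous, short-term, long-term (pooled
#' over all time points of all sounds) and overall loudness (one value per
#' sound).
#'
#' @param params trained [init_params()] object (the student).
#' @param sounds list of [audio_signal()] objects at 16 kHz.
#' @param teacher a [tvl_teacher()].
#' @param cfg a [smoother_config()].
#' @return a list of [error_report()]s: `instantaneous`, `short_term`,
#'   `long_term`, `overall`.
#' @export
trace_errors <- function(params, sounds, teacher, cfg = smoother_config()) {
  stopifnot(inherits(params, "mlp_params"), inherits(teacher, "tvl_teacher"),
            length(sounds) >= 1)
  acc <- list(inst = list(), st = list(), lt = list())
  ov_pred <- numeric(length(sounds))
  ov_ref <- numeric(length(sounds))
  for (k in seq_along(sounds)) {
    frames <- frame_signal(sounds[[k]], teacher$bands$dft_size, 16)
    spectra <- band_spectrum(frames, teacher$bands, teacher$calibration,
                             teacher$floor_db)
    ref_inst <- teacher_phons(teacher, spectra)
    pred_inst <- mlp_forward(params, t(spectra))
    ref_tr <- smooth_trace(ref_inst, teacher, cfg)
    pred_tr <- smooth_trace(pred_inst, teacher, cfg)
    acc$inst[[k]] <- cbind(pred_tr$instantaneous_phon,
                           ref_tr$instantaneous_phon)
    acc$st[[k]] <- cbind(pred_tr$short_term_phon, ref_tr$short_term_phon)
    acc$lt[[k]] <- cbind(pred_tr$long_term_phon, ref_tr$long_term_phon)
    ov_pred[k] <- overall_loudness(pred_tr)
    ov_ref[k] <- overall_loudness(ref_tr)
  }
  pool <- function(l) do.call(rbind, l)
  inst <- pool(acc$inst); st <- pool(acc$st); lt <- pool(acc$lt)
  list(
    instantaneous = error_report(inst[, 1], inst[, 2]),
    short_term = error_report(st[, 1], st[, 2]),
    long_term = error_report(lt[, 1], lt[, 2]),
    overall = error_report(ov_pred, ov_ref)
  )
}

#' Write a table of error reports as CSV
#'
#' Rows are report names, columns the five error measures.
#'
#' @param reports named list of [error_report()]s.
#' @param path output path.
#' @param hash optional configuration hash embedded as a comment line.
#' @export
write_report_csv <- function(reports, path, hash = NULL) {
  df <- do.call(rbind, lapply(reports, as.data.frame))
  df <- cbind(data.frame(set = names(reports)), df)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(sprintf("# config_hash: %s", hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}
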