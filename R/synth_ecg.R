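#' Construct a raw single-lead ECG record
#'
#' The unit of input for the pipeline: a 1-D sample vector with its
#' sampling rate, diagnostic label and subject/record identity.
#'
#' @param samples Finite numeric vector, length >= 1 (mV-like units).
#' @param fs Sampling rate in Hz (> 0).
#' @param label One of `mddnet_classes()`.
#' @param subject_id,record_id Opaque identifiers.
#' @param snr_db Optional noise annotation in dB (`Inf` = clean).
#' @return Object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, label, subject_id, record_id,
                       snr_db = Inf) {
  if (length(samples) < 1 || !all(is.finite(samples)))
    stop("`samples` must be a non-empty finite vector", call. = FALSE)
  if (!is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive sampling rate in Hz", call. = FALSE)
  label <- match.arg(label, CLASS_LEVELS)
  structure(list(samples = as.numeric(samples), fs = fs, label = label,
                 subject_id = as.character(subject_id),
                 record_id = as.character(record_id), snr_db = snr_db),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s | %s/%s | %g Hz | %d samples (%.1f s)%s\n",
              x$label, x$subject_id, x$record_id, x$fs, length(x$samples),
              length(x$samples) / x$fs,
              if (is.finite(x$snr_db)) sprintf(" | SNR %g dB", x$snr_db) else ""))
  invisible(x)
}

#' Per-class beat morphology templates
#'
#' Each beat is a sum of Gaussian bumps (P, Q, R, S, T waves) on a
#' quasi-periodic grid, with an optional smooth ST-segment plateau.  The
#' class templates encode the qualitative diagnostic cues of the four
#' categories: myocardial infarction carries an ST-segment shift, coronary
#' artery disease an inverted T wave with mild ST depression, and
#' congestive heart failure a low-amplitude QRS complex.  Normal is the
#' unmodified template.
#'
#' @param label One of `mddnet_classes()`.
#' @param beat_rate Beats per minute (> 0).
#' @param st_offset ST-segment shift as a fraction of the R amplitude
#'   (positive = elevation).
#' @param t_scale T-wave amplitude multiplier (negative inverts).
#' @param qrs_atten Multiplier on Q/R/S amplitudes in (0, 1]; values
#'   below 1 model the low-amplitude QRS of heart failure.
#' @param jitter Beat-to-beat timing/amplitude jitter scale (>= 0,
#'   relative units).
#' @return Object of class `morphology_config`.
#' @export
morphology_config <- function(label = "Normal", beat_rate = 60,
                              st_offset = 0, t_scale = 1, qrs_atten = 1,
                              jitter = 0.03) {
  if (!is.finite(beat_rate) || beat_rate <= 0)
    stop("`beat_rate` must be > 0", call. = FALSE)
  if (!is.finite(jitter) || jitter < 0)
    stop("`jitter` must be >= 0", call. = FALSE)
  structure(list(label = label, beat_rate = beat_rate, st_offset = st_offset,
                 t_scale = t_scale, qrs_atten = qrs_atten, jitter = jitter),
            class = "morphology_config")
}

#' @rdname morphology_config
#' @export
default_morphology <- function(label) {
  label <- match.arg(label, CLASS_LEVELS)
  switch(label,
    Normal = morphology_config("Normal"),
    MI     = morphology_config("MI", st_offset = 0.25, t_scale = 1.2),
    CAD    = morphology_config("CAD", st_offset = -0.08, t_scale = -0.9),
    CHF    = morphology_config("CHF", beat_rate = 85, qrs_atten = 0.45,
                               t_scale = 0.9)
  )
}

# One beat evaluated at phase u in [0, 1): Gaussian bumps for P, Q, R, S, T
# plus a raised-cosine ST plateau between the S and T waves.
beat_waveform <- function(u, amp, st_offset, t_scale, qrs_atten) {
  g <- function(centre, width, a) a * exp(-0.5 * ((u - centre) / width)^2)
  y <- g(0.18, 0.025, 0.15 * amp[1]) +                     # P
    qrs_atten * (g(0.355, 0.009, -0.12 * amp[2]) +         # Q
                 g(0.375, 0.011, 1.00 * amp[3]) +          # R
                 g(0.395, 0.009, -0.22 * amp[4])) +        # S
    t_scale * g(0.60, 0.05, 0.35 * amp[5])                 # T
  if (st_offset != 0) {
    # smooth plateau over the ST interval [0.41, 0.56]
    w <- rep(0, length(u))
    inside <- u >= 0.41 & u <= 0.56
    w[inside] <- 0.5 * (1 - cos(2 * pi * (u[inside] - 0.41) / 0.15))
    y <- y + st_offset * qrs_atten * w
  }
  y
}

#' Generate one synthetic ECG-like record
#'
#' Emits `round(fs * duration_s)` samples of a quasi-periodic waveform
#' with class-dependent morphology and small beat-to-beat jitter, plus a
#' low-amplitude baseline wander.  Output is fully determined by the
#' arguments: the same call always returns the identical vector.
#'
#' @param label Class label; chooses the default morphology.
#' @param fs Sampling rate in Hz (defaults used in this package:
#'   250, 257 and 1000).
#' @param duration_s Record duration in seconds (> 0).
#' @param morphology A [morphology_config()]; defaults to the class
#'   template.
#' @param seed Integer seed controlling jitter and wander.
#' @param subject_id,record_id Identity attached to the record.
#' @return An [ecg_record()].
#' @examples
#' r <- make_record("Normal", fs = 250, duration_s = 30, seed = 1)
#' length(r$samples)  # 7500
#' @export
make_record <- function(label, fs, duration_s,
                        morphology = default_morphology(label), seed = 1L,
                        subject_id = "S1", record_id = "R1") {
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("`duration_s` must be > 0", call. = FALSE)
  if (!is.finite(fs) || fs <= 0)
    stop("`fs` must be > 0", call. = FALSE)
  n <- as.integer(round(fs * duration_s))
  m <- morphology
  samples <- with_seed(mix_seed(seed, label, fs, n, "record"), {
    t <- (seq_len(n) - 1) / fs
    period <- 60 / m$beat_rate
    n_beats <- ceiling(duration_s / period) + 2L
    # jittered beat onsets and per-beat amplitude scales
    periods <- period * (1 + m$jitter * rnorm(n_beats, sd = 0.5))
    onsets <- cumsum(c(0, periods))
    y <- numeric(n)
    for (b in seq_len(n_beats)) {
      t0 <- onsets[b]
      span <- periods[min(b, length(periods))]
      sel <- which(t >= t0 & t < t0 + span)
      if (!length(sel)) next
      u <- (t[sel] - t0) / span
      amp <- 1 + m$jitter * rnorm(5, sd = 0.6)
      y[sel] <- y[sel] + beat_waveform(u, amp, m$st_offset, m$t_scale,
                                       m$qrs_atten)
    }
    # slow baseline wander (respiration-like)
    y + 0.03 * sin(2 * pi * 0.25 * t + runif(1, 0, 2 * pi))
  })
  ecg_record(samples, fs, label, subject_id, record_id)
}

#' Add white Gaussian noise at a target signal-to-noise ratio
#'
#' Measures the input's mean power `P = mean(x^2)` and adds zero-mean
#' Gaussian noise of variance `P / 10^(snr_db / 10)` ("measured" SNR
#' semantics).  `snr_db = Inf` returns the input unchanged.
#'
#' @param signal Non-empty finite numeric vector, or an [ecg_record()]
#'   (whose samples are replaced and `snr_db` annotated).
#' @param snr_db Target SNR in dB (finite, or `Inf` for no noise).
#' @param seed Integer seed; the same call is reproducible.
#' @return Same type as `signal`.
#' @export
add_awgn <- function(signal, snr_db, seed = 1L) {
  if (inherits(signal, "ecg_record")) {
    r <- signal
    r$samples <- add_awgn(signal$samples, snr_db,
                          mix_seed(seed, r$subject_id, r$record_id, "awgn"))
    r$snr_db <- snr_db
    return(r)
  }
  if (length(signal) == 0 || !all(is.finite(signal)))
    stop("`signal` must be non-empty and finite", call. = FALSE)
  if (is.infinite(snr_db) && snr_db > 0) return(signal)
  if (!is.finite(snr_db))
    stop("`snr_db` must be finite or +Inf", call. = FALSE)
  p <- mean(signal^2)
  if (p == 0)
    stop("SNR is undefined for an all-zero signal", call. = FALSE)
  sigma <- sqrt(p / 10^(snr_db / 10))
  with_seed(mix_seed(seed, "awgn"), signal + rnorm(length(signal), sd = sigma))
}

#' Configuration for a synthetic multi-subject dataset
#'
#' Defaults mirror the heterogeneous-rate structure of the public
#' databases the pipeline targets: Normal and MI at 1000 Hz, CAD at
#' 257 Hz and CHF at 250 Hz, several subjects per class with a few
#' records each.
#'
#' @param subjects Named integer vector: subjects per class.
#' @param records_per_subject Records generated for each subject.
#' @param fs Named numeric vector: sampling rate per class (Hz).
#' @param duration_s Record duration in seconds.
#' @return A list used by [make_dataset()].
#' @export
dataset_config <- function(subjects = c(Normal = 6L, MI = 6L, CAD = 5L, CHF = 5L),
                           records_per_subject = 2L,
                           fs = c(Normal = 1000, MI = 1000, CAD = 257, CHF = 250),
                           duration_s = 30) {
  list(subjects = subjects, records_per_subject = records_per_subject,
       fs = fs, duration_s = duration_s)
}

#' Generate a labeled multi-subject synthetic ECG dataset
#'
#' Stands in for the public ECG databases: every class gets its configured
#' number of subjects (ids distinct across classes), each subject a small
#' random morphology offset (so inter-patient generalisation is
#' non-trivial) and `records_per_subject` records at the class's sampling
#' rate.  Fully reproducible for a fixed `(config, seed)`.
#'
#' @param config A [dataset_config()].
#' @param seed Integer seed.
#' @return List of [ecg_record()]s with attribute `manifest`, a data frame
#'   of (record_id, subject_id, label, fs).
#' @export
make_dataset <- function(config = dataset_config(), seed = 1L) {
  classes <- names(config$subjects)
  if (is.null(classes) || !all(classes %in% CLASS_LEVELS))
    stop("`config$subjects` must be named with class labels", call. = FALSE)
  if (any(config$subjects < 1))
    stop(sprintf("class %s requests zero subjects",
                 paste(classes[config$subjects < 1], collapse = ", ")),
         call. = FALSE)
  records <- list()
  for (cl in classes) {
    fs <- config$fs[[cl]]
    for (s in seq_len(config$subjects[[cl]])) {
      subject_id <- sprintf("%s-%02d", cl, s)
      # subject-specific morphology offset
      base <- default_morphology(cl)
      off <- with_seed(mix_seed(seed, subject_id, "subject"), {
        list(rate = rnorm(1, sd = 3), amp = rnorm(1, sd = 0.05),
             st = rnorm(1, sd = 0.02))
      })
      morph <- base
      morph$beat_rate <- max(40, base$beat_rate + off$rate)
      morph$qrs_atten <- base$qrs_atten * (1 + off$amp)
      morph$st_offset <- base$st_offset + off$st
      for (r in seq_len(config$records_per_subject)) {
        record_id <- sprintf("%s-r%02d", subject_id, r)
        rec <- make_record(cl, fs, config$duration_s, morph,
                           seed = mix_seed(seed, record_id),
                           subject_id = subject_id, record_id = record_id)
        records[[length(records) + 1L]] <- rec
      }
    }
  }
  manifest <- data.frame(
    record_id = vapply(records, `[[`, "", "record_id"),
    subject_id = vapply(records, `[[`, "", "subject_id"),
    label = vapply(records, `[[`, "", "label"),
    fs = vapply(records, `[[`, 0, "fs"),
    stringsAsFactors = FALSE
  )
  attr(records, "manifest") <- manifest
  records
}
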