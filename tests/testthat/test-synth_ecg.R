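test_that("record generation honours length arithmetic and determinism", {
  r <- make_record("Normal", fs = 250, duration_s = 30, seed = 1)
  expect_length(r$samples, 7500L)
  expect_identical(r$samples,
                   make_record("Normal", 250, 30, seed = 1)$samples)
  expect_false(identical(r$samples,
                         make_record("Normal", 250, 30, seed = 2)$samples))
  expect_error(make_record("Normal", 250, 0, seed = 1), "duration")
  expect_error(make_record("Normal", -1, 10, seed = 1), "fs")
})

test_that("QRS attenuation caps the heart-failure template amplitude", {
  chf <- make_record("CHF", 1000, 10,
                     morphology_config("CHF", qrs_atten = 0.5), seed = 7)
  nor <- make_record("Normal", 1000, 10, seed = 7)
  # R-peak magnitude about the baseline
  peak <- function(r) max(abs(r$samples - stats::median(r$samples)))
  expect_lte(peak(chf), 0.6 * peak(nor))
})

test_that("class templates carry their diagnostic cues", {
  t_of <- function(label) {
    r <- make_record(label, 1000, 10, morphology_config(
      label,
      st_offset = default_morphology(label)$st_offset,
      t_scale = default_morphology(label)$t_scale,
      qrs_atten = default_morphology(label)$qrs_atten,
      jitter = 0), seed = 3)
    r$samples
  }
  nor <- t_of("Normal"); mi <- t_of("MI"); cad <- t_of("CAD")
  # ST interval (0.41-0.56 of the first one-second beat) is elevated for MI
  st_win <- 411:559
  expect_gt(mean(mi[st_win]) - mean(nor[st_win]), 0.1)
  # CAD T wave (around 0.60 of the beat) is inverted
  t_win <- 570:640
  expect_lt(min(cad[t_win]), -0.15)
  expect_gt(max(nor[t_win]), 0.15)
})

test_that("white-noise injection realises the target SNR", {
  set.seed(4)
  x <- rnorm(1e5)  # approximately unit power
  noisy <- add_awgn(x, 0, seed = 3)
  noise <- noisy - x
  expect_lt(abs(mean(noise^2) - mean(x^2)) / mean(x^2), 0.05)
  noisy12 <- add_awgn(x, 12, seed = 3)
  realized <- 10 * log10(mean(x^2) / mean((noisy12 - x)^2))
  expect_lt(abs(realized - 12), 0.5)
  # no-noise limit and determinism
  expect_identical(add_awgn(x, Inf), x)
  expect_identical(add_awgn(x, 6, seed = 9), add_awgn(x, 6, seed = 9))
  expect_error(add_awgn(rep(0, 10), 6), "all-zero")
})

test_that("dataset generation books subjects, records and rates correctly", {
  cfg <- dataset_config(subjects = c(Normal = 4L), records_per_subject = 2L,
                        fs = c(Normal = 1000), duration_s = 5)
  ds <- make_dataset(cfg, seed = 1)
  expect_length(ds, 8)
  expect_length(unique(vapply(ds, `[[`, "", "subject_id")), 4)
  # heterogeneous default rates per class
  ds2 <- make_dataset(dataset_config(
    subjects = c(Normal = 1L, MI = 1L, CAD = 1L, CHF = 1L),
    records_per_subject = 1L, duration_s = 5), seed = 1)
  fs <- vapply(ds2, `[[`, 0, "fs")
  names(fs) <- vapply(ds2, `[[`, "", "label")
  expect_equal(fs[["CAD"]], 257)
  expect_equal(fs[["CHF"]], 250)
  expect_equal(fs[["Normal"]], 1000)
  expect_equal(fs[["MI"]], 1000)
  # seed contract
  dsA <- make_dataset(cfg, seed = 1)
  dsB <- make_dataset(cfg, seed = 2)
  expect_identical(ds[[1]]$samples, dsA[[1]]$samples)
  expect_false(identical(dsA[[1]]$samples, dsB[[1]]$samples))
  expect_length(dsB[[1]]$samples, length(dsA[[1]]$samples))
  expect_error(make_dataset(dataset_config(subjects = c(Normal = 0L))),
               "zero subjects")
})

test_that("a template-correlation classifier separates the clean classes", {
  # sanity floor: with default morphologies and no noise, nearest-template
  # correlation on segment images must be nearly perfect, so downstream
  # learning tests are meaningful
  ds <- make_dataset(dataset_config(
    subjects = c(Normal = 3L, MI = 3L, CAD = 3L, CHF = 3L),
    records_per_subject = 1L, duration_s = 12), seed = 33)
  segs <- segment_records(ds)
  labs <- vapply(segs, `[[`, "", "label")
  vecs <- t(vapply(segs, function(s) as.vector(t(s$matrix)), numeric(3000)))
  vecs <- vecs - rowMeans(vecs)
  centroids <- sapply(mddnet_classes(), function(cl)
    colMeans(vecs[labs == cl, , drop = FALSE]))
  # matched filter: correlation maximised over circular lags (beats are
  # not phase-aligned across segments)
  xcmax <- function(a, b) {
    cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
    max(cc) / sqrt(sum(a^2) * sum(b^2))
  }
  pred <- mddnet_classes()[apply(vecs, 1, function(v)
    which.max(vapply(1:4, function(k) xcmax(v, centroids[, k]), 0)))]
  expect_gt(mean(pred == labs), 0.9)
})
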