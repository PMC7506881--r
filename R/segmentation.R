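#' Plan fixed-duration overlapping segmentation at a native sampling rate
#'
#' Computes the segment and overlap lengths of the adaptive
#' sample-frequency segmentation (ASFS) scheme.  A segment spans `n_cyc`
#' nominal cardiac cycles; at a native rate `f_cur` its length in samples
#' is `Ls = floor(f_cur * n_cyc)` and the overlap between consecutive
#' segments is `Lo = ceiling(Ls * overlap_rate)`.  `n_cyc` is
#' seconds-equivalent: one "cycle" is the nominal one-second beat period
#' of a 60 bpm rhythm, so `Ls` is also `n_cyc` seconds of signal.
#'
#' @param f_cur Native sampling rate in Hz (> 0).
#' @param n_cyc Cycles (seconds-equivalent) per segment, >= 1. Default 3.
#' @param overlap_rate Fraction of a segment shared with its successor,
#'   in `[0, 1)`. Default 0.1.
#' @return An object of class `segment_plan` with fields `ls`, `lo`,
#'   `f_cur`, `n_cyc`, `overlap_rate`.
#' @examples
#' segment_plan(1000, 3, 0.1)  # ls = 3000, lo = 300
#' @export
segment_plan <- function(f_cur, n_cyc = 3, overlap_rate = 0.1) {
  if (!is.finite(f_cur) || f_cur <= 0)
    stop("`f_cur` must be a positive rate in Hz", call. = FALSE)
  if (!is.finite(n_cyc) || n_cyc < 1)
    stop("`n_cyc` must be >= 1", call. = FALSE)
  if (!is.finite(overlap_rate) || overlap_rate < 0 || overlap_rate >= 1)
    stop("`overlap_rate` must lie in [0, 1): the extraction loop would not advance",
         call. = FALSE)
  ls <- as.integer(floor(f_cur * n_cyc))
  lo <- as.integer(ceiling(ls * overlap_rate))
  structure(list(ls = ls, lo = lo, f_cur = f_cur, n_cyc = n_cyc,
                 overlap_rate = overlap_rate),
            class = "segment_plan")
}

#' Resample a segment to a target rate
#'
#' Rate conversion by natural cubic-spline interpolation on the segment's
#' time grid.  The output length is the binding contract:
#' `round(length(seg) * f_max / f_cur)` samples spanning the same
#' duration.  Equal rates return the input untouched; constant segments
#' are reproduced exactly (DC preservation).
#'
#' @param seg Numeric vector (non-empty).
#' @param f_cur Native rate in Hz.
#' @param f_max Target rate in Hz.
#' @return Numeric vector of `round(length(seg) * f_max / f_cur)` samples.
#' @export
resample_segment <- function(seg, f_cur, f_max) {
  if (length(seg) == 0)
    stop("`seg` must be non-empty", call. = FALSE)
  if (!is.finite(f_cur) || f_cur <= 0 || !is.finite(f_max) || f_max <= 0)
    stop("rates must be positive", call. = FALSE)
  if (f_cur == f_max) return(seg)
  n_out <- as.integer(round(length(seg) * f_max / f_cur))
  if (length(seg) == 1L) return(rep(seg, n_out))
  t_in <- (seq_along(seg) - 1) / f_cur
  t_out <- (seq_len(n_out) - 1) / f_max
  f <- splinefun(t_in, seg, method = "natural")
  f(t_out)
}

#' Min-max normalize a segment to [0, 1]
#'
#' @param seg Finite numeric vector.
#' @return Vector scaled so min is 0 and max is 1; a constant segment
#'   (degenerate range) maps to all zeros.
#' @export
normalize_segment <- function(seg) {
  if (!all(is.finite(seg)))
    stop("`seg` must be finite", call. = FALSE)
  r <- range(seg)
  if (r[1] == r[2]) return(rep(0, length(seg)))
  (seg - r[1]) / (r[2] - r[1])
}

#' Fold a 1-D segment into a 2-D matrix (segment image)
#'
#' Row-major fold: element `(r, c)` of the matrix is sample
#' `(r - 1) * cols + c` of the vector, so consecutive samples run along
#' matrix rows.  The default 60 x 50 shape holds a 3000-sample segment.
#'
#' @param vec Numeric vector of exactly `rows * cols` samples.
#' @param rows,cols Matrix shape.
#' @return `rows` x `cols` numeric matrix.
#' @export
fold_segment <- function(vec, rows = 60L, cols = 50L) {
  if (length(vec) != rows * cols)
    stop(sprintf("segment has %d samples; need exactly rows * cols = %d",
                 length(vec), rows * cols), call. = FALSE)
  matrix(vec, nrow = rows, ncol = cols, byrow = TRUE)
}

# Inverse of fold_segment (row-major flatten); round-trip identity.
unfold_segment <- function(m) as.vector(t(m))

#' Adaptive sample-frequency segmentation of a raw ECG record
#'
#' Cuts a raw record into fixed-duration overlapping segments without any
#' denoising or R-peak detection: repeatedly take the leading `ls` native
#' samples, resample them to `f_max`, min-max normalize, fold into a 2-D
#' segment image, then advance by `ls - lo` samples; stop when fewer than
#' `ls` samples remain.  Records shorter than one segment yield an empty
#' list.  The emitted segment count is
#' `1 + floor((Le - ls) / (ls - lo))` for a record of `Le >= ls` samples,
#' and every segment image has the same shape regardless of the native
#' rate.
#'
#' @param record An [ecg_record()].
#' @param plan A [segment_plan()] whose `f_cur` matches `record$fs`; by
#'   default built from the record's rate.
#' @param f_max Common target rate in Hz (default 1000).
#' @param rows Rows of the folded segment image (default 60); columns are
#'   inferred as `n_resampled / rows`, which must be an integer.
#' @return List of `segment_matrix` objects: each carries `matrix`,
#'   `label`, `subject_id`, `record_id`, `segment_index` and the record's
#'   `snr_db` annotation (if any).
#' @export
asfs_extract <- function(record, plan = NULL, f_max = 1000, rows = 60L) {
  stopifnot(inherits(record, "ecg_record"))
  if (is.null(plan)) plan <- segment_plan(record$fs)
  if (!inherits(plan, "segment_plan"))
    stop("`plan` must be a segment_plan", call. = FALSE)
  if (plan$f_cur != record$fs)
    stop(sprintf("plan rate (%g Hz) does not match record rate (%g Hz)",
                 plan$f_cur, record$fs), call. = FALSE)
  ls <- plan$ls; lo <- plan$lo
  n_rs <- as.integer(round(ls * f_max / plan$f_cur))
  if (n_rs %% rows != 0L)
    stop(sprintf("resampled length %d is not divisible by rows = %d",
                 n_rs, rows), call. = FALSE)
  cols <- n_rs %/% rows
  ve <- record$samples
  out <- list()
  idx <- 0L
  while (length(ve) >= ls) {
    seg <- ve[seq_len(ls)]
    seg <- resample_segment(seg, plan$f_cur, f_max)
    seg <- normalize_segment(seg)
    idx <- idx + 1L
    out[[idx]] <- structure(list(
      matrix = fold_segment(seg, rows, cols),
      label = record$label,
      subject_id = record$subject_id,
      record_id = record$record_id,
      segment_index = idx,
      snr_db = record$snr_db %||% Inf
    ), class = "segment_matrix")
    ve <- ve[-seq_len(min(ls - lo, length(ve)))]
  }
  out
}
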