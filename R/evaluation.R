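#' Build a confusion matrix
#'
#' Rows are true classes, columns predicted classes, in the order given
#' by `classes`.
#'
#' @param true,predicted Label vectors of equal length (values from
#'   `classes`, or integer indices into it).
#' @param classes Ordered class names (default [mddnet_classes()]).
#' @return Integer `K x K` matrix with class dimnames.
#' @export
confusion_matrix <- function(true, predicted, classes = mddnet_classes()) {
  if (length(true) != length(predicted))
    stop("`true` and `predicted` must have equal length", call. = FALSE)
  to_idx <- function(v) {
    if (is.numeric(v)) {
      if (any(v < 1 | v > length(classes)))
        stop("label index out of range", call. = FALSE)
      as.integer(v)
    } else {
      i <- match(as.character(v), classes)
      if (anyNA(i))
        stop("label not in `classes`", call. = FALSE)
      i
    }
  }
  ti <- to_idx(true); pi <- to_idx(predicted)
  k <- length(classes)
  cm <- matrix(0L, k, k, dimnames = list(true = classes, predicted = classes))
  for (j in seq_along(ti)) cm[ti[j], pi[j]] <- cm[ti[j], pi[j]] + 1L
  cm
}

# One-vs-rest tallies for class c of a confusion matrix.
ovr_counts <- function(cm, c) {
  tp <- cm[c, c]
  fn <- sum(cm[c, ]) - tp
  fp <- sum(cm[, c]) - tp
  tn <- sum(cm) - tp - fn - fp
  list(tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Per-class one-vs-rest metrics (percent)
#'
#' For each class: accuracy `ACC = (TP+TN)/total`, positive predictive
#' value `PPV = TP/(TP+FP)`, sensitivity `SEN = TP/(TP+FN)` and
#' specificity `SPE = TN/(TN+FP)`, all as percentages.  Values are
#' returned unrounded; report-time rounding is half-away-from-zero to
#' two decimals (see [format.metrics_report()]).  A class with no true
#' samples yields `NA` (undefined), never zero.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return Data frame with columns `class`, `ACC`, `PPV`, `SEN`, `SPE`.
#' @export
per_class_metrics <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  classes <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  res <- lapply(seq_len(nrow(cm)), function(c) {
    o <- ovr_counts(cm, c)
    if (o$tp + o$fn == 0)
      return(data.frame(class = classes[c], ACC = NA_real_, PPV = NA_real_,
                        SEN = NA_real_, SPE = NA_real_))
    data.frame(
      class = classes[c],
      ACC = 100 * (o$tp + o$tn) / (o$tp + o$fp + o$tn + o$fn),
      PPV = if (o$tp + o$fp > 0) 100 * o$tp / (o$tp + o$fp) else NA_real_,
      SEN = 100 * o$tp / (o$tp + o$fn),
      SPE = 100 * o$tn / (o$tn + o$fp)
    )
  })
  do.call(rbind, res)
}

#' Macro-averaged metrics
#'
#' Arithmetic mean of the *unrounded* per-class values; rounding to two
#' decimals happens only at report time.  Undefined per-class metrics
#' propagate to an undefined average.
#'
#' @param cm Confusion matrix.
#' @return Named numeric vector `ACC`, `PPV`, `SEN`, `SPE` (percent).
#' @export
macro_metrics <- function(cm) {
  pc <- per_class_metrics(cm)
  c(ACC = mean(pc$ACC), PPV = mean(pc$PPV),
    SEN = mean(pc$SEN), SPE = mean(pc$SPE))
}

#' Overall accuracy (percent)
#'
#' Correctly classified instances over all instances.
#'
#' @param cm Confusion matrix.
#' @export
overall_accuracy <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  100 * sum(diag(cm)) / sum(cm)
}

#' Full metrics report for a confusion matrix
#'
#' @param cm Confusion matrix.
#' @return Object of class `metrics_report`: list with `confusion`,
#'   `per_class` (unrounded data frame), `macro` (unrounded named
#'   vector) and `overall_accuracy`.
#' @export
metrics_report <- function(cm) {
  structure(list(confusion = cm,
                 per_class = per_class_metrics(cm),
                 macro = macro_metrics(cm),
                 overall_accuracy = overall_accuracy(cm)),
            class = "metrics_report")
}

#' @export
format.metrics_report <- function(x, ...) {
  pc <- x$per_class
  pc[-1] <- lapply(pc[-1], round_half_up)
  mac <- round_half_up(x$macro)
  c(sprintf("Overall accuracy: %.2f%%", round_half_up(x$overall_accuracy)),
    utils::capture.output(print(cbind(pc, row.names = NULL))),
    sprintf("Average: ACC %.2f  PPV %.2f  SEN %.2f  SPE %.2f",
            mac["ACC"], mac["PPV"], mac["SEN"], mac["SPE"]))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Segment-level k-fold split (intra-patient paradigm)
#'
#' Random, nearly equal folds: sizes differ by at most one, folds
#' partition the index set, and the shuffle is fixed by the seed.
#'
#' @param n Number of segments (or a list whose length is used).
#' @param k Fold count (default 10).
#' @param seed Integer seed.
#' @return Object of class `split_plan` with `mode = "intra_10fold"` and
#'   `folds`, an integer vector of fold assignments in `1:k`.
#' @export
kfold_split <- function(n, k = 10L, seed = 1L) {
  if (is.list(n)) n <- length(n)
  if (n < k) stop("need at least k segments", call. = FALSE)
  folds <- with_seed(mix_seed(seed, "kfold"), {
    sample(rep(seq_len(k), length.out = n))
  })
  structure(list(mode = "intra_10fold", k = as.integer(k), folds = folds,
                 seed = seed),
            class = "split_plan")
}

#' Subject-disjoint train/test split (inter-patient paradigm)
#'
#' All segments of one subject land on one side; the two subject lists
#' must be disjoint and jointly cover every subject present.
#'
#' @param subject_ids Per-segment (or per-record) subject identifiers.
#' @param ds1_subjects,ds2_subjects Training (DS1) and testing (DS2)
#'   subject id vectors.
#' @return Object of class `split_plan` with `mode = "inter_patient"`,
#'   `train_idx`, `test_idx`.
#' @export
inter_patient_split <- function(subject_ids, ds1_subjects, ds2_subjects) {
  both <- intersect(ds1_subjects, ds2_subjects)
  if (length(both))
    stop(sprintf("subject(s) in both DS1 and DS2: %s",
                 paste(both, collapse = ", ")), call. = FALSE)
  unknown <- setdiff(unique(subject_ids), c(ds1_subjects, ds2_subjects))
  if (length(unknown))
    stop(sprintf("subject(s) assigned to neither set: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  structure(list(mode = "inter_patient",
                 train_idx = which(subject_ids %in% ds1_subjects),
                 test_idx = which(subject_ids %in% ds2_subjects),
                 ds1 = ds1_subjects, ds2 = ds2_subjects),
            class = "split_plan")
}
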