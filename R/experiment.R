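#' Segment a collection of records
#'
#' Applies [asfs_extract()] to every record with a per-record plan built
#' from its native rate, so heterogeneous-rate collections yield
#' identically shaped segment images.
#'
#' @param records List of [ecg_record()]s.
#' @param n_cyc,overlap_rate,f_max Segmentation parameters (see
#'   [segment_plan()]).
#' @return Flat list of `segment_matrix` objects.
#' @export
segment_records <- function(records, n_cyc = 3, overlap_rate = 0.1,
                            f_max = 1000) {
  out <- lapply(records, function(r)
    asfs_extract(r, segment_plan(r$fs, n_cyc, overlap_rate), f_max))
  do.call(c, out)
}

# Tensors straight from a list of segment images + labels (used for
# SMOTE-synthesised training samples).
tensors_from_matrices <- function(mats, labels, subject_id = NULL,
                                  record_id = NULL, levels = 3L) {
  segs <- lapply(seq_along(mats), function(i) {
    structure(list(matrix = mats[[i]], label = labels[i],
                   subject_id = (subject_id %||% rep("synthetic", length(mats)))[i],
                   record_id = (record_id %||% rep("synthetic", length(mats)))[i],
                   segment_index = i, snr_db = Inf),
              class = "segment_matrix")
  })
  segments_to_tensors(segs, levels)
}

bind_tensors <- function(a, b) {
  abind4 <- function(x, y) {
    d <- dim(x)
    out <- array(0, c(d[1:3], d[4] + dim(y)[4]))
    out[, , , seq_len(d[4])] <- x
    out[, , , d[4] + seq_len(dim(y)[4])] <- y
    out
  }
  list(img = abind4(a$img, b$img),
       dwt = Map(abind4, a$dwt, b$dwt),
       y = c(a$y, b$y), labels = c(a$labels, b$labels),
       subject_id = c(a$subject_id, b$subject_id),
       record_id = c(a$record_id, b$record_id))
}

# Borderline-SMOTE on the training tensors: augments every class whose
# count trips the imbalance trigger, working on flattened (row-major)
# segment vectors and recomputing the wavelet stacks of synthetic
# samples.  Returns the augmented tensors plus a provenance manifest.
augment_training_tensors <- function(tensors, levels = 3L, k = 5L, s = 2L,
                                     threshold = 1 / 3, seed = 1L) {
  counts <- table(factor(tensors$labels, levels = mddnet_classes()))
  counts <- counts[counts > 0]
  flags <- needs_oversampling(as.vector(counts), threshold)
  manifest <- data.frame(synthetic = rep(FALSE, length(tensors$y)))
  if (!any(flags)) return(list(tensors = tensors, manifest = manifest))
  d <- dim(tensors$img)
  # rows = samples of the row-major unfolded segments
  flat <- t(vapply(seq_along(tensors$y), function(i)
    unfold_segment(tensors$img[, , 1L, i]), numeric(d[1] * d[2])))
  out <- tensors
  for (cl in names(counts)[flags]) {
    target <- oversample_target(as.vector(counts), threshold)
    sm <- borderline_smote(flat, tensors$labels, cl,
                           smote_config(k = k, s = s, target = target,
                                        seed = mix_seed(seed, cl)))
    new_rows <- which(sm$provenance$synthetic)
    if (!length(new_rows)) next
    mats <- lapply(new_rows, function(i) fold_segment(sm$x[i, ], d[1], d[2]))
    synth <- tensors_from_matrices(mats, rep(cl, length(new_rows)),
                                   levels = levels)
    out <- bind_tensors(out, synth)
    manifest <- rbind(manifest,
                      data.frame(synthetic = rep(TRUE, length(new_rows))))
  }
  list(tensors = out, manifest = manifest)
}

#' Run a full classification experiment
#'
#' Orchestrates segmentation, splitting, optional Borderline-SMOTE
#' augmentation (training folds only -- test folds are never oversampled
#' or reduced), training and evaluation.  Intra-patient mode performs
#' segment-level k-fold cross-validation; inter-patient mode trains on
#' the DS1 subjects and tests on the disjoint DS2 subjects.
#'
#' @param records List of [ecg_record()]s.
#' @param mode `"intra"` or `"inter"`.
#' @param k Folds for intra-patient mode (default 10).
#' @param ds1_subjects,ds2_subjects Subject lists for inter-patient mode.
#' @param config Network configuration ([mddnet_config()]).
#' @param epochs,batch_size,lr,target_acc Training controls (see
#'   [mddnet_train()]).
#' @param smote Apply Borderline-SMOTE to imbalanced training folds.
#' @param n_cyc,overlap_rate,f_max Segmentation parameters.
#' @param seed Integer seed governing splitting, initialisation,
#'   training and augmentation.
#' @return List with `pooled` ([metrics_report()] over all test folds),
#'   `per_fold` reports, `models` (fitted models per fold) and
#'   `n_segments`.
#' @export
run_experiment <- function(records, mode = c("intra", "inter"), k = 10L,
                           ds1_subjects = NULL, ds2_subjects = NULL,
                           config = mddnet_config(), epochs = 30L,
                           batch_size = 50L, lr = 1e-3, target_acc = NULL,
                           smote = TRUE, n_cyc = 3, overlap_rate = 0.1,
                           f_max = 1000, seed = 1L) {
  mode <- match.arg(mode)
  segments <- segment_records(records, n_cyc, overlap_rate, f_max)
  tensors <- segments_to_tensors(segments, config$levels)
  n <- length(tensors$y)
  folds <- if (mode == "intra") {
    sp <- kfold_split(n, k, seed)
    lapply(seq_len(k), function(f)
      list(train = which(sp$folds != f), test = which(sp$folds == f)))
  } else {
    sp <- inter_patient_split(tensors$subject_id, ds1_subjects, ds2_subjects)
    list(list(train = sp$train_idx, test = sp$test_idx))
  }
  pooled_cm <- matrix(0L, length(mddnet_classes()), length(mddnet_classes()),
                      dimnames = list(true = mddnet_classes(),
                                      predicted = mddnet_classes()))
  per_fold <- list()
  models <- list()
  for (f in seq_along(folds)) {
    tr_idx <- folds[[f]]$train
    te_idx <- folds[[f]]$test
    train_t <- slice_tensors(tensors, tr_idx)
    test_t <- slice_tensors(tensors, te_idx)
    n_test_before <- length(test_t$y)
    if (smote) {
      aug <- augment_training_tensors(train_t, config$levels,
                                      seed = mix_seed(seed, "aug", f))
      train_t <- aug$tensors
      if (length(test_t$y) != n_test_before)
        stop("leakage: test fold size changed by augmentation", call. = FALSE)
    }
    counts <- table(factor(train_t$labels, levels = mddnet_classes()))
    loss_spec <- select_loss(as.vector(counts[counts > 0]))
    model <- mddnet_init(config_graph(config), seed = mix_seed(seed, "init", f))
    model <- mddnet_train(model, train_t, loss_spec, epochs = epochs,
                          batch_size = batch_size, lr = lr,
                          seed = mix_seed(seed, "fold", f),
                          target_acc = target_acc)
    pred <- mddnet_predict(model, test_t)
    cm <- confusion_matrix(test_t$y, pred$class_index)
    pooled_cm <- pooled_cm + cm
    per_fold[[f]] <- metrics_report(cm)
    models[[f]] <- model
  }
  list(pooled = metrics_report(pooled_cm), per_fold = per_fold,
       models = models, n_segments = n)
}

config_graph <- function(config) build_mddnet(config)

#' Noise-robustness experiment
#'
#' Evaluates a fitted model on a test set re-generated at each
#' signal-to-noise ratio: white Gaussian noise is injected into the raw
#' records *before* segmentation, the records are re-segmented, and the
#' model is evaluated.  The first row is the clean baseline
#' (`snr_db = Inf`).
#'
#' @param model A fitted `mddnet_model`.
#' @param test_records Raw test [ecg_record()]s.
#' @param snr_list SNR levels in dB (default 24, 18, 12, 6, 0).
#' @param n_cyc,overlap_rate,f_max Segmentation parameters.
#' @param seed Integer seed for the noise draws.
#' @return List with `summary` (data frame: one row per SNR level plus
#'   baseline, macro metrics and overall accuracy) and `reports` (the
#'   full [metrics_report()]s).
#' @export
run_noise_robustness <- function(model, test_records,
                                 snr_list = c(24, 18, 12, 6, 0),
                                 n_cyc = 3, overlap_rate = 0.1, f_max = 1000,
                                 seed = 1L) {
  if (!length(test_records)) stop("empty test set", call. = FALSE)
  levels_ <- model$graph$config$levels
  rows <- list()
  reports <- list()
  for (snr in c(Inf, snr_list)) {
    recs <- if (is.infinite(snr)) test_records
            else lapply(test_records, add_awgn, snr_db = snr,
                        seed = mix_seed(seed, "robust", snr))
    segs <- segment_records(recs, n_cyc, overlap_rate, f_max)
    tens <- segments_to_tensors(segs, levels_)
    pred <- mddnet_predict(model, tens)
    cm <- confusion_matrix(tens$y, pred$class_index)
    rep_ <- metrics_report(cm)
    key <- if (is.infinite(snr)) "baseline" else sprintf("%g dB", snr)
    reports[[key]] <- rep_
    rows[[key]] <- data.frame(snr_db = snr, ACC = rep_$macro["ACC"],
                              PPV = rep_$macro["PPV"], SEN = rep_$macro["SEN"],
                              SPE = rep_$macro["SPE"],
                              OA = rep_$overall_accuracy, row.names = NULL)
  }
  summary <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  summary$level <- names(rows)
  list(summary = summary, reports = reports)
}
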