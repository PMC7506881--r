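EPS_P <- 1e-12

clamp_p <- function(p) pmin(pmax(p, EPS_P), 1 - EPS_P)

#' Binary cross-entropy loss
#'
#' `-log(p)` for positive samples (`y = 1`) and `-log(1 - p)` for
#' negative samples; probabilities are clamped to `[1e-12, 1 - 1e-12]`.
#'
#' @param p Predicted probability (vectorised).
#' @param y Label in `{0, 1}` (vectorised).
#' @return Nonnegative loss.
#' @export
cross_entropy <- function(p, y) {
  p <- clamp_p(p)
  ifelse(y == 1, -log(p), -log(1 - p))
}

#' Binary focal loss
#'
#' Cross-entropy modulated to down-weight easy samples:
#' `-alpha * (1 - p)^gamma * log(p)` for positives and
#' `-(1 - alpha) * p^gamma * log(1 - p)` for negatives.  With
#' `gamma = 0` it reduces to `alpha`-weighted cross-entropy.
#'
#' @param p,y As in [cross_entropy()].
#' @param gamma Focusing exponent, >= 0 (default 2).
#' @param alpha Positive-class weight in (0, 1) (default 0.25).
#' @export
focal_loss <- function(p, y, gamma = 2, alpha = 0.25) {
  stopifnot(gamma >= 0, alpha > 0, alpha < 1)
  p <- clamp_p(p)
  ifelse(y == 1,
         -alpha * (1 - p)^gamma * log(p),
         -(1 - alpha) * p^gamma * log(1 - p))
}

#' Multiclass focal loss on a probability vector
#'
#' `-alpha[c] * (1 - p[c])^gamma * log(p[c])` where `c` is the true
#' class; `gamma = 0` with unit alphas gives the multiclass
#' cross-entropy.
#'
#' @param prob Probability vector (sums to 1).
#' @param true_class Integer class index in `1:length(prob)`.
#' @param gamma Focusing exponent (>= 0).
#' @param alpha Scalar or per-class weight vector.
#' @export
multiclass_focal_loss <- function(prob, true_class, gamma = 2, alpha = 1) {
  if (length(true_class) != 1 || true_class < 1 || true_class > length(prob))
    stop("`true_class` must index `prob`", call. = FALSE)
  a <- if (length(alpha) == 1) alpha else alpha[true_class]
  pc <- clamp_p(prob[true_class])
  -a * (1 - pc)^gamma * log(pc)
}

#' Label minority samples as noise, safe or border
#'
#' For each minority-class sample, inspects its `k` nearest neighbours
#' (Euclidean distance on the feature rows) within the full training set:
#' all-majority neighbourhoods mark a `noise` sample, all-minority a
#' `safe` sample, and mixed neighbourhoods a `border` sample -- the only
#' ones Borderline-SMOTE synthesises from.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param labels Vector of class labels aligned with `x`.
#' @param minority_class The label treated as minority.
#' @param k Neighbour count (`1 <= k < nrow(x)`).
#' @return Factor with levels `noise`, `safe`, `border`, one entry per
#'   minority sample (in row order of the minority subset).
#' @export
classify_minority_samples <- function(x, labels, minority_class, k = 5L) {
  x <- as.matrix(x)
  if (k < 1 || k >= nrow(x))
    stop("`k` must satisfy 1 <= k < number of samples", call. = FALSE)
  min_idx <- which(labels == minority_class)
  if (!length(min_idx))
    stop("no samples of the minority class", call. = FALSE)
  d <- as.matrix(stats::dist(x))
  out <- character(length(min_idx))
  for (ii in seq_along(min_idx)) {
    i <- min_idx[ii]
    nn <- order(d[i, -i])[seq_len(k)]
    nn <- seq_len(nrow(x))[-i][nn]
    n_min <- sum(labels[nn] == minority_class)
    out[ii] <- if (n_min == 0) "noise" else if (n_min == k) "safe" else "border"
  }
  factor(out, levels = c("noise", "safe", "border"))
}

#' Borderline-SMOTE configuration
#'
#' @param k Neighbours used both to classify minority samples and to pick
#'   interpolation partners (default 5).
#' @param s Neighbours sampled per border point per round (default 2).
#' @param target Target minority count after augmentation; `NULL` keeps
#'   the caller's choice (see [oversample_target()]).
#' @param seed Integer seed.
#' @export
smote_config <- function(k = 5L, s = 2L, target = NULL, seed = 1L) {
  stopifnot(k >= 1, s >= 1)
  list(k = k, s = s, target = target, seed = seed)
}

#' Default oversampling target for a minority class
#'
#' Minority classes are raised to `ceiling(threshold * max(counts))`,
#' i.e. just past the imbalance trigger ratio.
#'
#' @param class_counts Named nonnegative counts.
#' @param threshold Imbalance ratio (default 1/3).
#' @export
oversample_target <- function(class_counts, threshold = 1 / 3) {
  ceiling(threshold * max(class_counts))
}

#' Borderline-SMOTE oversampling of one minority class
#'
#' Synthesises new minority samples only from `border` points (minority
#' samples whose neighbourhoods mix classes).  Each synthetic point is an
#' interpolation `h = parent + r * (neighbour - parent)` toward a
#' randomly chosen minority neighbour of the parent, with
#' `r ~ U(0, 1)` -- restricted to `U(0, 0.5)` when the chosen neighbour
#' is itself a noise or safe sample -- so every synthetic point lies on
#' the open segment between parent and neighbour.  Original samples are
#' never modified.  If no border sample exists, the routine warns and
#' falls back to plain interpolation between safe samples.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param labels Labels aligned with `x`.
#' @param minority_class Label of the class to augment.
#' @param cfg A [smote_config()]; `cfg$target` defaults to
#'   [oversample_target()] of the label counts.
#' @return List with `x` (original rows then synthetic rows), `labels`,
#'   and `provenance`: a data frame with one row per output sample
#'   (`synthetic`, `parent`, `neighbour`, `r`).
#' @export
borderline_smote <- function(x, labels, minority_class, cfg = smote_config()) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  counts <- table(labels)
  target <- cfg$target %||% oversample_target(as.vector(counts))
  n_min <- sum(labels == minority_class)
  n_new <- max(0L, target - n_min)
  prov0 <- data.frame(synthetic = rep(FALSE, nrow(x)), parent = NA_integer_,
                      neighbour = NA_integer_, r = NA_real_)
  if (n_new == 0L)
    return(list(x = x, labels = labels, provenance = prov0))

  kinds <- classify_minority_samples(x, labels, minority_class, cfg$k)
  min_idx <- which(labels == minority_class)
  parents <- min_idx[kinds == "border"]
  if (!length(parents)) {
    warning("no border samples; falling back to interpolation between safe samples",
            call. = FALSE)
    parents <- min_idx[kinds == "safe"]
    if (!length(parents))
      stop("minority class has neither border nor safe samples", call. = FALSE)
  }
  xmin <- x[min_idx, , drop = FALSE]
  # k nearest minority neighbours of each parent (within the minority set)
  dmin <- as.matrix(stats::dist(xmin))
  kind_of <- stats::setNames(as.character(kinds), min_idx)

  synth <- matrix(NA_real_, n_new, ncol(x))
  prov <- data.frame(synthetic = rep(TRUE, n_new), parent = NA_integer_,
                     neighbour = NA_integer_, r = NA_real_)
  with_seed(mix_seed(cfg$seed, "bsmote"), {
    made <- 0L
    while (made < n_new) {
      for (p in sample(parents)) {
        if (made >= n_new) break
        pi_min <- match(p, min_idx)
        kk <- min(cfg$k, length(min_idx) - 1L)
        nn_local <- order(dmin[pi_min, -pi_min])[seq_len(kk)]
        nn_idx <- min_idx[-pi_min][nn_local]
        chosen <- sample(nn_idx, size = min(cfg$s, length(nn_idx)))
        for (q in chosen) {
          if (made >= n_new) break
          r_max <- if (kind_of[[as.character(q)]] %in% c("noise", "safe")) 0.5 else 1
          r <- runif(1, 0, r_max)
          made <- made + 1L
          synth[made, ] <- x[p, ] + r * (x[q, ] - x[p, ])
          prov$parent[made] <- p
          prov$neighbour[made] <- q
          prov$r[made] <- r
        }
      }
    }
  })
  list(x = rbind(x, synth),
       labels = c(labels, rep(minority_class, n_new)),
       provenance = rbind(prov0, prov))
}

#' Flag classes requiring oversampling
#'
#' A class needs oversampling when its count falls strictly below
#' `threshold` times the largest class count (the imbalance trigger
#' ratio; default 1/3).
#'
#' @param class_counts Named nonnegative counts.
#' @param threshold Ratio in (0, 1].
#' @return Named logical vector.
#' @export
needs_oversampling <- function(class_counts, threshold = 1 / 3) {
  if (all(class_counts == 0))
    stop("all class counts are zero", call. = FALSE)
  class_counts / max(class_counts) < threshold
}

#' Select the training loss from the class balance
#'
#' Focal loss when any class trips the imbalance trigger; plain
#' cross-entropy otherwise.
#'
#' @param class_counts Named counts.
#' @param gamma,alpha Focal parameters used when imbalance is detected.
#' @param threshold Imbalance trigger ratio (default 1/3, strict).
#' @return Object of class `focal_loss_spec` with fields `mode`
#'   (`"focal"` or `"cross_entropy"`), `gamma`, `alpha`.
#' @export
select_loss <- function(class_counts, gamma = 2, alpha = 0.25,
                        threshold = 1 / 3) {
  imbalanced <- any(needs_oversampling(class_counts, threshold))
  structure(list(mode = if (imbalanced) "focal" else "cross_entropy",
                 gamma = if (imbalanced) gamma else 0,
                 alpha = alpha),
            class = "focal_loss_spec")
}

#' Proportionally reduce disease class counts
#'
#' The scale-reduction rule of the imbalance experiments: the protected
#' (normal) class keeps its count while every other class is reduced to
#' `floor(count / scale)`.
#'
#' @param class_counts Named counts.
#' @param scale Integer reduction factor, >= 1.
#' @param protected_class Class left unchanged (default `"Normal"`).
#' @return Named counts after reduction.
#' @examples
#' scale_reduce(c(Normal = 3454, MI = 15011, CAD = 11339, CHF = 22215), 20)
#' @export
scale_reduce <- function(class_counts, scale, protected_class = "Normal") {
  if (!is.finite(scale) || scale < 1 || scale != round(scale))
    stop("`scale` must be an integer >= 1", call. = FALSE)
  out <- floor(class_counts / scale)
  out[names(class_counts) == protected_class] <-
    class_counts[names(class_counts) == protected_class]
  out
}
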