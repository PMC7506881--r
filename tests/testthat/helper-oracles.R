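# Independent oracles and published reference tables used across the suite.

# Brute-force single-level 2-D orthonormal Haar analysis: explicit
# per-output-entry evaluation of the separable filters with trailing-edge
# replication on odd axes.  Deliberately loop-based and structured
# differently from the package implementation.
haar_dwt2_ref <- function(m) {
  h <- nrow(m); w <- ncol(m)
  he <- h + h %% 2; we <- w + w %% 2
  me <- matrix(0, he, we)
  me[1:h, 1:w] <- m
  if (he > h) me[he, 1:w] <- m[h, ]
  if (we > w) me[, we] <- me[, w]
  h2 <- he / 2; w2 <- we / 2
  LL <- HL <- LH <- HH <- matrix(0, h2, w2)
  for (i in seq_len(h2)) {
    for (j in seq_len(w2)) {
      blk <- me[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]
      a <- blk[1, 1]; b <- blk[1, 2]; c <- blk[2, 1]; d <- blk[2, 2]
      LL[i, j] <- (a + b + c + d) / 2
      HL[i, j] <- (a - b + c - d) / 2   # high along the horizontal axis
      LH[i, j] <- (a + b - c - d) / 2   # high along the vertical axis
      HH[i, j] <- (a - b - c + d) / 2
    }
  }
  list(LL = LL, HL = HL, LH = LH, HH = HH)
}

# Straight-line reference transcription of Borderline-SMOTE with
# brute-force kNN, kept independent of the package implementation.
# Returns only the synthetic points.
bsmote_ref <- function(x, labels, minority_class, k, s, n_new, seed) {
  set.seed(seed)
  nmin_idx <- which(labels == minority_class)
  kinds <- character(length(nmin_idx))
  for (ii in seq_along(nmin_idx)) {
    i <- nmin_idx[ii]
    dd <- sqrt(colSums((t(x) - x[i, ])^2))
    dd[i] <- Inf
    nn <- order(dd)[1:k]
    nm <- sum(labels[nn] == minority_class)
    kinds[ii] <- if (nm == 0) "noise" else if (nm == k) "safe" else "border"
  }
  border <- nmin_idx[kinds == "border"]
  kind_of <- setNames(kinds, nmin_idx)
  synth <- matrix(NA_real_, n_new, ncol(x))
  made <- 0
  while (made < n_new) {
    for (p in sample(border)) {
      if (made >= n_new) break
      dd <- sqrt(colSums((t(x[nmin_idx, , drop = FALSE]) - x[p, ])^2))
      dd[nmin_idx == p] <- Inf
      nn <- nmin_idx[order(dd)[1:min(k, length(nmin_idx) - 1)]]
      for (q in sample(nn, min(s, length(nn)))) {
        if (made >= n_new) break
        rmax <- if (kind_of[[as.character(q)]] %in% c("noise", "safe")) 0.5 else 1
        r <- runif(1, 0, rmax)
        made <- made + 1
        synth[made, ] <- x[p, ] + r * (x[q, ] - x[p, ])
      }
    }
  }
  synth
}

# Published reference confusion matrices (inputs to the metric engine).
classes4 <- c("Normal", "MI", "CAD", "CHF")
cm_intra <- matrix(c(3297, 157, 0, 0,
                     82, 14921, 2, 6,
                     0, 1, 11322, 16,
                     0, 0, 7, 22208),
                   4, 4, byrow = TRUE, dimnames = list(classes4, classes4))
cm_inter_densenet <- matrix(c(1075, 537, 6, 0,
                              202, 5744, 20, 290,
                              9, 69, 3421, 1170,
                              8, 257, 194, 9908),
                            4, 4, byrow = TRUE,
                            dimnames = list(classes4, classes4))
cm_inter_mldwt <- matrix(c(1322, 295, 1, 0,
                           361, 5829, 16, 50,
                           91, 7, 3717, 854,
                           10, 2, 611, 9744),
                         4, 4, byrow = TRUE, dimnames = list(classes4, classes4))
cm_inter_mddnet <- matrix(c(1173, 442, 3, 0,
                            149, 6013, 48, 46,
                            15, 10, 4250, 394,
                            5, 3, 294, 10065),
                          4, 4, byrow = TRUE, dimnames = list(classes4, classes4))

# Published segment counts and their scale-reduced values.
counts_full <- c(Normal = 3454, MI = 15011, CAD = 11339, CHF = 22215)
scale_table <- list(
  `20` = c(Normal = 3454, MI = 750, CAD = 566, CHF = 1110),
  `40` = c(Normal = 3454, MI = 375, CAD = 283, CHF = 555),
  `60` = c(Normal = 3454, MI = 250, CAD = 188, CHF = 370),
  `80` = c(Normal = 3454, MI = 187, CAD = 141, CHF = 277),
  `100` = c(Normal = 3454, MI = 150, CAD = 113, CHF = 222)
)

round2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100

# Small labelled dataset shared by slower pipeline tests.
tiny_dataset <- function(seed = 7, subjects = 2L, records = 1L,
                         duration_s = 15) {
  make_dataset(dataset_config(
    subjects = c(Normal = subjects, MI = subjects, CAD = subjects,
                 CHF = subjects),
    records_per_subject = records, duration_s = duration_s), seed = seed)
}
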