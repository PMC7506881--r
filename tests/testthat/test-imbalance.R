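test_that("cross-entropy behaves as the binary log loss", {
  expect_lt(cross_entropy(1 - 1e-12, 1), 1e-11)
  expect_equal(cross_entropy(0.5, 1), log(2))
  expect_equal(cross_entropy(0.5, 0), log(2))
  p <- seq(0.05, 0.95, by = 0.1)
  expect_equal(cross_entropy(p, 1), cross_entropy(1 - p, 0))
  expect_true(all(cross_entropy(p, 1) >= 0))
})

test_that("focal loss reduces to alpha-weighted cross-entropy at gamma 0", {
  p <- seq(1e-12, 1 - 1e-12, length.out = 2001)
  for (y in 0:1)
    expect_lt(max(abs(focal_loss(p, y, gamma = 0, alpha = 0.5) -
                        0.5 * cross_entropy(p, y))), 1e-12)
})

test_that("focal loss matches hand-computed values and down-weights easy samples", {
  # alpha (1-p)^gamma CE at p = 0.9, gamma = 2, alpha = 0.25
  expect_equal(focal_loss(0.9, 1, gamma = 2, alpha = 0.25),
               0.25 * 0.01 * (-log(0.9)), tolerance = 1e-12)
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(focal_loss(p, 1, gamma = 2, alpha = 0.25) <=
                    0.25 * cross_entropy(p, 1)))
})

test_that("multiclass focal loss generalises the binary form", {
  expect_equal(multiclass_focal_loss(rep(0.25, 4), 2, gamma = 0, alpha = 1),
               log(4))
  expect_lt(multiclass_focal_loss(c(1 - 3e-13, 1e-13, 1e-13, 1e-13), 1,
                                  gamma = 2, alpha = 0.25), 1e-11)
  p <- c(0.7, 0.1, 0.15, 0.05)
  expect_equal(multiclass_focal_loss(p, 1, gamma = 0, alpha = c(2, 1, 1, 1)),
               -2 * log(0.7))
  expect_error(multiclass_focal_loss(p, 5), "index")
})

test_that("minority neighbourhoods classify into noise, safe and border", {
  # 1-D toy from hand-computed neighbourhoods
  x <- matrix(c(0, 0.1, 10, 11, 12), ncol = 1)
  labs <- c("min", "min", "maj", "maj", "maj")
  k2 <- classify_minority_samples(x, labs, "min", k = 2)
  expect_equal(as.character(k2), c("border", "border"))
  # far-away minority point with all-majority neighbours is noise
  x2 <- rbind(x, 100)
  labs2 <- c(labs, "min")
  expect_equal(as.character(
    classify_minority_samples(x2, labs2, "min", k = 3))[3], "noise")
  # dense minority cluster far from the majority is safe
  x3 <- matrix(c(0, 0.05, 0.1, 50, 51), ncol = 1)
  labs3 <- c("min", "min", "min", "maj", "maj")
  expect_equal(as.character(
    classify_minority_samples(x3, labs3, "min", k = 2)),
    c("safe", "safe", "safe"))
  expect_error(classify_minority_samples(x, labs, "min", k = 5), "k")
})

test_that("synthetic points interpolate between border parents and neighbours", {
  set.seed(9)
  maj <- matrix(rnorm(120, mean = 1.5, sd = 0.8), ncol = 2)
  min_ <- matrix(rnorm(30, mean = 0, sd = 0.8), ncol = 2)
  x <- rbind(maj, min_)
  labs <- rep(c("maj", "min"), c(60, 15))
  res <- borderline_smote(x, labs, "min",
                          smote_config(k = 5, s = 2, target = 60, seed = 4))
  expect_equal(sum(res$labels == "min"), 60)
  # originals untouched, in place
  expect_equal(res$x[seq_len(nrow(x)), ], x, ignore_attr = TRUE)
  syn <- res$provenance[res$provenance$synthetic, ]
  expect_equal(nrow(syn), 45)
  for (i in seq_len(nrow(syn))) {
    h <- res$x[nrow(x) + i, ]
    a <- x[syn$parent[i], ]; b <- x[syn$neighbour[i], ]
    # componentwise betweenness on the open segment
    expect_true(all(h >= pmin(a, b) - 1e-12 & h <= pmax(a, b) + 1e-12))
    expect_equal(h, a + syn$r[i] * (b - a), ignore_attr = TRUE)
    expect_equal(labs[syn$parent[i]], "min")
  }
  # target equal to the current count is a no-op
  noop <- borderline_smote(x, labs, "min",
                           smote_config(target = 15, seed = 1))
  expect_equal(nrow(noop$x), nrow(x))
  # determinism
  res2 <- borderline_smote(x, labs, "min",
                           smote_config(k = 5, s = 2, target = 60, seed = 4))
  expect_identical(res$x, res2$x)
})

test_that("synthetic distribution matches an independent reference oracle", {
  set.seed(21)
  maj <- cbind(rnorm(300, 1.5, 0.8), rnorm(300, 1.5, 0.8))
  min_ <- cbind(rnorm(60, 0, 1), rnorm(60, 0, 1))
  x <- rbind(maj, min_)
  labs <- rep(c("maj", "min"), c(300, 60))
  n_new <- 1000
  res <- borderline_smote(x, labs, "min",
                          smote_config(k = 5, s = 2, target = 60 + n_new,
                                       seed = 10))
  mine <- res$x[res$provenance$synthetic, ]
  ref <- bsmote_ref(x, labs, "min", k = 5, s = 2, n_new = n_new, seed = 77)
  for (ax in 1:2) {
    ks <- suppressWarnings(stats::ks.test(mine[, ax], ref[, ax]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("a minority set with no border points falls back with a warning", {
  x <- matrix(c(0, 0.05, 0.1, 50, 51, 52, 53, 54), ncol = 1)
  labs <- rep(c("min", "maj"), c(3, 5))
  expect_warning(
    res <- borderline_smote(x, labs, "min",
                            smote_config(k = 2, s = 1, target = 6, seed = 2)),
    "border")
  expect_equal(sum(res$labels == "min"), 6)
})

test_that("the imbalance trigger is strict at one third", {
  flags <- needs_oversampling(c(Normal = 300, CAD = 90))
  expect_equal(unname(flags), c(FALSE, TRUE))  # 90/300 = 0.3 < 1/3
  expect_false(any(needs_oversampling(c(100, 100, 100))))
  expect_false(any(needs_oversampling(c(300, 100))))  # exactly 1/3
  expect_error(needs_oversampling(c(0, 0)), "zero")
})

test_that("loss selection follows the imbalance policy", {
  expect_equal(select_loss(c(100, 100, 100, 100))$mode, "cross_entropy")
  spec <- select_loss(c(100, 10, 100, 100))
  expect_equal(spec$mode, "focal")
  expect_equal(spec$gamma, 2)
  expect_equal(spec$alpha, 0.25)
  expect_equal(select_loss(c(300, 100))$mode, "cross_entropy")  # boundary
})

test_that("scale reduction reproduces the published count table", {
  for (s in names(scale_table))
    expect_equal(scale_reduce(counts_full, as.numeric(s)), scale_table[[s]])
  expect_equal(scale_reduce(counts_full, 1), counts_full)
  expect_error(scale_reduce(counts_full, 0), "integer")
})
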