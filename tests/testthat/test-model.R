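# Reduced configuration used by the engine tests: same wiring, far fewer
# channels, so a forward/backward pass is immediate.
tiny_cfg <- function() {
  mddnet_config(input_shape = c(12L, 10L, 1L), classes = 3L, growth = 2L,
                n_composite = 2L, bottleneck = 3L, levels = 2L,
                sub_filters = c(4L, 3L), link_filters = 2L)
}

tiny_batch <- function(n = 3, seed = 7) {
  set.seed(seed)
  list(img = array(runif(12 * 10 * n), c(12, 10, 1, n)),
       dwt = list(array(rnorm(6 * 5 * 4 * n), c(6, 5, 4, n)),
                  array(rnorm(3 * 3 * 4 * n), c(3, 3, 4, n))),
       y = rep_len(1:3, n))
}

test_that("the default graph reproduces the published architecture table", {
  tab <- shape_table(build_mddnet())
  expected <- data.frame(
    layer = c("Convolution2D", "AveragePooling2D", "Dense block 1",
              "Transition block 1", "Dense block 2", "Transition block 2",
              "Dense block 3", "Maxpooling2D", "Conv block 1",
              "Concatenation 1", "Maxpooling2D", "Conv block 2",
              "Conv block 3", "Concatenation 2", "Maxpooling2D",
              "Conv block 4", "Conv block 5", "Concatenation 3",
              "Maxpooling2D", "Concatenation 4", "Maxpooling2D",
              "GlobalMaxPooling2D", "Softmax"),
    output_shape = c("(60, 50, 24)", "(30, 25, 24)", "(30, 25, 36)",
                     "(15, 13, 18)", "(15, 13, 30)", "(8, 7, 15)",
                     "(8, 7, 27)", "(4, 4, 27)", "(30, 25, 24)",
                     "(30, 25, 96)", "(15, 13, 96)", "(15, 13, 12)",
                     "(15, 13, 24)", "(15, 13, 108)", "(8, 7, 108)",
                     "(8, 7, 12)", "(8, 7, 24)", "(8, 7, 108)",
                     "(4, 4, 108)", "(4, 4, 135)", "(2, 2, 135)",
                     "(135)", "4"))
  expect_equal(tab, expected)
})

test_that("channel arithmetic follows dense-block and wavelet-branch laws", {
  tr <- shape_trace(build_mddnet())
  ch <- function(nm) tr$c[tr$name == nm]
  # dense blocks add the growth rate; transitions halve
  expect_equal(ch("db1_out"), ch("ap1") + 12)
  expect_equal(ch("db2_out"), ch("t1_pool") + 12)
  expect_equal(ch("db3_out"), ch("t2_pool") + 12)
  expect_equal(ch("t1_conv"), ch("db1_out") %/% 2)
  expect_equal(ch("t2_conv"), ch("db2_out") %/% 2)
  # wavelet stages: 4 x 24 = 96; with the 12-channel link, 108; fusion 135
  expect_equal(ch("c_w1"), 96)
  expect_equal(ch("c_w2"), 108)
  expect_equal(ch("c_w3"), 108)
  expect_equal(ch("fuse"), 27 + 108)
})

test_that("reduced variants build consistently and bad configs fail loudly", {
  for (lv in 1:3) {
    g <- build_mddnet(mddnet_config(levels = lv))
    tab <- shape_table(g)
    expect_equal(tab$output_shape[nrow(tab)], "4")
    # fusion = 27 dense channels + 96 subband channels (+ 12-channel
    # stage link once more than one level is decomposed)
    fusion <- 27 + 96 + if (lv > 1) 12 else 0
    expect_equal(tab$output_shape[nrow(tab) - 1], sprintf("(%d)", fusion))
  }
  g <- build_mddnet(tiny_cfg())
  expect_equal(shape_table(g)$output_shape[1], "(12, 10, 24)")
  # an inconsistent hand-edited graph is rejected with the layer named
  bad <- build_mddnet()
  bad$layers$fuse$inputs <- c("db3_out", "mp_w3")  # (8,7) vs (4,4)
  expect_error(shape_trace(bad), "concat layer 'fuse'")
})

test_that("softmax is a shift-invariant probability map", {
  expect_equal(softmax(c(0, 0, 0, 0)), rep(0.25, 4))
  expect_equal(softmax(c(0, log(3))), c(0.25, 0.75))
  set.seed(1)
  v <- rnorm(6)
  expect_equal(softmax(v), softmax(v + 42.5), tolerance = 1e-12)
  expect_equal(sum(softmax(v)), 1, tolerance = 1e-12)
  expect_true(all(softmax(v) > 0))
  expect_error(softmax(numeric(0)), "empty")
  expect_error(softmax(c(1, NaN)), "finite")
})

test_that("forward pass emits probability rows and matches the static trace", {
  g <- build_mddnet(tiny_cfg())
  model <- mddnet_init(g, seed = 1)
  batch <- tiny_batch(n = 2)
  fw <- mddnet:::forward_pass(model, batch, training = FALSE, keep = TRUE)
  expect_equal(dim(fw$probs), c(2L, 3L))
  expect_equal(rowSums(fw$probs), c(1, 1), tolerance = 1e-12)
  # identical call is deterministic
  fw2 <- mddnet:::forward_pass(model, batch, training = FALSE)
  expect_identical(fw$probs, fw2$probs)
  # runtime spatial shapes equal the static trace everywhere
  tr <- shape_trace(g)
  for (nm in tr$name) {
    out <- get(nm, envir = fw$outs)
    s <- attr(out, "spatial")
    row <- tr[tr$name == nm, ]
    if (!is.null(s)) {
      expect_equal(unname(s[1:2]), c(row$h, row$w), label = nm)
      expect_equal(ncol(out), row$c, label = nm)
    } else {
      expect_equal(ncol(out), row$c, label = nm)
    }
  }
})

test_that("analytic gradients agree with finite differences", {
  g <- build_mddnet(tiny_cfg())
  model <- mddnet_init(g, seed = 3)
  batch <- tiny_batch(n = 3)
  loss_of <- function(m, spec) {
    fw <- mddnet:::forward_pass(m, batch, training = TRUE)
    mddnet:::loss_and_grad(fw$probs, batch$y, spec)$loss
  }
  specs <- list(
    structure(list(mode = "cross_entropy", gamma = 0, alpha = 0.25),
              class = "focal_loss_spec"),
    structure(list(mode = "focal", gamma = 2, alpha = 0.3),
              class = "focal_loss_spec"))
  for (spec in specs) {
    fw <- mddnet:::forward_pass(model, batch, training = TRUE, keep = TRUE)
    lg <- mddnet:::loss_and_grad(fw$probs, batch$y, spec)
    pg <- mddnet:::backward_pass(model, fw, lg$dz)
    eps <- 1e-6
    set.seed(11)
    for (nm in sample(names(pg), 8)) {
      for (pn in names(pg[[nm]])) {
        P <- model$params[[nm]][[pn]]
        i <- sample(length(P), 1)
        m2 <- model
        m2$params[[nm]][[pn]][i] <- P[i] + eps
        lp <- loss_of(m2, spec)
        m2$params[[nm]][[pn]][i] <- P[i] - eps
        lm <- loss_of(m2, spec)
        num <- (lp - lm) / (2 * eps)
        ana <- pg[[nm]][[pn]][i]
        # absolute tolerance handles true-zero gradients (bias feeding
        # a downstream batch norm), where finite differences only see
        # round-off noise
        expect_equal(ana, num, tolerance = 1e-4,
                     label = sprintf("%s (%s/%s)", spec$mode, nm, pn))
      }
    }
  }
})

test_that("training reduces the loss and zero epochs is a no-op", {
  g <- build_mddnet(tiny_cfg())
  model <- mddnet_init(g, seed = 5)
  set.seed(20)
  n <- 30
  # three linearly separable blob classes in image space
  img <- array(0, c(12, 10, 1, n))
  y <- rep_len(1:3, n)
  for (i in seq_len(n))
    img[, , 1, i] <- matrix(runif(120), 12, 10) +
      outer(seq(0, 1, length.out = 12), seq(0, 1, length.out = 10)) * y[i]
  dwt <- list(
    array(0, c(6, 5, 4, n)), array(0, c(3, 3, 4, n)))
  for (i in seq_len(n)) {
    st <- multilevel_decompose(img[, , 1, i], 2)
    dwt[[1]][, , , i] <- stack_subbands(st[[1]])
    dwt[[2]][, , , i] <- stack_subbands(st[[2]])
  }
  tens <- list(img = img, dwt = dwt, y = y,
               labels = c("Normal", "MI", "CAD")[y],
               subject_id = rep("s", n), record_id = rep("r", n))
  m0 <- mddnet_train(model, tens, epochs = 0L)
  expect_identical(m0$params, model$params)
  spec <- structure(list(mode = "cross_entropy", gamma = 0, alpha = 0.25),
                    class = "focal_loss_spec")
  m1 <- mddnet_train(model, tens, spec, epochs = 5L, batch_size = 10L,
                     seed = 2)
  expect_equal(nrow(m1$history), 5)
  expect_lt(m1$history$loss[5], m1$history$loss[1])
  # repeat training with the same seed is bitwise identical
  m1b <- mddnet_train(model, tens, spec, epochs = 5L, batch_size = 10L,
                      seed = 2)
  expect_identical(m1$params, m1b$params)
  pred <- mddnet_predict(m1, tens)
  expect_equal(dim(pred$probs), c(n, 3L))
  expect_equal(rowSums(pred$probs), rep(1, n), tolerance = 1e-10)
  expect_true(all(pred$class_index %in% 1:3))
  pred2 <- mddnet_predict(m1, tens)
  expect_identical(pred$probs, pred2$probs)
})

test_that("training on an empty set errors", {
  g <- build_mddnet(tiny_cfg())
  model <- mddnet_init(g, seed = 1)
  expect_error(mddnet_train(model, list(y = integer(0))), "empty")
})
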