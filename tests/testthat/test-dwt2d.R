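test_that("2x2 Haar coefficients match the closed-form separable formulas", {
  set.seed(1)
  vals <- matrix(rnorm(4), 2, 2)
  a <- vals[1, 1]; b <- vals[1, 2]; c <- vals[2, 1]; d <- vals[2, 2]
  sb <- haar_dwt2(vals)
  expect_equal(sb$LL[1, 1], (a + b + c + d) / 2)
  expect_equal(sb$HL[1, 1], (a - b + c - d) / 2)
  expect_equal(sb$LH[1, 1], (a + b - c - d) / 2)
  expect_equal(sb$HH[1, 1], (a - b - c + d) / 2)
})

test_that("transform matches the brute-force oracle on random matrices", {
  set.seed(11)
  for (dims in list(c(2, 2), c(6, 8), c(5, 7), c(9, 4), c(60, 50), c(1, 1))) {
    m <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    sb <- haar_dwt2(m)
    ref <- haar_dwt2_ref(m)
    for (band in c("LL", "HL", "LH", "HH"))
      expect_equal(sb[[band]], ref[[band]], tolerance = 1e-12,
                   label = sprintf("%s at %dx%d", band, dims[1], dims[2]))
  }
})

test_that("transform agrees with an established wavelet library", {
  # pywavelets single-level Haar with symmetric extension; its cV/cH
  # subbands carry horizontal/vertical detail respectively.
  set.seed(42)
  for (dims in list(c(6, 8), c(5, 7), c(60, 50))) {
    m <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    f <- tempfile(fileext = ".txt")
    writeLines(apply(m, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), f)
    py <- sprintf(paste0(
      "import numpy as np, pywt\n",
      "m = np.loadtxt('%s').reshape(%d, %d)\n",
      "cA,(cH,cV,cD) = pywt.dwt2(m,'haar',mode='symmetric')\n",
      "np.savetxt('%s', np.vstack([cA,cV,cH,cD]), fmt='%%.17g')\n"),
      f, dims[1], dims[2], paste0(f, ".out"))
    res <- system2("python", "-", input = py, stdout = TRUE, stderr = TRUE)
    expect_true(file.exists(paste0(f, ".out")),
                info = paste(res, collapse = "\n"))
    ref <- as.matrix(read.table(paste0(f, ".out")))
    dimnames(ref) <- NULL
    h2 <- ceiling(dims[1] / 2)
    sb <- haar_dwt2(m)
    expect_lt(max(abs(sb$LL - ref[1:h2, ])), 1e-8)
    expect_lt(max(abs(sb$HL - ref[(h2 + 1):(2 * h2), ])), 1e-8)
    expect_lt(max(abs(sb$LH - ref[(2 * h2 + 1):(3 * h2), ])), 1e-8)
    expect_lt(max(abs(sb$HH - ref[(3 * h2 + 1):(4 * h2), ])), 1e-8)
  }
})

test_that("constants concentrate in LL and details vanish", {
  sb <- haar_dwt2(matrix(3, 4, 4))
  expect_equal(sb$LL, matrix(6, 2, 2))
  expect_equal(sb$HL, matrix(0, 2, 2))
  expect_equal(sb$LH, matrix(0, 2, 2))
  expect_equal(sb$HH, matrix(0, 2, 2))
})

test_that("energy is conserved and the inverse reconstructs (even dims)", {
  set.seed(2)
  for (i in 1:5) {
    m <- matrix(rnorm(16 * 12), 16, 12)
    sb <- haar_dwt2(m)
    expect_equal(sum(sb$LL^2) + sum(sb$HL^2) + sum(sb$LH^2) + sum(sb$HH^2),
                 sum(m^2), tolerance = 1e-9)
    expect_lt(max(abs(haar_idwt2(sb) - m)), 1e-9)
  }
  z <- haar_dwt2(matrix(0, 4, 4))
  expect_equal(haar_idwt2(z), matrix(0, 4, 4))
})

test_that("transform is linear", {
  set.seed(3)
  x <- matrix(rnorm(30), 5, 6); y <- matrix(rnorm(30), 5, 6)
  s1 <- haar_dwt2(2 * x - 3 * y)
  sx <- haar_dwt2(x); sy <- haar_dwt2(y)
  for (band in c("LL", "HL", "LH", "HH"))
    expect_equal(s1[[band]], 2 * sx[[band]] - 3 * sy[[band]],
                 tolerance = 1e-12)
})

test_that("multilevel decomposition follows the ceiling-halving shape ladder", {
  st <- multilevel_decompose(matrix(rnorm(3000), 60, 50), 3)
  expect_length(st, 3)
  expect_equal(dim(st[[1]]$LL), c(30, 25))
  expect_equal(dim(st[[2]]$LL), c(15, 13))
  expect_equal(dim(st[[3]]$LL), c(8, 7))
  # level k decomposes level (k-1)'s LL
  expect_equal(st[[2]]$HH, haar_dwt2(st[[1]]$LL)$HH)
  st2 <- multilevel_decompose(matrix(rnorm(64 * 64), 64, 64), 2)
  expect_equal(dim(st2[[1]]$LL), c(32, 32))
  expect_equal(dim(st2[[2]]$LL), c(16, 16))
  expect_length(multilevel_decompose(diag(4), 1), 1)
  expect_error(multilevel_decompose(diag(4), 0), "levels")
})

test_that("stacking fixes the channel order LL, HL, LH, HH", {
  sb <- haar_dwt2(matrix(rnorm(3000), 60, 50))
  st <- stack_subbands(sb)
  expect_equal(dim(st), c(30, 25, 4))
  expect_equal(st[, , 1], sb$LL)
  expect_equal(st[, , 2], sb$HL)
  expect_equal(st[, , 3], sb$LH)
  expect_equal(st[, , 4], sb$HH)
})

test_that("degenerate inputs are rejected", {
  expect_error(haar_dwt2(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(haar_dwt2(matrix(c(1, NA), 1, 2)), "finite")
  bad <- haar_dwt2(diag(4)); bad$HH <- matrix(0, 3, 3)
  expect_error(haar_idwt2(bad), "share one shape")
})
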