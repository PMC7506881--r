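# Primitive tensor ops for the network engine.  Activations are
# "channel matrices": N x c with N = h*w*n_batch (spatial-major,
# per-sample blocks) carrying a `spatial` attribute c(h, w, n).  This
# layout avoids transposes around the im2col GEMMs, makes channel
# concatenation a cbind and batch-norm a column operation.  The heavy
# per-element work lives in the C++ kernels; convolution columns are
# recomputed in the backward pass instead of cached (they are an order
# of magnitude larger than the activations).

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

chmat <- function(m, hwn) {
  attr(m, "spatial") <- hwn
  m
}

spatial <- function(m) attr(m, "spatial")

# Forward through one conv layer (optionally pre-activated BN+ReLU).
conv_layer_forward <- function(x, p, layer, training) {
  hwn <- spatial(x)
  cache <- list()
  if (isTRUE(layer$preact)) {
    if (training) {
      bn <- cpp_bn_relu_fw(x, p$gamma, p$beta, numeric(0), numeric(0),
                           TRUE, BN_EPS)
    } else {
      # bias-corrected running moments (the exponential averages start
      # from zero, so short trainings would otherwise predict with
      # statistics shrunk toward the initial state)
      t_bn <- p$bn_t %||% 0L
      if (t_bn > 0) {
        corr <- 1 - BN_MOMENTUM^t_bn
        rm <- p$running_mean / corr
        rv <- p$running_var / corr
      } else {
        rm <- numeric(length(p$gamma))
        rv <- rep(1, length(p$gamma))
      }
      bn <- cpp_bn_relu_fw(x, p$gamma, p$beta, rm, rv, FALSE, BN_EPS)
    }
    a <- bn$a
    cache$mu <- bn$mu
    cache$istd <- bn$istd
    cache$a <- a
    if (training) {
      cache$new_running <- list(
        mean = BN_MOMENTUM * p$running_mean + (1 - BN_MOMENTUM) * bn$mu,
        var = BN_MOMENTUM * p$running_var +
          (1 - BN_MOMENTUM) * (1 / bn$istd^2 - BN_EPS),
        t = (p$bn_t %||% 0L) + 1L)
    }
  } else {
    a <- x
  }
  k <- layer$k
  y <- cpp_conv_fw(a, hwn[1], hwn[2], hwn[3], p$W, p$b, k, (k - 1L) %/% 2L)
  list(out = chmat(y, hwn), cache = cache)
}

conv_layer_backward <- function(dy, x, p, cache, layer, need_dx = TRUE) {
  hwn <- spatial(x)
  k <- layer$k
  pad <- (k - 1L) %/% 2L
  a <- if (isTRUE(layer$preact)) cache$a else x
  need_through <- need_dx || isTRUE(layer$preact)
  bb <- cpp_conv_bw(dy, a, hwn[1], hwn[2], hwn[3], p$W, k, pad, need_through)
  grads <- list(W = bb$dW, b = bb$db)
  dx <- NULL
  if (need_through) {
    da <- bb$dx
    if (isTRUE(layer$preact)) {
      bn <- cpp_bn_relu_bw(da, x, a, p$gamma, cache$mu, cache$istd, need_dx)
      grads$gamma <- bn$dgamma
      grads$beta <- bn$dbeta
      if (need_dx) dx <- chmat(bn$dx, hwn)
    } else if (need_dx) {
      dx <- chmat(da, hwn)
    }
  }
  list(dx = dx, grads = grads)
}

#' Softmax probabilities
#'
#' Numerically stable softmax: invariant to additive shifts of the
#' logits; entries are positive and sum to one.
#'
#' @param logits Finite numeric vector (length >= 2), or a matrix whose
#'   rows are per-sample logit vectors.
#' @return Probabilities with the same shape.
#' @examples
#' softmax(c(0, log(3)))  # 0.25, 0.75
#' @export
softmax <- function(logits) {
  if (length(logits) == 0) stop("empty logits", call. = FALSE)
  if (!all(is.finite(logits))) stop("logits must be finite", call. = FALSE)
  if (is.matrix(logits)) {
    e <- exp(logits - apply(logits, 1, max))
    e / rowSums(e)
  } else {
    e <- exp(logits - max(logits))
    e / sum(e)
  }
}

# Loss value and gradient wrt logits for a batch.
# probs: n x C (rows sum to 1), y: integer vector in 1..C.
loss_and_grad <- function(probs, y, loss_spec) {
  n <- nrow(probs)
  C <- ncol(probs)
  ic <- cbind(seq_len(n), y)
  pc <- clamp_p(probs[ic])
  if (loss_spec$mode == "cross_entropy") {
    loss <- mean(-log(pc))
    dz <- probs
    dz[ic] <- dz[ic] - 1
    dz <- dz / n
  } else {
    g <- loss_spec$gamma
    a <- if (length(loss_spec$alpha) == 1) rep(loss_spec$alpha, C) else loss_spec$alpha
    ac <- a[y]
    loss <- mean(-ac * (1 - pc)^g * log(pc))
    # dL/dp_c, then chain through softmax: dL/dz_j = dL/dp_c * p_c (1[j=c] - p_j)
    gpc <- ac * (g * (1 - pc)^(pmax(g - 1, 0)) * log(pc) - (1 - pc)^g / pc)
    scale <- gpc * pc / n
    dz <- -probs * scale
    dz[ic] <- dz[ic] + scale
  }
  list(loss = loss, dz = dz)
}

# Adam update applied on a params/state pair.
adam_step <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g * g
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
}
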