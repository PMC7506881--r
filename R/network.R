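#' Initialise network parameters for an architecture graph
#'
#' Fan-in scaled random initialisation for convolution and head weights
#' (He initialisation), unit-gamma/zero-beta batch-norm parameters, and
#' zero biases.  Deterministic for a fixed seed.
#'
#' @param graph An [build_mddnet()] graph.
#' @param seed Integer seed.
#' @return Object of class `mddnet_model`.
#' @export
mddnet_init <- function(graph = build_mddnet(), seed = 1L) {
  tr <- shape_trace(graph)
  ch_of <- stats::setNames(tr$c, tr$name)
  params <- list()
  with_seed(mix_seed(seed, "init"), {
    for (l in graph$layers) {
      if (l$kind == "conv") {
        cin <- ch_of[[l$inputs]]
        fan_in <- l$k * l$k * cin
        p <- list(W = matrix(rnorm(fan_in * l$filters, sd = sqrt(2 / fan_in)),
                             fan_in, l$filters),
                  b = numeric(l$filters))
        if (isTRUE(l$preact)) {
          p$gamma <- rep(1, cin); p$beta <- numeric(cin)
          # exponential averages start at zero and are bias-corrected at
          # inference time (see conv_layer_forward)
          p$running_mean <- numeric(cin); p$running_var <- numeric(cin)
          p$bn_t <- 0L
        }
        params[[l$name]] <- p
      } else if (l$kind == "softmax") {
        cin <- ch_of[[l$inputs]]
        params[[l$name]] <- list(W = matrix(rnorm(cin * l$filters,
                                                  sd = sqrt(2 / cin)),
                                            cin, l$filters),
                                 b = numeric(l$filters))
      }
    }
  })
  cls <- if (graph$config$classes == length(mddnet_classes()))
    mddnet_classes() else paste0("class", seq_len(graph$config$classes))
  structure(list(graph = graph, params = params, classes = cls,
                 trained = FALSE, history = NULL, epochs_done = 0L,
                 adam = NULL),
            class = "mddnet_model")
}

# Convert batch input arrays to channel matrices.
# img: (h, w, 1, n) array -> N x 1; dwt level: (h, w, 4, n) -> N x 4.
input_chmats <- function(inputs) {
  d <- dim(inputs$img)
  img <- chmat(matrix(as.vector(inputs$img), ncol = 1L), c(d[1], d[2], d[4]))
  dwt <- lapply(inputs$dwt, function(a) {
    da <- dim(a)
    chmat(matrix(aperm(a, c(1, 2, 4, 3)), ncol = da[3]),
          c(da[1], da[2], da[4]))
  })
  list(img = img, dwt = dwt)
}

# Forward pass over the graph.
# inputs: list(img = (h,w,1,n) array, dwt = list of (h,w,4,n) arrays).
# Returns list(probs = n x C, outs, caches).
forward_pass <- function(model, inputs, training = FALSE, keep = FALSE) {
  g <- model$graph
  cm <- input_chmats(inputs)
  outs <- new.env(parent = emptyenv())
  caches <- if (keep) new.env(parent = emptyenv()) else NULL
  probs <- NULL
  for (l in g$layers) {
    x <- if (length(l$inputs) == 1) get(l$inputs, envir = outs) else NULL
    val <- switch(l$kind,
      input = {
        if (l$name == "input_img") cm$img
        else cm$dwt[[as.integer(sub("input_dwt", "", l$name))]]
      },
      slice = chmat(x[, l$channel, drop = FALSE], spatial(x)),
      conv = {
        p <- model$params[[l$name]]
        r <- conv_layer_forward(x, p, l, training)
        if (keep) assign(l$name, r$cache, envir = caches)
        if (training && isTRUE(l$preact)) {
          model$params[[l$name]]$running_mean <- r$cache$new_running$mean
          model$params[[l$name]]$running_var <- r$cache$new_running$var
          model$params[[l$name]]$bn_t <- r$cache$new_running$t
        }
        r$out
      },
      avg_pool = {
        s <- spatial(x)
        chmat(cpp_avgpool_fw(x, s[1], s[2], s[3], l$k, 2L),
              c(pool_out(s[1:2]), s[3]))
      },
      max_pool = {
        s <- spatial(x)
        r <- cpp_maxpool_fw(x, s[1], s[2], s[3], l$k, 2L)
        if (keep) assign(l$name, r$argmax, envir = caches)
        chmat(r$out, c(pool_out(s[1:2]), s[3]))
      },
      concat = {
        parts <- lapply(l$inputs, function(nm) get(nm, envir = outs))
        sp <- vapply(parts, function(a) spatial(a)[1:2], numeric(2))
        if (any(sp != sp[, 1]))
          stop(sprintf("shape mismatch at concat layer '%s'", l$name),
               call. = FALSE)
        chmat(do.call(cbind, parts), spatial(parts[[1]]))
      },
      global_max_pool = {
        s <- spatial(x)
        r <- cpp_gmp_fw(x, s[1], s[2], s[3])
        if (keep) assign(l$name, r$argmax, envir = caches)
        r$out  # n x c matrix
      },
      softmax = {
        p <- model$params[[l$name]]
        z <- x %*% p$W + rep(p$b, each = nrow(x))  # n x C
        probs <- softmax(z)
        probs
      },
      stop("unknown kind")
    )
    assign(l$name, val, envir = outs)
  }
  list(probs = probs, outs = outs, caches = caches, model = model)
}

# Backward pass; dz is the n x C loss gradient at the logits.
# Returns parameter gradients keyed by layer name.
backward_pass <- function(model, fw, dz) {
  g <- model$graph
  outs <- fw$outs
  caches <- fw$caches
  grads_out <- new.env(parent = emptyenv())  # dL/d(layer output)
  pgrads <- list()
  add_grad <- function(nm, g_) {
    if (exists(nm, envir = grads_out, inherits = FALSE)) {
      prev <- get(nm, envir = grads_out)
      s <- spatial(prev) %||% NULL
      tot <- prev + g_
      if (!is.null(s)) tot <- chmat(tot, s)
      assign(nm, tot, envir = grads_out)
    } else assign(nm, g_, envir = grads_out)
  }
  stops_grad <- function(nm) g$layers[[nm]]$kind %in% c("input", "slice")
  for (l in rev(g$layers)) {
    if (l$kind == "input") next
    if (l$kind == "softmax") {
      x <- get(l$inputs, envir = outs)  # n x cin
      p <- model$params[[l$name]]
      pgrads[[l$name]] <- list(W = crossprod(x, dz), b = colSums(dz))
      add_grad(l$inputs, dz %*% t(p$W))
      next
    }
    if (!exists(l$name, envir = grads_out, inherits = FALSE)) next
    dy <- get(l$name, envir = grads_out)
    src <- l$inputs
    switch(l$kind,
      global_max_pool = {
        x <- get(src, envir = outs)
        add_grad(src, chmat(cpp_gmp_bw(dy, get(l$name, envir = caches),
                                       nrow(x)), spatial(x)))
      },
      max_pool = {
        x <- get(src, envir = outs)
        add_grad(src, chmat(cpp_maxpool_bw(dy, get(l$name, envir = caches),
                                           nrow(x)), spatial(x)))
      },
      avg_pool = {
        x <- get(src, envir = outs)
        s <- spatial(x)
        add_grad(src, chmat(cpp_avgpool_bw(dy, s[1], s[2], s[3], l$k, 2L), s))
      },
      conv = {
        x <- get(src, envir = outs)
        bb <- conv_layer_backward(dy, x, model$params[[l$name]],
                                  if (!is.null(caches) &&
                                      exists(l$name, envir = caches,
                                             inherits = FALSE))
                                    get(l$name, envir = caches) else NULL,
                                  l, need_dx = !stops_grad(src))
        pgrads[[l$name]] <- bb$grads
        if (!stops_grad(src)) add_grad(src, bb$dx)
      },
      slice = NULL,  # nothing trainable upstream of a subband slice
      concat = {
        off <- 0L
        for (nm in l$inputs) {
          part <- get(nm, envir = outs)
          ci <- ncol(part)
          if (!stops_grad(nm))
            add_grad(nm, chmat(dy[, off + seq_len(ci), drop = FALSE],
                               spatial(part)))
          off <- off + ci
        }
      }
    )
  }
  pgrads
}

#' Convert segment matrices to model input tensors
#'
#' Builds the image batch and the per-level stacked wavelet subband
#' batches consumed by the network, plus aligned label / identity
#' vectors.
#'
#' @param segments List of `segment_matrix` objects from
#'   [asfs_extract()].
#' @param levels Wavelet decomposition levels (default from the graph's
#'   configuration, 3).
#' @return List with `img` (h, w, 1, n), `dwt` (list of (h', w', 4, n)
#'   arrays), `y` (integer labels), `labels`, `subject_id`, `record_id`.
#' @export
segments_to_tensors <- function(segments, levels = 3L) {
  n <- length(segments)
  if (!n) stop("no segments", call. = FALSE)
  d <- dim(segments[[1]]$matrix)
  img <- array(0, c(d[1], d[2], 1L, n))
  dwt <- lapply(seq_len(levels), function(lv) {
    sh <- dwt_shape(d[1], d[2], lv)
    array(0, c(sh[1], sh[2], 4L, n))
  })
  for (i in seq_len(n)) {
    m <- segments[[i]]$matrix
    img[, , 1L, i] <- m
    st <- multilevel_decompose(m, levels)
    for (lv in seq_len(levels)) dwt[[lv]][, , , i] <- stack_subbands(st[[lv]])
  }
  labels <- vapply(segments, `[[`, "", "label")
  list(img = img, dwt = dwt, y = match(labels, mddnet_classes()),
       labels = labels,
       subject_id = vapply(segments, `[[`, "", "subject_id"),
       record_id = vapply(segments, `[[`, "", "record_id"))
}

slice_tensors <- function(tensors, idx) {
  list(img = tensors$img[, , , idx, drop = FALSE],
       dwt = lapply(tensors$dwt, function(a) a[, , , idx, drop = FALSE]),
       y = tensors$y[idx],
       labels = tensors$labels[idx],
       subject_id = tensors$subject_id[idx],
       record_id = tensors$record_id[idx])
}

#' Train the network
#'
#' Minibatch Adam training.  The loss is chosen by `loss_spec` (from
#' [select_loss()]): plain multiclass cross-entropy, or the focal loss
#' when class imbalance calls for it.  Per-epoch mean training loss and
#' training accuracy (accumulated from the training forward passes) are
#' recorded in the history, together with validation accuracy when a
#' validation set is supplied.  Training is deterministic for a fixed
#' seed.  Set `target_acc` to stop as soon as the epoch training
#' accuracy reaches the target.
#'
#' @param model An [mddnet_init()] model.
#' @param tensors Training data from [segments_to_tensors()].
#' @param loss_spec A `focal_loss_spec`; default chosen from the label
#'   counts via [select_loss()].
#' @param epochs Maximum epochs (default 100).
#' @param batch_size Minibatch size (default 50).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed Integer seed for shuffling (initialisation is seeded in
#'   [mddnet_init()]).
#' @param target_acc Optional early-stop threshold on training accuracy.
#' @param validation Optional tensors list for per-epoch validation
#'   accuracy.
#' @param verbose Print per-epoch progress.
#' @return The fitted model with `history` (data frame: epoch, loss,
#'   train_acc, val_acc).
#' @export
mddnet_train <- function(model, tensors, loss_spec = NULL, epochs = 100L,
                         batch_size = 50L, lr = 1e-3, seed = 1L,
                         target_acc = NULL, validation = NULL,
                         verbose = FALSE) {
  n <- length(tensors$y)
  if (!n) stop("empty training set", call. = FALSE)
  if (is.null(loss_spec)) {
    counts <- table(factor(tensors$y,
                           levels = seq_len(model$graph$config$classes)))
    loss_spec <- select_loss(as.vector(counts[counts > 0]))
  }
  if (epochs == 0L) return(model)
  if (is.null(model$adam)) {
    model$adam <- lapply(model$params, function(p) {
      lapply(p[intersect(names(p), c("W", "b", "gamma", "beta"))],
             function(v) list(m = v * 0, v = v * 0))
    })
    model$adam_t <- 0L
  }
  history <- model$history
  with_seed(mix_seed(seed, "train", model$epochs_done), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0; correct <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        batch <- slice_tensors(tensors, idx)
        fw <- forward_pass(model, batch, training = TRUE, keep = TRUE)
        model <- fw$model  # running BN stats updated
        lg <- loss_and_grad(fw$probs, batch$y, loss_spec)
        tot_loss <- tot_loss + lg$loss * length(idx)
        correct <- correct +
          sum(max.col(fw$probs, ties.method = "first") == batch$y)
        pg <- backward_pass(model, fw, lg$dz)
        model$adam_t <- model$adam_t + 1L
        for (nm in names(pg)) {
          for (pn in names(pg[[nm]])) {
            upd <- adam_step(model$params[[nm]][[pn]], pg[[nm]][[pn]],
                             model$adam[[nm]][[pn]], lr, model$adam_t)
            model$params[[nm]][[pn]] <- upd$p
            model$adam[[nm]][[pn]] <- upd$st
          }
        }
      }
      ep_loss <- tot_loss / n
      ep_acc <- correct / n
      val_acc <- NA_real_
      if (!is.null(validation)) {
        pr <- mddnet_predict(model, validation, batch_size = batch_size)
        val_acc <- mean(pr$class_index == validation$y)
      }
      model$epochs_done <- model$epochs_done + 1L
      history <- rbind(history,
                       data.frame(epoch = model$epochs_done, loss = ep_loss,
                                  train_acc = ep_acc, val_acc = val_acc))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  train acc %.3f%s",
                        model$epochs_done, ep_loss, ep_acc,
                        if (is.na(val_acc)) "" else sprintf("  val acc %.3f", val_acc)))
      if (!is.null(target_acc) && ep_acc >= target_acc) break
    }
  })
  model$history <- history
  model$trained <- TRUE
  model$loss_spec <- loss_spec
  model
}

#' Predict class probabilities and labels
#'
#' Runs the network in inference mode (batch-norm running statistics).
#' Ties at the argmax resolve to the lowest class index.
#'
#' @param model A (fitted) `mddnet_model`.
#' @param tensors Data from [segments_to_tensors()].
#' @param batch_size Forward batch size.
#' @return List with `probs` (n x C matrix), `class_index` and `label`.
#' @export
mddnet_predict <- function(model, tensors, batch_size = 100L) {
  n <- length(tensors$y %||% tensors$labels)
  if (is.null(n) || n == 0) n <- dim(tensors$img)[4]
  probs <- matrix(NA_real_, n, model$graph$config$classes)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- forward_pass(model, slice_tensors(tensors, idx), training = FALSE)
    probs[idx, ] <- fw$probs
  }
  colnames(probs) <- model$classes
  ci <- max.col(probs, ties.method = "first")
  list(probs = probs, class_index = ci, label = model$classes[ci])
}

#' @export
print.mddnet_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p)
    sum(vapply(p[intersect(names(p), c("W", "b", "gamma", "beta"))],
               length, 1)), 1))
  cat(sprintf("<mddnet_model> %s, %d trainable parameters, %s\n",
              paste(x$graph$config$input_shape, collapse = "x"), np,
              if (x$trained) sprintf("trained %d epochs", x$epochs_done)
              else "untrained"))
  invisible(x)
}
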