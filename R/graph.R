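# Declarative layer graph for the dual-branch network: a reformed densely
# connected branch over the raw segment image, and a wavelet branch over
# the multilevel Haar subbands, fused before the classification head.
#
# Primitive layer kinds: input, slice (channel select), conv (optionally
# pre-activated with BN+ReLU), avg_pool / max_pool (3x3, stride 2,
# ceiling output), concat (channel axis), global_max_pool, softmax
# (fully connected + softmax).  Rows of the published architecture table
# are marked via each layer's `display` name, in table order.

layer_spec <- function(name, kind, inputs = character(), display = NA_character_,
                       k = 3L, stride = 1L, filters = NA_integer_,
                       preact = FALSE, channel = NA_integer_,
                       shape = NULL) {
  list(name = name, kind = kind, inputs = inputs, display = display,
       k = k, stride = stride, filters = filters, preact = preact,
       channel = channel, shape = shape)
}

#' Default configuration of the dual-branch network
#'
#' Defaults are the tuned operating point used throughout: 60 x 50
#' single-channel input, 3 dense blocks of 3 composite layers with
#' growth rate 12 and bottleneck width 48, 3 wavelet decomposition
#' levels with per-subband conv blocks of widths 96 and 24 plus a
#' 12-channel stage-link convolution, and a 4-class softmax head.
#'
#' @param input_shape `c(h, w, channels)` of the segment image.
#' @param classes Number of output classes.
#' @param growth Channels added by each dense composite layer.
#' @param n_composite Composite layers per dense block.
#' @param bottleneck Width of the first conv of each composite layer.
#' @param levels Wavelet decomposition levels fed to the wavelet branch
#'   (1 to 3).
#' @param sub_filters Widths of the two per-subband convolutions.
#' @param link_filters Width of the stage-link convolution applied to the
#'   pooled previous stage.
#' @export
mddnet_config <- function(input_shape = c(60L, 50L, 1L), classes = 4L,
                          growth = 12L, n_composite = 3L, bottleneck = 48L,
                          levels = 3L, sub_filters = c(96L, 24L),
                          link_filters = 12L) {
  stopifnot(growth >= 1, n_composite >= 1, levels >= 1, classes >= 2)
  list(input_shape = as.integer(input_shape), classes = as.integer(classes),
       growth = as.integer(growth), n_composite = as.integer(n_composite),
       bottleneck = as.integer(bottleneck), levels = as.integer(levels),
       sub_filters = as.integer(sub_filters),
       link_filters = as.integer(link_filters))
}

#' Build the dual-branch architecture graph
#'
#' Constructs the declarative layer graph: the dense branch
#' (3x3x24 convolution, average pooling, three dense blocks separated by
#' transition blocks, max pooling), the wavelet branch (per-subband
#' two-convolution blocks at every decomposition level, stage
#' concatenations carrying 4 x 24 = 96 subband channels plus a
#' 12-channel link from the pooled previous stage, max pooling between
#' stages) and the fusion (channel concatenation, max pooling, global
#' max pooling, softmax).  Dense blocks concatenate their input with the
#' final composite layer's `growth` channels, so output channels are
#' input + growth; transition blocks halve the channels (floor) and
#' ceiling-halve the spatial dimensions.
#'
#' @param config A [mddnet_config()].
#' @return Object of class `mddnet_graph`.
#' @export
build_mddnet <- function(config = mddnet_config()) {
  cfg <- config
  ly <- list()
  add <- function(...) {
    l <- layer_spec(...)
    ly[[l$name]] <<- l
  }
  h <- cfg$input_shape[1]; w <- cfg$input_shape[2]
  add("input_img", "input", shape = cfg$input_shape)
  for (lv in seq_len(cfg$levels))
    add(sprintf("input_dwt%d", lv), "input",
        shape = c(dwt_shape(h, w, lv), 4L))

  # ---- dense branch ----
  add("conv1", "conv", "input_img", display = "Convolution2D", filters = 24L)
  add("ap1", "avg_pool", "conv1", display = "AveragePooling2D")
  prev <- "ap1"; ch <- 24L
  for (b in 1:3) {
    feats <- prev
    for (ci in seq_len(cfg$n_composite)) {
      cin_name <- if (length(feats) == 1) feats else {
        nm <- sprintf("db%d_c%d_in", b, ci)
        add(nm, "concat", feats)
        nm
      }
      add(sprintf("db%d_c%d_a", b, ci), "conv", cin_name,
          filters = cfg$bottleneck, preact = TRUE)
      add(sprintf("db%d_c%d_b", b, ci), "conv", sprintf("db%d_c%d_a", b, ci),
          filters = cfg$growth, preact = TRUE)
      feats <- c(feats, sprintf("db%d_c%d_b", b, ci))
    }
    out_nm <- sprintf("db%d_out", b)
    add(out_nm, "concat", c(prev, sprintf("db%d_c%d_b", b, cfg$n_composite)),
        display = sprintf("Dense block %d", b))
    ch <- ch + cfg$growth
    if (b < 3) {
      tc <- ch %/% 2L
      add(sprintf("t%d_conv", b), "conv", out_nm, filters = tc, preact = TRUE)
      add(sprintf("t%d_pool", b), "avg_pool", sprintf("t%d_conv", b),
          display = sprintf("Transition block %d", b))
      prev <- sprintf("t%d_pool", b)
      ch <- tc
    } else {
      add("mp_dense", "max_pool", out_nm, display = "Maxpooling2D")
    }
  }

  # ---- wavelet branch ----
  conv_block_no <- 0L
  for (lv in seq_len(cfg$levels)) {
    stage_inputs <- character()
    if (lv > 1) {
      add(sprintf("mp_w%d", lv - 1L), "max_pool", sprintf("c_w%d", lv - 1L),
          display = "Maxpooling2D")
      conv_block_no <- conv_block_no + 1L
      add(sprintf("link%d", lv), "conv", sprintf("mp_w%d", lv - 1L),
          display = sprintf("Conv block %d", conv_block_no),
          filters = cfg$link_filters, preact = TRUE)
    }
    conv_block_no <- conv_block_no + 1L
    for (sb in 1:4) {
      add(sprintf("w%d_s%d", lv, sb), "slice", sprintf("input_dwt%d", lv),
          channel = sb)
      add(sprintf("w%d_s%d_a", lv, sb), "conv", sprintf("w%d_s%d", lv, sb),
          filters = cfg$sub_filters[1])
      add(sprintf("w%d_s%d_b", lv, sb), "conv", sprintf("w%d_s%d_a", lv, sb),
          display = if (sb == 1) sprintf("Conv block %d", conv_block_no)
                    else NA_character_,
          filters = cfg$sub_filters[2], preact = TRUE)
      stage_inputs <- c(stage_inputs, sprintf("w%d_s%d_b", lv, sb))
    }
    if (lv > 1) stage_inputs <- c(stage_inputs, sprintf("link%d", lv))
    add(sprintf("c_w%d", lv), "concat", stage_inputs,
        display = sprintf("Concatenation %d", lv))
  }
  add(sprintf("mp_w%d", cfg$levels), "max_pool", sprintf("c_w%d", cfg$levels),
      display = "Maxpooling2D")
  # extra (undisplayed) pools so both branches meet at one spatial size
  wav_hw <- dwt_shape(h, w, cfg$levels)
  wav_hw <- ceiling(wav_hw / 2)
  dense_hw <- c(h, w)
  for (i in 1:4) dense_hw <- ceiling(dense_hw / 2)  # ap1 + 2 transitions + mp
  wav_last <- sprintf("mp_w%d", cfg$levels)
  extra <- 0L
  while (wav_hw[1] > dense_hw[1] || wav_hw[2] > dense_hw[2]) {
    extra <- extra + 1L
    nm <- sprintf("mp_w_extra%d", extra)
    add(nm, "max_pool", wav_last)
    wav_last <- nm
    wav_hw <- ceiling(wav_hw / 2)
  }

  # ---- fusion and head ----
  add("fuse", "concat", c("mp_dense", wav_last),
      display = sprintf("Concatenation %d", cfg$levels + 1L))
  add("mp_final", "max_pool", "fuse", display = "Maxpooling2D")
  add("gmp", "global_max_pool", "mp_final", display = "GlobalMaxPooling2D")
  add("head", "softmax", "gmp", display = "Softmax", filters = cfg$classes)

  g <- structure(list(layers = ly, config = cfg), class = "mddnet_graph")
  shape_trace(g)  # validates shape consistency at build time
  g
}

pool_out <- function(hw) c(ceiling(hw[1] / 2), ceiling(hw[2] / 2))

#' Static shape trace of an architecture graph
#'
#' Computes every layer's output shape: stride-1 same-padded
#' convolutions keep spatial size, stride-2 pooling uses ceiling
#' division, concatenation sums channels (and fails with a structured
#' error naming the layer if the spatial shapes disagree).
#'
#' @param graph An `mddnet_graph`.
#' @param input_shape Optional override of the image input shape.
#' @return Data frame with columns `name`, `display`, `h`, `w`, `c`
#'   (spatial dims are `NA` for vector-valued layers).
#' @export
shape_trace <- function(graph, input_shape = NULL) {
  stopifnot(inherits(graph, "mddnet_graph"))
  shapes <- list()
  rows <- list()
  for (l in graph$layers) {
    s <- switch(l$kind,
      input = {
        sh <- l$shape
        if (l$name == "input_img" && !is.null(input_shape)) sh <- input_shape
        sh
      },
      slice = {
        s_in <- shapes[[l$inputs]]
        c(s_in[1], s_in[2], 1L)
      },
      conv = {
        s_in <- shapes[[l$inputs]]
        c(s_in[1], s_in[2], l$filters)
      },
      avg_pool = ,
      max_pool = {
        s_in <- shapes[[l$inputs]]
        c(pool_out(s_in[1:2]), s_in[3])
      },
      concat = {
        ins <- lapply(l$inputs, function(nm) shapes[[nm]])
        hw <- vapply(ins, function(s) s[1:2], numeric(2))
        if (any(hw != hw[, 1]))
          stop(sprintf("shape mismatch at concat layer '%s': inputs %s have spatial shapes %s",
                       l$name, paste(l$inputs, collapse = ", "),
                       paste(apply(hw, 2, paste, collapse = "x"), collapse = ", ")),
               call. = FALSE)
        c(ins[[1]][1:2], sum(vapply(ins, function(s) s[3], numeric(1))))
      },
      global_max_pool = {
        s_in <- shapes[[l$inputs]]
        c(NA_integer_, NA_integer_, s_in[3])
      },
      softmax = c(NA_integer_, NA_integer_, l$filters),
      stop(sprintf("unknown layer kind '%s'", l$kind), call. = FALSE)
    )
    shapes[[l$name]] <- s
    rows[[l$name]] <- data.frame(name = l$name, display = l$display,
                                 h = s[1], w = s[2], c = s[3])
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Architecture summary table
#'
#' The graph's named rows (one per row of the published architecture
#' table, in order) with their output shapes.
#'
#' @param graph An `mddnet_graph`.
#' @return Data frame with columns `layer` and `output_shape` (strings
#'   like `"(60, 50, 24)"`, or `"(135)"` / `"4"` for vector layers).
#' @export
shape_table <- function(graph) {
  tr <- shape_trace(graph)
  tr <- tr[!is.na(tr$display), ]
  fmt <- function(h, w, c, display) {
    if (display == "Softmax") sprintf("%d", c)
    else if (is.na(h)) sprintf("(%d)", c)
    else sprintf("(%d, %d, %d)", h, w, c)
  }
  data.frame(layer = tr$display,
             output_shape = mapply(fmt, tr$h, tr$w, tr$c, tr$display),
             row.names = NULL)
}

#' @export
print.mddnet_graph <- function(x, ...) {
  cat(sprintf("<mddnet_graph> %d layers (%d displayed rows), input %s, %d classes\n",
              length(x$layers), sum(!is.na(vapply(x$layers, `[[`, "", "display"))),
              paste(x$config$input_shape, collapse = "x"), x$config$classes))
  print(shape_table(x), right = FALSE)
  invisible(x)
}
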