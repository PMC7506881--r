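#' Single-level 2-D orthonormal Haar wavelet transform
#'
#' Decomposes a matrix (a segment image) into four subbands using the
#' separable orthonormal Haar filters (coefficients `1/sqrt(2)`), analysing
#' the vertical (row) axis first and then the horizontal (column) axis.
#' Odd-length axes are symmetrically extended by replicating the trailing
#' edge sample, so the output dimensions are `ceiling(dim(m)/2)`.
#'
#' Subband naming: the first letter is the filter applied along the
#' horizontal axis (matrix columns), the second along the vertical axis
#' (rows), so `HL` carries horizontal detail (vertical edges) and `LH`
#' vertical detail; on a 2x2 block `[a b; c d]` the four coefficients
#' are `(a+b+c+d)/2`, `(a-b+c-d)/2`, `(a+b-c-d)/2`, `(a-b-c+d)/2`.  For
#' even-dimension inputs the transform is orthonormal: the total energy
#' (sum of squares) of the four subbands equals that of the input, and
#' [haar_idwt2()] reconstructs the input exactly.
#'
#' @param m Numeric matrix with at least one row and column, all finite.
#' @return An object of class `subband_set`: a list with matrices `LL`,
#'   `HL`, `LH`, `HH` (all `ceiling(nrow/2) x ceiling(ncol/2)`) and the
#'   decomposition `level` (1 for a direct call).
#' @seealso [multilevel_decompose()], [haar_idwt2()], [stack_subbands()]
#' @examples
#' sb <- haar_dwt2(matrix(1:12, 3, 4))
#' dim(sb$LL)  # 2 x 2
#' @export
haar_dwt2 <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) < 1 || ncol(m) < 1)
    stop("`m` must be a non-empty numeric matrix", call. = FALSE)
  if (!all(is.finite(m)))
    stop("`m` must be finite", call. = FALSE)
  if (nrow(m) %% 2L) m <- rbind(m, m[nrow(m), , drop = FALSE])
  if (ncol(m) %% 2L) m <- cbind(m, m[, ncol(m), drop = FALSE])
  s2 <- sqrt(2)
  ro <- seq(1L, nrow(m), by = 2L)
  lo_v <- (m[ro, , drop = FALSE] + m[ro + 1L, , drop = FALSE]) / s2
  hi_v <- (m[ro, , drop = FALSE] - m[ro + 1L, , drop = FALSE]) / s2
  co <- seq(1L, ncol(m), by = 2L)
  structure(list(
    LL = (lo_v[, co, drop = FALSE] + lo_v[, co + 1L, drop = FALSE]) / s2,
    HL = (lo_v[, co, drop = FALSE] - lo_v[, co + 1L, drop = FALSE]) / s2,
    LH = (hi_v[, co, drop = FALSE] + hi_v[, co + 1L, drop = FALSE]) / s2,
    HH = (hi_v[, co, drop = FALSE] - hi_v[, co + 1L, drop = FALSE]) / s2,
    level = 1L
  ), class = "subband_set")
}

#' Inverse single-level 2-D Haar transform
#'
#' Reconstructs the matrix that produced a [haar_dwt2()] subband set.
#' Exact (to numerical round-off) for subbands originating from an
#' even-dimension analysis; used as the round-trip verification oracle.
#'
#' @param sb A `subband_set` whose four matrices share one shape.
#' @return Numeric matrix of dimension `2 * dim(sb$LL)`.
#' @export
haar_idwt2 <- function(sb) {
  if (!inherits(sb, "subband_set"))
    stop("`sb` must be a subband_set", call. = FALSE)
  dims <- vapply(sb[c("LL", "HL", "LH", "HH")], dim, integer(2))
  if (any(dims != dims[, 1]))
    stop("subband matrices must share one shape", call. = FALSE)
  s2 <- sqrt(2)
  h2 <- nrow(sb$LL); w2 <- ncol(sb$LL)
  lo_v <- hi_v <- matrix(0, h2, 2L * w2)
  co <- seq(1L, 2L * w2, by = 2L)
  lo_v[, co] <- (sb$LL + sb$HL) / s2
  lo_v[, co + 1L] <- (sb$LL - sb$HL) / s2
  hi_v[, co] <- (sb$LH + sb$HH) / s2
  hi_v[, co + 1L] <- (sb$LH - sb$HH) / s2
  m <- matrix(0, 2L * h2, 2L * w2)
  ro <- seq(1L, 2L * h2, by = 2L)
  m[ro, ] <- (lo_v + hi_v) / s2
  m[ro + 1L, ] <- (lo_v - hi_v) / s2
  m
}

#' Multilevel 2-D Haar decomposition
#'
#' Applies [haar_dwt2()] repeatedly: level 1 decomposes the input and each
#' further level decomposes the previous level's approximation (`LL`)
#' subband, the standard pyramid used to feed the wavelet branch of the
#' network.  A 60 x 50 segment image yields subband shapes 30 x 25,
#' 15 x 13 and 8 x 7 at levels 1-3.
#'
#' @param m Numeric matrix.
#' @param levels Number of decomposition levels (>= 1, default 3).
#' @return An object of class `decomposition_stack`: a list of
#'   `subband_set`s for levels `1:levels`.
#' @export
multilevel_decompose <- function(m, levels = 3L) {
  if (length(levels) != 1L || !is.finite(levels) || levels < 1)
    stop("`levels` must be >= 1", call. = FALSE)
  levels <- as.integer(levels)
  out <- vector("list", levels)
  cur <- m
  for (l in seq_len(levels)) {
    sb <- haar_dwt2(cur)
    sb$level <- l
    out[[l]] <- sb
    cur <- sb$LL
  }
  structure(out, class = "decomposition_stack")
}

#' Stack a subband set into a 4-channel feature map
#'
#' Concatenates the four subbands of one level along a channel axis in the
#' fixed order `(LL, HL, LH, HH)`, the order consumed by the network's
#' wavelet branch.
#'
#' @param sb A `subband_set`.
#' @return A 3-d array of dimension `c(dim(sb$LL), 4)`.
#' @export
stack_subbands <- function(sb) {
  if (!inherits(sb, "subband_set"))
    stop("`sb` must be a subband_set", call. = FALSE)
  array(c(sb$LL, sb$HL, sb$LH, sb$HH), dim = c(dim(sb$LL), 4L),
        dimnames = NULL)
}

# Shape of the level-L subbands of an h x w input (ceiling halving).
dwt_shape <- function(h, w, level) {
  for (i in seq_len(level)) { h <- ceiling(h / 2); w <- ceiling(w / 2) }
  c(h, w)
}
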