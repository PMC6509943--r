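## Convolution / pooling primitives.
##
## All convolutions are stride-1 valid cross-correlations followed by a
## per-filter bias and relu; all poolings are stride-1 (overlapping)
## sliding maxima, as pinned by the published output-index ranges. The
## batched kernels keep the minibatch as the trailing array dimension and
## lower each convolution to one im2col + GEMM in compiled code
## (src/kernels.cpp); pooling captures argmaxes so its backward pass is a
## scatter-add.

#' Zero-pad a matrix border
#'
#' Adds one row and one column of zeros on every side, so a 2 x n_t feature
#' matrix becomes the 4 x (n_t + 2) padded input of the first convolution.
#'
#' @param M numeric matrix (non-empty).
#' @return `(h + 2) x (w + 2)` matrix with `M` in its interior.
#' @export
pad_border <- function(M) {
  if (!is.matrix(M) || length(M) == 0L) stopf("pad_border: input must be a non-empty matrix")
  out <- matrix(0, nrow(M) + 2L, ncol(M) + 2L)
  out[2L:(nrow(M) + 1L), 2L:(ncol(M) + 1L)] <- M
  out
}

## Coerce a (c, h, w) array or (h, w) matrix to (c, h, w, 1).
as_chw1 <- function(X) {
  if (is.matrix(X)) X <- array(X, dim = c(1L, dim(X)))
  if (length(dim(X)) == 3L) dim(X) <- c(dim(X), 1L)
  X
}

#' Convolution forward pass
#'
#' Stride-1 valid cross-correlation over all input channels, plus a
#' per-filter bias and elementwise relu.
#'
#' @param X input, `(channels, h, w)` array or `(h, w)` matrix.
#' @param W filter bank, `(filters, channels, k_h, k_w)` array.
#' @param b bias vector of length `filters`.
#' @param relu apply relu (default `TRUE`).
#' @return `(filters, h - k_h + 1, w - k_w + 1)` array.
#' @export
conv_forward <- function(X, W, b, relu = TRUE) {
  X <- as_chw1(X)
  Z <- conv_fwd_batch(X, W, b, relu = relu)$Z
  array(Z, dim = dim(Z)[1:3])
}

#' Max-pooling forward pass
#'
#' Stride-1 sliding maximum over `n_g x n_p` windows, per channel.
#'
#' @param X input, `(channels, h, w)` array or `(h, w)` matrix.
#' @param n_g,n_p pooling window width (rows) and length (columns).
#' @return `(channels, h - n_g + 1, w - n_p + 1)` array.
#' @export
maxpool_forward <- function(X, n_g = 2L, n_p = 2L) {
  X <- as_chw1(X)
  Z <- maxpool_fwd_batch(X, n_g, n_p)$out
  array(Z, dim = dim(Z)[1:3])
}

## --- batched kernels (batch = trailing dimension) --------------------------

## Returns list(Z, cols); cols is the im2col matrix reused by the backward
## pass. pad = TRUE applies the one-cell zero border implicitly.
conv_fwd_batch <- function(X, W, b, relu = TRUE, pad = FALSE) {
  cpp_conv_fwd(X, dim(X), W, dim(W), b, relu, pad)
}

## Backward of conv_fwd_batch. Zpost is the (post-relu) forward output; its
## positivity encodes the relu mask. dX comes back on the unpadded geometry.
conv_bwd_batch <- function(cols, xdim, W, dZ, Zpost, relu = TRUE, pad = FALSE) {
  cpp_conv_bwd(cols, xdim, W, dim(W), dZ, Zpost, relu, pad)
}

## Returns list(out, argmax); argmax feeds the backward scatter.
maxpool_fwd_batch <- function(X, n_g, n_p) {
  cpp_maxpool_fwd(X, dim(X), n_g, n_p)
}

maxpool_bwd_batch <- function(dOut, argmax, xdim) {
  cpp_maxpool_bwd(dOut, argmax, xdim)
}
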