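## Pairwise feature matrix for one (lncRNA, disease) pair.
##
## For lncRNA l and disease d, the model input is the 2 x n_t matrix
## (n_t = n_l + n_d + n_m) formed from six relationship vectors:
##
##   row 1: [ x1 = L[l, ]  | x3 = A[l, ]  | x5 = Y[l, ]  ]   (lncRNA side)
##   row 2: [ x2 = A[, d]  | x4 = D[d, ]  | x6 = B[, d]  ]   (disease side)
##
## The lncRNA block pairs l's similarity profile with d's known lncRNA
## partners; the disease block pairs l's known diseases with d's similarity
## profile; the miRNA block pairs l's miRNA interactions with d's miRNA
## associations. Shared partners across a column are the association
## evidence the convolutional model learns to detect.
##
## Fold masking happens upstream: the caller passes the training-masked
## copy of A (held-out positives zeroed), so no masking logic lives here.

#' Build the pairwise feature matrix
#'
#' @param net a `hetero_network`.
#' @param l,d lncRNA and disease indices (1-based).
#' @param L_active lncRNA similarity matrix to use; defaults to `net$L`.
#'   During cross-validation pass the training-recomputed similarity.
#' @param A_active association matrix to use; defaults to `net$A`. During
#'   cross-validation pass the fold-masked copy.
#' @param mask_self_cell zero the `A[l, d]` cell in the pair's own vectors
#'   (`x2`/`x3`) before assembly (default `FALSE`; the target cell is used
#'   as stored).
#' @return An object of class `feature_matrix`: list with `values`
#'   (2 x n_t), `segments` (named list of column ranges for the lncRNA,
#'   disease and miRNA blocks) and `pair = c(l, d)`.
#' @export
build_feature_matrix <- function(net, l, d, L_active = net$L,
                                 A_active = net$A, mask_self_cell = FALSE) {
  idx <- net$index
  if (!is_count(l) || l > idx$n_l) stopf("lncRNA index %s out of range [1, %d]", l, idx$n_l)
  if (!is_count(d) || d > idx$n_d) stopf("disease index %s out of range [1, %d]", d, idx$n_d)
  A <- A_active
  if (mask_self_cell) A[l, d] <- 0
  row_l <- c(L_active[l, ], A[l, ], net$Y[l, ])
  row_d <- c(A[, d], net$D[d, ], net$B[, d])
  values <- rbind(row_l, row_d)
  dimnames(values) <- NULL
  structure(list(
    values = values,
    segments = feature_segments(idx$n_l, idx$n_d, idx$n_m),
    pair = c(l = as.integer(l), d = as.integer(d))
  ), class = "feature_matrix")
}

## Column ranges of the three blocks of the feature matrix.
feature_segments <- function(n_l, n_d, n_m) {
  list(lncrna  = seq_len(n_l),
       disease = n_l + seq_len(n_d),
       mirna   = n_l + n_d + seq_len(n_m))
}

#' Dump a feature matrix as annotated TSV (debug aid)
#'
#' @param fm a `feature_matrix`.
#' @param path output file.
#' @export
write_feature_matrix <- function(fm, path) {
  seg <- character(ncol(fm$values))
  for (nm in names(fm$segments)) seg[fm$segments[[nm]]] <- nm
  df <- data.frame(segment = seg, column = seq_along(seg),
                   lncrna_side = fm$values[1, ], disease_side = fm$values[2, ])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Batched builders used by the training engine. ------------------------------

## Feature matrices for a batch of pairs: returns array (2, n_t, B).
fm_batch <- function(net, pairs, L_active, A_active) {
  n_l <- net$index$n_l; n_d <- net$index$n_d; n_m <- net$index$n_m
  n_t <- n_l + n_d + n_m
  B <- nrow(pairs)
  li <- pairs[, 1]; di <- pairs[, 2]
  ## row 1 of each P: rows li of cbind(L, A, Y); row 2: rows di of
  ## cbind(t(A), D, t(B)).
  side_l <- cbind(L_active[li, , drop = FALSE], A_active[li, , drop = FALSE],
                  net$Y[li, , drop = FALSE])                    # B x n_t
  side_d <- cbind(t(A_active)[di, , drop = FALSE], net$D[di, , drop = FALSE],
                  t(net$B)[di, , drop = FALSE])                 # B x n_t
  out <- array(0, dim = c(2L, n_t, B))
  out[1L, , ] <- t(side_l)
  out[2L, , ] <- t(side_d)
  out
}

## Six relationship vectors per pair, zero-padded to n_max:
## returns array (n_max, 6, B); vector order x1..x6.
xvec_batch <- function(net, pairs, L_active, A_active) {
  n_l <- net$index$n_l; n_d <- net$index$n_d; n_m <- net$index$n_m
  n_max <- max(n_l, n_d, n_m)
  B <- nrow(pairs)
  li <- pairs[, 1]; di <- pairs[, 2]
  X <- array(0, dim = c(n_max, 6L, B))
  X[seq_len(n_l), 1L, ] <- t(L_active[li, , drop = FALSE])
  X[seq_len(n_l), 2L, ] <- A_active[, di, drop = FALSE]
  X[seq_len(n_d), 3L, ] <- t(A_active[li, , drop = FALSE])
  X[seq_len(n_d), 4L, ] <- t(net$D[di, , drop = FALSE])
  X[seq_len(n_m), 5L, ] <- t(net$Y[li, , drop = FALSE])
  X[seq_len(n_m), 6L, ] <- net$B[, di, drop = FALSE]
  X
}

## Validity masks for the six padded relationship vectors: (n_max, 6) logical.
xvec_masks <- function(n_l, n_d, n_m) {
  n_max <- max(n_l, n_d, n_m)
  M <- matrix(FALSE, n_max, 6L)
  M[seq_len(n_l), 1:2] <- TRUE
  M[seq_len(n_d), 3:4] <- TRUE
  M[seq_len(n_m), 5:6] <- TRUE
  M
}
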