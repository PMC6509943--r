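## Disease-set based lncRNA-lncRNA similarity.
##
## Two lncRNAs are compared through the diseases they are associated with:
## for disease sets DT_a (size m) and DT_b (size n),
##
##   LS(l_a, l_b) = [ sum_i max_j DS(d_ai, d_bj)
##                  + sum_j max_i DS(d_bj, d_ai) ] / (m + n)
##
## i.e. every disease of one lncRNA is matched to its most similar disease
## of the other, in both directions, and the matched similarities are
## averaged. LS is symmetric and lies in [0, 1] whenever DS does.
##
## When a lncRNA has no associated disease the quotient is undefined
## (m + n = 0 against an empty sum); the package defines similarity
## involving an empty set as 0 and forces unit self-similarity, keeping the
## diagonal usable in the feature matrix.

#' Similarity of two disease sets
#'
#' Evaluates the best-match average similarity between two sets of disease
#' indices under a disease-disease semantic similarity matrix.
#'
#' @param dt_a,dt_b integer vectors of disease indices (rows/columns of `D`);
#'   duplicates are ignored.
#' @param D disease similarity matrix with entries in `[0, 1]`.
#' @return A similarity in `[0, 1]`; 0 if either set is empty.
#' @export
lncrna_similarity_pair <- function(dt_a, dt_b, D) {
  if (any(D < 0)) stopf("disease similarity matrix has negative entries")
  a <- unique(as.integer(dt_a)); b <- unique(as.integer(dt_b))
  m <- length(a); n <- length(b)
  if (m == 0L || n == 0L) return(0)
  if (any(c(a, b) < 1L) || any(c(a, b) > nrow(D)))
    stopf("disease index out of range for a %d x %d similarity matrix", nrow(D), ncol(D))
  S <- D[a, b, drop = FALSE]
  (sum(apply(S, 1, max)) + sum(apply(S, 2, max))) / (m + n)
}

#' lncRNA similarity matrix from associations
#'
#' Computes the full `n_l x n_l` similarity matrix: entry `(i, j)` is the
#' best-match average similarity between the disease sets supported by rows
#' `i` and `j` of the association matrix `A`. The diagonal is forced to 1,
#' including for lncRNAs with an empty association profile.
#'
#' @param A binary `n_l x n_d` lncRNA-disease association matrix.
#' @param D disease similarity matrix (`n_d x n_d`, entries in `[0, 1]`).
#' @return Symmetric `n_l x n_l` matrix with unit diagonal.
#' @export
lncrna_similarity_matrix <- function(A, D) {
  if (!is.matrix(A) || !is.matrix(D)) stopf("A and D must be matrices")
  if (ncol(A) != nrow(D) || nrow(D) != ncol(D))
    stopf("dimension mismatch: A is %d x %d but D is %d x %d",
          nrow(A), ncol(A), nrow(D), ncol(D))
  if (!is_binary(A)) stopf("A must be binary")
  if (any(D < 0)) stopf("disease similarity matrix has negative entries")
  n_l <- nrow(A)
  sets <- lapply(seq_len(n_l), function(i) which(A[i, ] == 1))
  sizes <- lengths(sets)
  L <- diag(1, n_l)
  if (n_l >= 2L) {
    for (i in seq_len(n_l - 1L)) {
      if (sizes[i] == 0L) next
      a <- sets[[i]]
      for (j in seq.int(i + 1L, n_l)) {
        if (sizes[j] == 0L) next
        S <- D[a, sets[[j]], drop = FALSE]
        ## row/column maxima of the cross-similarity block, averaged
        rm_ <- if (ncol(S) == 1L) S[, 1L] else do.call(pmax, asplit(S, 2))
        cm_ <- if (nrow(S) == 1L) S[1L, ] else do.call(pmax, asplit(S, 1))
        L[i, j] <- L[j, i] <- (sum(rm_) + sum(cm_)) / (sizes[i] + sizes[j])
      }
    }
  }
  L
}

#' Recompute lncRNA similarity from training associations only
#'
#' During cross-validation the lncRNA similarities must not see held-out
#' positives: an association matrix containing 1 only at the supplied
#' training pairs is built and the similarity recomputed from it. The input
#' network is never modified.
#'
#' @param net a `hetero_network`.
#' @param training_pairs two-column matrix/data.frame of (lncRNA index,
#'   disease index) training positives; must be a subset of the support of
#'   `net$A`.
#' @return `n_l x n_l` training-only similarity matrix.
#' @export
recompute_training_similarity <- function(net, training_pairs) {
  tp <- as.matrix(training_pairs)
  if (ncol(tp) != 2L) stopf("training_pairs must have two columns")
  storage.mode(tp) <- "integer"
  A_train <- matrix(0, net$index$n_l, net$index$n_d)
  if (nrow(tp) > 0L) {
    if (any(net$A[tp] != 1))
      stopf("training pair outside the support of A (label leakage guard)")
    A_train[tp] <- 1
  }
  lncrna_similarity_matrix(A_train, net$D)
}
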