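## Feature-level and relationship-level attention.
##
## The six relationship vectors x_1..x_6 of a pair have unequal lengths
## (n_l, n_l, n_d, n_d, n_m, n_m) yet share one projection at the feature
## level and are summed at the relationship level. They are therefore
## zero-padded to a common length n_max = max(n_l, n_d, n_m) with validity
## masks; softmaxes run over valid positions only, and the shared
## projections have width n_max.
##
## Feature level (per vector x_i):
##   s_i   = H_F tanh(W_xF x_i + b_F)          scores per position
##   alpha = masked softmax(s_i)               weights, sum 1 over valid
##   y_i   = alpha * x_i                       elementwise
## Relationship level (across the six y_i):
##   s_i^R = h_R tanh(W_yR y_i + b_R)          scalar score per vector
##   beta  = softmax(s^R) over the 6 vectors
##   g     = sum_i beta_i y_i

#' Feature-level attention over one relationship vector
#'
#' @param x numeric vector padded to length `n_max`.
#' @param mask logical vector marking valid positions (at least one).
#' @param params model parameters (uses `H_F`, `W_xF`, `b_F`).
#' @return List with `y` (reweighted vector), `alpha` (weights summing to 1
#'   over valid positions, 0 elsewhere) and `scores`.
#' @export
feature_attention <- function(x, mask, params) {
  if (!any(mask)) stopf("feature_attention: mask has no valid positions")
  s <- as.vector(params$H_F %*% tanh(params$W_xF %*% x + params$b_F))
  s[!mask] <- -Inf
  e <- exp(s - max(s))
  alpha <- e / sum(e)
  list(y = alpha * x, alpha = alpha, scores = s)
}

#' Relationship-level attention over the six reweighted vectors
#'
#' @param y_set list of six numeric vectors of common padded length.
#' @param params model parameters (uses `h_R`, `W_yR`, `b_R`).
#' @return List with `g` (the beta-weighted sum), `beta` (six weights
#'   summing to 1) and `scores`.
#' @export
relationship_attention <- function(y_set, params) {
  if (length(y_set) != 6L) stopf("relationship_attention: expected 6 vectors, got %d", length(y_set))
  Y <- do.call(cbind, y_set)
  s <- as.vector(params$h_R %*% tanh(params$W_yR %*% Y + as.vector(params$b_R)))
  e <- exp(s - max(s))
  beta <- e / sum(e)
  list(g = as.vector(Y %*% beta), beta = beta, scores = s)
}
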