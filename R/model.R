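## The dual-CNN scoring model.
##
## Left branch:  P (2 x n_t) -> border pad -> conv (n_conv1 filters) ->
##               stride-1 maxpool -> border pad -> conv (n_conv2) ->
##               maxpool -> Z_glo (n_conv2 x 2 x n_t with defaults).
## Right branch: six relationship vectors -> feature-level attention ->
##               relationship-level attention -> g -> border pad ->
##               conv (n_att_conv) -> maxpool -> Z_att (n_att_conv x 1 x
##               n_max).
## Final:        Z_att right-padded to width n_t, stacked under Z_glo ->
##               border pad -> conv (n_final) -> maxpool -> flatten ->
##               fully connected + softmax -> p (2 classes; p[2] is the
##               association score).
##
## Training minimizes sum of cross-entropy over each minibatch plus
## lambda * ||theta||^2 (all weights and biases) with Adam. The backward
## pass is analytic; see tests for the finite-difference check.

#' Initialize model parameters
#'
#' Weight banks are drawn from fan-in-scaled normals
#' (`sd = sqrt(2 / fan_in)`), biases start at zero. Driven by `cfg$seed`.
#'
#' @param cfg a `model_config`.
#' @param n_l,n_d,n_m entity counts.
#' @return Named list of parameter arrays (class `model_parameters`).
#' @export
init_parameters <- function(cfg, n_l, n_d, n_m) {
  shapes <- infer_shapes(cfg, n_l, n_d, n_m)
  n_max <- shapes$n_max
  ah <- cfg$attention_hidden
  with_seed(cfg$seed, {
    rnorm_arr <- function(dims, fan_in) {
      array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
    }
    p <- list(
      W_conv1 = rnorm_arr(c(cfg$n_conv1, 1L, cfg$n_w, cfg$n_f), cfg$n_w * cfg$n_f),
      b_conv1 = numeric(cfg$n_conv1),
      W_conv2 = rnorm_arr(c(cfg$n_conv2, cfg$n_conv1, cfg$n_w, cfg$n_f),
                          cfg$n_conv1 * cfg$n_w * cfg$n_f),
      b_conv2 = numeric(cfg$n_conv2),
      W_xF = rnorm_arr(c(ah, n_max), n_max),
      b_F  = numeric(ah),
      H_F  = rnorm_arr(c(n_max, ah), ah),
      W_yR = rnorm_arr(c(ah, n_max), n_max),
      b_R  = numeric(ah),
      h_R  = rnorm_arr(c(1L, ah), ah),
      W_attconv = rnorm_arr(c(cfg$n_att_conv, 1L, cfg$n_w, cfg$n_f), cfg$n_w * cfg$n_f),
      b_attconv = numeric(cfg$n_att_conv),
      W_fin = rnorm_arr(c(cfg$n_final, cfg$n_conv2, cfg$n_w, cfg$n_f),
                        cfg$n_conv2 * cfg$n_w * cfg$n_f),
      b_fin = numeric(cfg$n_final),
      W_out = rnorm_arr(c(cfg$C, shapes$z_o), shapes$z_o),
      b_o   = numeric(cfg$C)
    )
    structure(p, class = "model_parameters",
              counts = c(n_l = n_l, n_d = n_d, n_m = n_m))
  })
}

#' Left convolutional module forward pass
#'
#' @param P a `feature_matrix` or a 2 x n_t numeric matrix.
#' @param params model parameters.
#' @param cfg a `model_config`.
#' @return `Z_glo`, array `(n_conv2, rows, n_t)` (2 rows with defaults).
#' @export
left_module_forward <- function(P, params, cfg) {
  M <- if (inherits(P, "feature_matrix")) P$values else P
  X <- array(M, dim = c(1L, nrow(M), ncol(M), 1L))
  Z1 <- conv_fwd_batch(X, params$W_conv1, params$b_conv1, pad = TRUE)$Z
  P1 <- maxpool_fwd_batch(Z1, cfg$n_g, cfg$n_p)$out
  Z2 <- conv_fwd_batch(P1, params$W_conv2, params$b_conv2, pad = TRUE)$Z
  P2 <- maxpool_fwd_batch(Z2, cfg$n_g, cfg$n_p)$out
  array(P2, dim = dim(P2)[1:3])
}

#' Attention module forward pass
#'
#' Runs feature-level and relationship-level attention over the six
#' relationship vectors of a feature matrix, then the attention branch's
#' convolution and pooling.
#'
#' @param fm a `feature_matrix` (segments are needed to split the six
#'   vectors).
#' @param params model parameters.
#' @param cfg a `model_config`.
#' @return List with `Z_att` (array `(n_att_conv, rows, n_max)`), `g`,
#'   `beta` (six relationship weights) and `alpha` (list of six
#'   feature-weight vectors).
#' @export
attention_module_forward <- function(fm, params, cfg) {
  seg <- fm$segments
  n_l <- length(seg$lncrna); n_d <- length(seg$disease); n_m <- length(seg$mirna)
  n_max <- max(n_l, n_d, n_m)
  masks <- xvec_masks(n_l, n_d, n_m)
  pad_to <- function(v) c(v, numeric(n_max - length(v)))
  xs <- list(pad_to(fm$values[1, seg$lncrna]),  pad_to(fm$values[2, seg$lncrna]),
             pad_to(fm$values[1, seg$disease]), pad_to(fm$values[2, seg$disease]),
             pad_to(fm$values[1, seg$mirna]),   pad_to(fm$values[2, seg$mirna]))
  fa <- lapply(1:6, function(i) feature_attention(xs[[i]], masks[, i], params))
  ra <- relationship_attention(lapply(fa, `[[`, "y"), params)
  G <- array(ra$g, dim = c(1L, 1L, n_max, 1L))
  Za <- conv_fwd_batch(G, params$W_attconv, params$b_attconv, pad = TRUE)$Z
  Pa <- maxpool_fwd_batch(Za, cfg$n_g, cfg$n_p)$out
  list(Z_att = array(Pa, dim = dim(Pa)[1:3]), g = ra$g, beta = ra$beta,
       alpha = lapply(fa, `[[`, "alpha"))
}

#' Final module forward pass
#'
#' Right-pads the attention representation to width `n_t`, stacks it under
#' the global representation, and applies the final convolution, pooling,
#' flattening and softmax output layer.
#'
#' @param Z_glo,Z_att branch outputs (channel counts must match).
#' @param params model parameters.
#' @param cfg a `model_config`.
#' @return List with `p` (probability vector of length 2; `p[2]` is the
#'   association score), `z_o` and `Z_fin`.
#' @export
final_forward <- function(Z_glo, Z_att, params, cfg) {
  if (dim(Z_glo)[1] != dim(Z_att)[1])
    stopf("channel mismatch between branches: %d vs %d", dim(Z_glo)[1], dim(Z_att)[1])
  if (dim(Z_att)[3] > dim(Z_glo)[3])
    stopf("attention representation wider than the global one (%d > %d)",
          dim(Z_att)[3], dim(Z_glo)[3])
  n_t <- dim(Z_glo)[3]
  ch <- dim(Z_glo)[1]
  rows <- dim(Z_glo)[2] + dim(Z_att)[2]
  Zc <- array(0, dim = c(ch, rows, n_t, 1L))
  Zc[, seq_len(dim(Z_glo)[2]), , 1L] <- Z_glo
  Zc[, dim(Z_glo)[2] + seq_len(dim(Z_att)[2]), seq_len(dim(Z_att)[3]), 1L] <- Z_att
  Zf <- conv_fwd_batch(Zc, params$W_fin, params$b_fin, pad = TRUE)$Z
  Pf <- maxpool_fwd_batch(Zf, cfg$n_g, cfg$n_p)$out
  z_o <- as.vector(Pf)
  logits <- as.vector(params$W_out %*% z_o + params$b_o)
  e <- exp(logits - max(logits))
  p <- e / sum(e)
  list(p = p, z_o = z_o, Z_fin = array(Pf, dim = dim(Pf)[1:3]))
}

#' Full forward pass for one pair
#'
#' @param fm a `feature_matrix`.
#' @param params model parameters.
#' @param cfg a `model_config`.
#' @return List with `p`, `score` (= `p[2]`), `beta`, `alpha`, `Z_glo`,
#'   `Z_att`.
#' @export
model_forward <- function(fm, params, cfg) {
  Z_glo <- left_module_forward(fm, params, cfg)
  att <- attention_module_forward(fm, params, cfg)
  fin <- final_forward(Z_glo, att$Z_att, params, cfg)
  list(p = fin$p, score = fin$p[2], beta = att$beta, alpha = att$alpha,
       Z_glo = Z_glo, Z_att = att$Z_att, z_o = fin$z_o)
}

#' Cross-entropy loss
#'
#' `-sum_j z_j log p_j` with probabilities clipped to `[1e-12, 1]`. For a
#' batch (matrix input, one column per sample) the losses are summed.
#'
#' @param p probability vector of length 2, or 2 x B matrix.
#' @param z one-hot label vector of length 2, or 2 x B matrix.
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(p, z) {
  p <- as.matrix(p); z <- as.matrix(z)
  if (!all(dim(p) == dim(z))) stopf("p and z must have matching dimensions")
  onehot <- apply(z, 2, function(col) sum(col == 1) == 1 && sum(col == 0) == length(col) - 1)
  if (!all(onehot)) stopf("z must be one-hot")
  -sum(z * log(pmin(pmax(p, 1e-12), 1)))
}

#' Regularized objective
#'
#' `loss + lambda * ||theta||^2`, the sum of squares running over every
#' trainable tensor, biases included.
#'
#' @param loss scalar training loss.
#' @param params model parameters.
#' @param lambda non-negative L2 trade-off.
#' @return Scalar objective value.
#' @export
objective <- function(loss, params, lambda) {
  if (lambda < 0) stopf("lambda must be non-negative")
  loss + lambda * sum(vapply(params, function(w) sum(w^2), 0))
}

## --- batched engine ---------------------------------------------------------

## All per-step work (forward and backward over a minibatch) runs inside a
## persistent compiled engine (src/engine.cpp) whose buffers are allocated
## once per shape/batch-capacity; see new_engine / cpp_engine_step. The
## kernel-level R functions above remain the reference path for the public
## single-sample API and for cross-checking the engine in tests.

new_engine <- function(cfg, n_l, n_d, n_m, capacity) {
  infer_shapes(cfg, n_l, n_d, n_m)   # validates the geometry, names bad layers
  cpp_engine_create(n_l, n_d, n_m, unclass(cfg), as.integer(capacity))
}

## Add the L2 term 2*lambda*theta to raw cross-entropy gradients.
add_l2_gradient <- function(grads, params, lambda) {
  if (lambda == 0) return(grads[names(params)])
  for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + 2 * lambda * params[[nm]]
  grads[names(params)]
}

#' Objective gradients for a sample batch (analytic backpropagation)
#'
#' Computes the gradient of `sum(cross-entropy) + lambda * ||theta||^2`
#' over a set of pairs, by the same backward pass used in training. Exposed
#' for gradient checking.
#'
#' @param net a `hetero_network`.
#' @param pairs two-column matrix of (lncRNA, disease) indices.
#' @param labels binary vector (1 = associated).
#' @param params model parameters.
#' @param cfg a `model_config`.
#' @param L_active,A_active matrices to build features from (defaults:
#'   `net$L`, `net$A`).
#' @return List with `objective` (scalar), `loss`, `p` (2 x n
#'   probabilities) and `gradients` (named list matching `params`).
#' @export
model_gradients <- function(net, pairs, labels, params, cfg,
                            L_active = net$L, A_active = net$A) {
  pairs <- as.matrix(pairs)
  idx <- net$index
  P2 <- fm_batch(net, pairs, L_active, A_active)
  Xa <- xvec_batch(net, pairs, L_active, A_active)
  Z <- rbind(1 - labels, labels)
  eng <- new_engine(cfg, idx$n_l, idx$n_d, idx$n_m, nrow(pairs))
  res <- cpp_engine_step(eng, P2, Xa, params, Z, nrow(pairs))
  obj <- objective(res$loss, params, cfg$lambda)
  grads <- add_l2_gradient(res$gradients, params, cfg$lambda)
  list(objective = obj, loss = res$loss, p = res$p, gradients = grads)
}

## --- training ---------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Train the model on a sample set
#'
#' Minimizes the regularized cross-entropy objective with Adam over
#' minibatches for `cfg$max_epochs` epochs. Identical seed, data and
#' configuration give identical histories and parameters.
#'
#' @param net a `hetero_network`.
#' @param samples list with `pairs` (two-column index matrix) and `labels`
#'   (binary vector), as produced by [make_cv_splits()].
#' @param cfg a `model_config`.
#' @param L_active,A_active feature sources (defaults: `net$L`, `net$A`);
#'   during cross-validation pass the fold's recomputed similarity and
#'   masked association matrix.
#' @param params optional warm-start parameters.
#' @param verbose print per-epoch objective (default `FALSE`).
#' @return List of class `cnnlda_model`: `params`, `cfg`, `history`
#'   (per-epoch mean objective per sample), `counts`.
#' @export
train_model <- function(net, samples, cfg, L_active = net$L, A_active = net$A,
                        params = NULL, verbose = FALSE) {
  pairs <- as.matrix(samples$pairs)
  labels <- as.numeric(samples$labels)
  n <- nrow(pairs)
  if (n == 0L) stopf("empty sample set")
  idx <- net$index
  if (is.null(params)) params <- init_parameters(cfg, idx$n_l, idx$n_d, idx$n_m)
  ## features are fixed during training: build once
  P2 <- fm_batch(net, pairs, L_active, A_active)
  Xa <- xvec_batch(net, pairs, L_active, A_active)
  if (cfg$mask_self_cell) {
    for (s in seq_len(n)) {
      l <- pairs[s, 1]; d <- pairs[s, 2]
      if (A_active[l, d] == 1) {
        P2[1L, idx$n_l + d, s] <- 0         # x3 entry for disease d
        P2[2L, l, s] <- 0                   # x2 entry for lncRNA l
        Xa[l, 2L, s] <- 0
        Xa[d, 3L, s] <- 0
      }
    }
  }
  Zlab <- rbind(1 - labels, labels)
  state <- adam_init(params)
  history <- numeric(cfg$max_epochs)
  eng <- new_engine(cfg, idx$n_l, idx$n_d, idx$n_m, min(cfg$batch_size, n))
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      epoch_obj <- 0
      for (s0 in starts) {
        bi <- ord[s0:min(s0 + cfg$batch_size - 1L, n)]
        res <- cpp_engine_step(eng, P2[, , bi, drop = FALSE],
                               Xa[, , bi, drop = FALSE],
                               params, Zlab[, bi, drop = FALSE], length(bi))
        epoch_obj <- epoch_obj + res$loss
        grads <- add_l2_gradient(res$gradients, params, cfg$lambda)
        upd <- adam_step(params, grads, state, cfg$learning_rate)
        params <- upd$params; state <- upd$state
      }
      history[epoch] <- epoch_obj / n +
        cfg$lambda * sum(vapply(params, function(w) sum(w^2), 0)) / n
      if (verbose) message(sprintf("epoch %3d  objective %.5f", epoch, history[epoch]))
    }
  })
  structure(list(params = params, cfg = cfg, history = history,
                 counts = c(n_l = idx$n_l, n_d = idx$n_d, n_m = idx$n_m)),
            class = "cnnlda_model")
}

#' Score (lncRNA, disease) pairs with a trained model
#'
#' @param model a `cnnlda_model` from [train_model()].
#' @param net a `hetero_network` with the same entity counts.
#' @param pairs two-column matrix of (lncRNA, disease) indices.
#' @param L_active,A_active feature sources (defaults: `net$L`, `net$A`).
#' @param chunk scoring batch size (default 512).
#' @return Numeric vector of association scores in `[0, 1]`.
#' @export
predict_pairs <- function(model, net, pairs, L_active = net$L,
                          A_active = net$A, chunk = 512L) {
  pairs <- as.matrix(pairs)
  idx <- net$index
  if (!all(model$counts == c(idx$n_l, idx$n_d, idx$n_m)))
    stopf("entity count mismatch: model (%s) vs data (%s)",
          paste(model$counts, collapse = ","),
          paste(c(idx$n_l, idx$n_d, idx$n_m), collapse = ","))
  n <- nrow(pairs)
  scores <- numeric(n)
  eng <- new_engine(model$cfg, idx$n_l, idx$n_d, idx$n_m, min(chunk, n))
  for (s0 in seq(1L, n, by = chunk)) {
    bi <- s0:min(s0 + chunk - 1L, n)
    P2 <- fm_batch(net, pairs[bi, , drop = FALSE], L_active, A_active)
    Xa <- xvec_batch(net, pairs[bi, , drop = FALSE], L_active, A_active)
    p <- cpp_engine_forward(eng, P2, Xa, model$params, length(bi))
    scores[bi] <- p[2L, ]
  }
  scores
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a JSON file carrying a format tag, the configuration,
#' entity counts and every parameter tensor (flattened with its shape), so
#' it survives as plain text.
#'
#' @param model a `cnnlda_model`.
#' @param path file path.
#' @rdname checkpoint
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(
    format = "cnnlda-checkpoint-v1",
    config = unclass(model$cfg),
    counts = as.list(model$counts),
    history = model$history,
    params = lapply(model$params, function(w) {
      list(dim = if (is.null(dim(w))) length(w) else dim(w), data = as.vector(w))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cnnlda-checkpoint-v1"))
    stopf("unrecognized checkpoint format in %s", path)
  cfg <- do.call(model_config, obj$config[setdiff(names(obj$config), "C")])
  params <- lapply(obj$params, function(w) array(w$data, dim = w$dim))
  ## vectors stored with a single dim come back as 1-d arrays; flatten biases
  for (nm in names(params)) {
    if (length(dim(params[[nm]])) == 1L) params[[nm]] <- as.vector(params[[nm]])
  }
  structure(list(params = params, cfg = cfg,
                 history = as.numeric(obj$history),
                 counts = unlist(obj$counts)),
            class = "cnnlda_model")
}
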