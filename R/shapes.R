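## Architecture hyperparameters and symbolic shape inference.

#' Model configuration
#'
#' All architecture and training hyperparameters of the dual-CNN scorer.
#' Window sizes and filter counts follow the published architecture
#' (2 x 2 windows everywhere; 8 and 16 filters in the left branch, 16 in
#' the attention branch, 32 in the final layer; 80 training epochs); the
#' optimizer settings the architecture leaves open (Adam learning rate,
#' batch size, L2 trade-off, attention hidden width) are exposed here with
#' package defaults.
#'
#' @param n_w,n_f convolution window width (rows) and length (columns),
#'   default 2 x 2.
#' @param n_g,n_p pooling window width and length, default 2 x 2 (stride 1,
#'   overlapping).
#' @param n_conv1,n_conv2 filters in the left branch's first and second
#'   convolutional layers (defaults 8 and 16).
#' @param n_att_conv filters in the attention branch convolution (default
#'   16; must equal `n_conv2` so the two representations can be stacked).
#' @param n_final filters in the final convolution (default 32).
#' @param attention_hidden hidden width of both attention projections
#'   (default 64).
#' @param lambda L2 regularization trade-off (default `1e-4`).
#' @param learning_rate Adam step size (default `1e-3`).
#' @param batch_size minibatch size (default 32).
#' @param max_epochs training epochs (default 80).
#' @param seed integer seed driving initialization, shuffling and sampling.
#' @param mask_self_cell zero the target cell `A[l, d]` in a training
#'   pair's own feature vectors (default `TRUE`). The cell is the pair's
#'   own label; leaving it visible lets the classifier read its label out
#'   of the input and degrades held-out ranking. `FALSE` reproduces the
#'   literal published construction, which states no masking rule.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_w = 2L, n_f = 2L, n_g = 2L, n_p = 2L,
                         n_conv1 = 8L, n_conv2 = 16L, n_att_conv = 16L,
                         n_final = 32L, attention_hidden = 64L,
                         lambda = 1e-4, learning_rate = 1e-3,
                         batch_size = 32L, max_epochs = 80L, seed = 1L,
                         mask_self_cell = TRUE) {
  cfg <- list(n_w = n_w, n_f = n_f, n_g = n_g, n_p = n_p,
              n_conv1 = n_conv1, n_conv2 = n_conv2, n_att_conv = n_att_conv,
              n_final = n_final, C = 2L, attention_hidden = attention_hidden,
              lambda = lambda, learning_rate = learning_rate,
              batch_size = batch_size, max_epochs = max_epochs,
              seed = seed, mask_self_cell = isTRUE(mask_self_cell))
  sizes <- c("n_w", "n_f", "n_g", "n_p", "n_conv1", "n_conv2", "n_att_conv",
             "n_final", "attention_hidden", "batch_size", "max_epochs")
  for (nm in sizes) {
    if (!is_count(cfg[[nm]])) stopf("%s must be a positive integer", nm)
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  if (cfg$lambda < 0) stopf("lambda must be non-negative")
  if (cfg$learning_rate <= 0) stopf("learning_rate must be positive")
  if (cfg$n_conv2 != cfg$n_att_conv)
    stopf("n_conv2 (%d) must equal n_att_conv (%d): the global and attention representations are stacked channelwise",
          cfg$n_conv2, cfg$n_att_conv)
  structure(cfg, class = "model_config")
}

#' Symbolic shape inference for every activation
#'
#' Computes the shape of every intermediate tensor of a forward pass from
#' the configuration and entity counts, failing with the offending layer
#' named whenever a window no longer fits. The first-layer shapes follow
#' the closed forms `n_conv1 x (4 - n_w + 1) x (n_t + 2 - n_f + 1)` for the
#' convolution and `n_conv1 x (5 - n_w - n_g + 1) x (n_t + 3 - n_f - n_p + 1)`
#' for the stride-1 pooling.
#'
#' @param cfg a `model_config`.
#' @param n_l,n_d,n_m entity counts.
#' @return Named list of integer shape vectors (channels, rows, columns),
#'   plus `z_o` and `p` lengths and the scalars `n_t`, `n_max`.
#' @export
infer_shapes <- function(cfg, n_l, n_d, n_m) {
  n_t <- n_l + n_d + n_m
  n_max <- max(n_l, n_d, n_m)
  conv_out <- function(hw, k, layer) {
    out <- c(hw[1] - k[1] + 1L, hw[2] - k[2] + 1L)
    if (any(out < 1L))
      stopf("layer %s: window %d x %d does not fit input %d x %d",
            layer, k[1], k[2], hw[1], hw[2])
    out
  }
  kw <- c(cfg$n_w, cfg$n_f); kp <- c(cfg$n_g, cfg$n_p)
  s <- list(n_t = n_t, n_max = n_max)
  s$P <- c(2L, n_t)
  s$P_pad <- c(4L, n_t + 2L)
  hw <- conv_out(s$P_pad, kw, "conv1");    s$Z_conv1 <- c(cfg$n_conv1, hw)
  hw <- conv_out(hw, kp, "pool1");         s$Z_convpool1 <- c(cfg$n_conv1, hw)
  pad2 <- hw + 2L
  hw <- conv_out(pad2, kw, "conv2");       s$Z_conv2 <- c(cfg$n_conv2, hw)
  hw <- conv_out(hw, kp, "pool2");         s$Z_glo <- c(cfg$n_conv2, hw)
  s$g <- n_max
  s$G <- c(3L, n_max + 2L)
  hw <- conv_out(s$G, kw, "att_conv");     s$Z_attconv <- c(cfg$n_att_conv, hw)
  hw <- conv_out(hw, kp, "att_pool");      s$Z_att <- c(cfg$n_att_conv, hw)
  if (s$Z_att[3] > s$Z_glo[3])
    stopf("layer att_pool: attention width %d exceeds the global branch width %d",
          s$Z_att[3], s$Z_glo[3])
  ## Z_att is right-padded to the global branch width (n_t with defaults)
  s$Z_con <- c(cfg$n_conv2, s$Z_glo[2] + s$Z_att[2], s$Z_glo[3])
  padf <- c(s$Z_con[2] + 2L, s$Z_con[3] + 2L)
  hw <- conv_out(padf, kw, "final_conv");  s$Z_fin_conv <- c(cfg$n_final, hw)
  hw <- conv_out(hw, kp, "final_pool");    s$Z_fin <- c(cfg$n_final, hw)
  s$z_o <- prod(s$Z_fin)
  s$p <- cfg$C
  s
}
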