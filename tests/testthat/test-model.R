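test_that("shape inference reproduces the closed-form layer-1 shapes", {
  cfg <- model_config()
  s <- infer_shapes(cfg, 240, 402, 495)
  expect_equal(s$Z_conv1, c(8, 3, 1138))
  expect_equal(s$Z_convpool1, c(8, 2, 1137))
  expect_equal(s$Z_glo, c(16, 2, 1137))
  expect_equal(s$z_o, 32 * 3 * 1137)
  ## the closed forms hold for random window/filter configurations
  set.seed(21)
  for (rep in 1:20) {
    n_w <- sample(2:3, 1); n_f <- sample(2:4, 1)
    n_g <- sample(2:2, 1); n_p <- sample(2:3, 1)
    n_conv1 <- sample(2:8, 1)
    counts <- sample(5:30, 3)
    n_t <- sum(counts)
    cfg_r <- try(model_config(n_w = n_w, n_f = n_f, n_g = n_g, n_p = n_p,
                              n_conv1 = n_conv1), silent = TRUE)
    s_r <- try(infer_shapes(cfg_r, counts[1], counts[2], counts[3]), silent = TRUE)
    if (inherits(s_r, "try-error")) next   # geometrically impossible config
    expect_equal(s_r$Z_conv1, c(n_conv1, 4 - n_w + 1, n_t + 2 - n_f + 1))
    expect_equal(s_r$Z_convpool1,
                 c(n_conv1, 5 - n_w - n_g + 1, n_t + 3 - n_f - n_p + 1))
  }
  expect_error(infer_shapes(model_config(n_w = 5), 3, 3, 3), "conv1")
})

test_that("configuration invariants are enforced", {
  expect_error(model_config(n_conv2 = 16, n_att_conv = 8), "stacked")
  expect_error(model_config(lambda = -1), "non-negative")
  expect_error(model_config(max_epochs = 0), "positive integer")
  cfg <- model_config()
  expect_equal(cfg$C, 2L)
  expect_equal(cfg$max_epochs, 80L)
  expect_equal(c(cfg$n_conv1, cfg$n_conv2, cfg$n_att_conv, cfg$n_final),
               c(8L, 16L, 16L, 32L))
})

test_that("forward pass produces normalized probabilities and weights", {
  net <- toy_network()
  cfg <- model_config(attention_hidden = 4L, seed = 2L)
  set.seed(31)
  for (rep in 1:100) {
    params <- generic_params(cfg, 3, 3, 2, seed = rep)
    fm <- build_feature_matrix(net, sample(3, 1), sample(3, 1))
    out <- model_forward(fm, params, cfg)
    expect_equal(sum(out$p), 1, tolerance = 1e-6)
    expect_true(all(out$p >= 0))
    expect_equal(sum(out$beta), 1, tolerance = 1e-6)
    for (al in out$alpha) expect_equal(sum(al), 1, tolerance = 1e-6)
  }
})

test_that("zero output layer gives an indifferent classifier", {
  net <- toy_network()
  cfg <- model_config(attention_hidden = 4L, seed = 2L)
  params <- generic_params(cfg, 3, 3, 2)
  params$W_out[] <- 0; params$b_o <- c(0, 0)
  out <- model_forward(build_feature_matrix(net, 1, 1), params, cfg)
  expect_equal(out$p, c(0.5, 0.5))
  params$b_o <- c(0, 10)
  out2 <- model_forward(build_feature_matrix(net, 1, 1), params, cfg)
  expect_gt(out2$score, 0.9999)
})

test_that("cross-entropy and the regularized objective match hand values", {
  expect_equal(cross_entropy_loss(c(0.5, 0.5), c(0, 1)), -log(0.5))
  expect_equal(cross_entropy_loss(c(0, 1), c(0, 1)), 0)
  expect_equal(cross_entropy_loss(c(1, 0), c(0, 1)), -log(1e-12))
  expect_error(cross_entropy_loss(c(0.5, 0.5), c(1, 1)), "one-hot")

  params <- list(w = matrix(c(1, 1, 1, 1), 2))
  expect_equal(objective(1, params, 0.5), 1 + 0.5 * 4)
  expect_equal(objective(2.5, params, 0), 2.5)
  expect_gt(objective(1, params, 0.2), objective(1, params, 0.1))
  expect_error(objective(1, params, -0.1), "non-negative")
})

test_that("analytic gradients match central finite differences", {
  gen <- generate_network(synthetic_config(n_l = 3, n_d = 3, n_m = 3,
                                           n_groups = 2, seed = 5))
  net <- gen$network
  cfg <- model_config(attention_hidden = 4L, seed = 11L, lambda = 1e-3)
  params <- generic_params(cfg, 3, 3, 3, seed = 99)
  pairs <- rbind(c(1, 2), c(2, 3), c(3, 1))
  labels <- c(1, 0, 1)
  mg <- model_gradients(net, pairs, labels, params, cfg)
  obj_at <- function(p) model_gradients(net, pairs, labels, p, cfg)$objective
  eps <- 1e-5
  set.seed(1)
  for (nm in names(params)) {
    for (i in sample(length(params[[nm]]), min(6, length(params[[nm]])))) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      fd <- (obj_at(p1) - obj_at(p2)) / (2 * eps)
      an <- mg$gradients[[nm]][i]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-4)
    }
  }
})

test_that("the training engine reproduces the modular forward pass", {
  net <- toy_network()
  cfg <- model_config(attention_hidden = 4L, seed = 8L)
  params <- generic_params(cfg, 3, 3, 2, seed = 4)
  pairs <- rbind(c(1, 1), c(2, 3), c(3, 2), c(1, 2))
  mg <- model_gradients(net, pairs, c(1, 0, 0, 1), params, cfg)
  for (s in seq_len(nrow(pairs))) {
    fm <- build_feature_matrix(net, pairs[s, 1], pairs[s, 2])
    out <- model_forward(fm, params, cfg)
    expect_equal(out$p, unname(mg$p[, s]), tolerance = 1e-12)
  }
})

test_that("training is reproducible and learns a separable toy problem", {
  gen <- generate_network(synthetic_config(n_l = 12, n_d = 12, n_m = 8,
                                           n_groups = 2, p_in = 0.9,
                                           p_out = 0.02, seed = 3))
  net <- gen$network
  cfg <- model_config(attention_hidden = 8L, seed = 5L, max_epochs = 15L)
  pos <- which(net$A == 1, arr.ind = TRUE)
  neg <- which(net$A == 0, arr.ind = TRUE)
  set.seed(2)
  neg <- neg[sample(nrow(neg), nrow(pos)), ]
  samples <- list(pairs = rbind(pos, neg),
                  labels = rep(c(1, 0), c(nrow(pos), nrow(neg))))
  m1 <- train_model(net, samples, cfg)
  m2 <- train_model(net, samples, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$W_out, m2$params$W_out)
  ## the smoothed objective decreases after the burn-in epochs
  sm <- stats::filter(m1$history, rep(1 / 3, 3), sides = 1)
  expect_lt(min(diff(sm[5:15])), 0)
  expect_lt(sm[15], sm[5])
  ## scores separate the classes on the training support
  sc <- predict_pairs(m1, net, samples$pairs)
  expect_gt(roc_auc(sc, samples$labels), 0.9)
  expect_error(train_model(net, list(pairs = pos[0, ], labels = numeric()), cfg),
               "empty")
})

test_that("a dominant regularizer shrinks the parameter norm", {
  gen <- generate_network(synthetic_config(n_l = 8, n_d = 8, n_m = 6,
                                           n_groups = 2, seed = 9))
  net <- gen$network
  cfg <- model_config(attention_hidden = 4L, seed = 5L, max_epochs = 10L,
                      lambda = 1e3)
  pos <- which(net$A == 1, arr.ind = TRUE)
  samples <- list(pairs = pos, labels = rep(1, nrow(pos)))
  norm0 <- sum(vapply(init_parameters(cfg, 8, 8, 6), function(w) sum(w^2), 0))
  m <- train_model(net, samples, cfg)
  norm1 <- sum(vapply(m$params, function(w) sum(w^2), 0))
  expect_lt(norm1, norm0)
})

test_that("checkpoints round-trip and guard entity counts", {
  net <- toy_network()
  cfg <- model_config(attention_hidden = 4L, seed = 7L, max_epochs = 2L)
  pos <- which(net$A == 1, arr.ind = TRUE)
  m <- train_model(net, list(pairs = pos, labels = rep(1, nrow(pos))), cfg)
  f <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, f)
  back <- load_checkpoint(f)
  expect_equal(back$params, m$params, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$counts, m$counts, ignore_attr = TRUE)
  sc1 <- predict_pairs(m, net, rbind(c(1, 1), c(2, 2)))
  sc2 <- predict_pairs(back, net, rbind(c(1, 1), c(2, 2)))
  expect_equal(sc1, sc2, tolerance = 1e-9)
  ## mismatched counts are refused
  gen <- generate_network(synthetic_config(n_l = 5, n_d = 4, n_m = 3,
                                           n_groups = 2, seed = 1))
  expect_error(predict_pairs(m, gen$network, rbind(c(1, 1))), "mismatch")
})
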