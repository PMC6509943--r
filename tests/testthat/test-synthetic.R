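test_that("generator config invariants are enforced", {
  expect_error(synthetic_config(p_in = 0.2, p_out = 0.5), "p_out < p_in")
  expect_error(synthetic_config(n_groups = 50), "smallest entity count")
  expect_error(synthetic_config(sim_noise = -0.1), "non-negative")
})

test_that("degenerate probabilities give an exact block structure", {
  gen <- generate_network(synthetic_config(n_l = 12, n_d = 12, n_m = 8,
                                           n_groups = 3, p_in = 1, p_out = 0,
                                           sim_noise = 0, seed = 5))
  net <- gen$network
  match_ld <- outer(gen$groups$lncrna, gen$groups$disease, `==`)
  expect_equal(unname(net$A), match_ld * 1)
  match_md <- outer(gen$groups$mirna, gen$groups$disease, `==`)
  expect_equal(unname(net$B), match_md * 1)
  expect_length(validate_network(net), 0L)
})

test_that("generation is deterministic per seed and valid", {
  g1 <- generate_network(synthetic_config(seed = 11))
  g2 <- generate_network(synthetic_config(seed = 11))
  expect_identical(g1$network$A, g2$network$A)
  expect_identical(g1$network$D, g2$network$D)
  expect_identical(g1$groups, g2$groups)
  g3 <- generate_network(synthetic_config(seed = 12))
  expect_false(identical(g1$network$A, g3$network$A))
  expect_length(validate_network(g1$network), 0L)
})

test_that("association density is within binomial bounds of its expectation", {
  cfg <- synthetic_config(n_l = 40, n_d = 40, n_m = 30, n_groups = 4,
                          p_in = 0.6, p_out = 0.05, seed = 19)
  gen <- generate_network(cfg)
  gl <- gen$groups$lncrna; gd <- gen$groups$disease
  n_match <- sum(outer(gl, gd, `==`))
  n_cells <- cfg$n_l * cfg$n_d
  mu <- n_match * cfg$p_in + (n_cells - n_match) * cfg$p_out
  sigma <- sqrt(n_match * cfg$p_in * (1 - cfg$p_in) +
                (n_cells - n_match) * cfg$p_out * (1 - cfg$p_out))
  expect_lt(abs(sum(gen$network$A) - mu), 3 * sigma)
})

test_that("the derived lncRNA similarity comes from the disease-set formula", {
  gen <- generate_network(synthetic_config(n_l = 8, n_d = 8, n_m = 5,
                                           n_groups = 2, seed = 3))
  net <- gen$network
  expect_equal(unname(net$L),
               lncrna_similarity_matrix(unname(net$A), unname(net$D)),
               tolerance = 1e-12)
})

test_that("corrupt_network flips exactly the requested fraction", {
  gen <- generate_network(synthetic_config(n_l = 10, n_d = 10, n_m = 6,
                                           n_groups = 2, seed = 8))
  net <- gen$network
  expect_identical(corrupt_network(net, 0, seed = 1)$A, net$A)
  comp <- corrupt_network(net, 1, seed = 1)
  expect_equal(unname(comp$A), 1 - unname(net$A))
  half <- corrupt_network(net, 0.5, seed = 1)
  expect_equal(sum(half$A != net$A), round(0.5 * length(net$A)))
  ## similarity is refreshed from the corrupted associations
  expect_equal(unname(half$L),
               lncrna_similarity_matrix(unname(half$A), unname(half$D)),
               tolerance = 1e-12)
  expect_error(corrupt_network(net, 1.2), "\\[0, 1\\]")
})

test_that("decoupling miRNA relations preserves validity but changes B and Y", {
  g_c <- generate_network(synthetic_config(seed = 6))
  g_d <- generate_network(synthetic_config(seed = 6, decouple_mirna = TRUE))
  expect_identical(g_c$network$A, g_d$network$A)   # same planted associations
  expect_false(identical(g_c$network$B, g_d$network$B))
  expect_length(validate_network(g_d$network), 0L)
})

test_that("association noise degrades held-out recovery", {
  gen <- generate_network(synthetic_config(n_l = 14, n_d = 14, n_m = 10,
                                           n_groups = 2, p_in = 0.8,
                                           p_out = 0.05, seed = 21))
  cfg <- model_config(attention_hidden = 8L, seed = 2L, max_epochs = 12L)
  auc_at <- function(flip) {
    net <- corrupt_network(gen$network, flip, seed = 31)
    sp <- make_cv_splits(net, 5, seed = 2)[[1]]
    m <- train_model(net, sp$training, cfg,
                     L_active = sp$L_train, A_active = sp$A_train)
    sc <- predict_pairs(m, net, sp$testing$pairs,
                        L_active = sp$L_train, A_active = sp$A_train)
    roc_auc(sc, sp$testing$labels)
  }
  expect_gt(auc_at(0), auc_at(0.4))
})
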