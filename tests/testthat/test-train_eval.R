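test_that("cross-validation splits follow the 80/20 + equal-negative protocol", {
  gen <- generate_network(synthetic_config(n_l = 15, n_d = 15, n_m = 8,
                                           n_groups = 3, seed = 2))
  net <- gen$network
  splits <- make_cv_splits(net, 5, seed = 7)
  pos <- which(net$A == 1, arr.ind = TRUE)
  n_pos <- nrow(pos)
  n_zero <- sum(net$A == 0)
  all_test_pos <- NULL
  for (sp in splits) {
    tr <- sp$training; te <- sp$testing
    n_tr_pos <- sum(tr$labels == 1)
    ## equal-count negatives; ~80% of positives in training
    expect_equal(sum(tr$labels == 0), n_tr_pos)
    expect_lte(abs(n_tr_pos - 0.8 * n_pos), 1)
    ## testing = fold positives + all zero cells
    expect_equal(sum(te$labels == 0), n_zero)
    ## no overlap between training and testing positives
    trp <- tr$pairs[tr$labels == 1, , drop = FALSE]
    tep <- te$pairs[te$labels == 1, , drop = FALSE]
    expect_length(intersect(paste(trp[, 1], trp[, 2]),
                            paste(tep[, 1], tep[, 2])), 0L)
    ## A_train masks exactly the held-out positives
    expect_equal(sum(sp$A_train), n_tr_pos)
    expect_true(all(sp$A_train[tep] == 0))
    ## training negatives are true zero cells
    trn <- tr$pairs[tr$labels == 0, , drop = FALSE]
    expect_true(all(net$A[trn] == 0))
    all_test_pos <- rbind(all_test_pos, tep)
  }
  ## folds partition the positives
  expect_equal(nrow(all_test_pos), n_pos)
  expect_length(unique(paste(all_test_pos[, 1], all_test_pos[, 2])), n_pos)
  ## reproducibility
  splits2 <- make_cv_splits(net, 5, seed = 7)
  expect_identical(splits[[3]]$training$pairs, splits2[[3]]$training$pairs)
  ## per-fold similarity is recomputed from training-only data
  sp <- splits[[1]]
  expect_equal(sp$L_train,
               recompute_training_similarity(net, sp$training$pairs[sp$training$labels == 1, ]),
               tolerance = 1e-12)
  held_lnc <- unique(sp$testing$pairs[sp$testing$labels == 1, 1])
  expect_gt(max(abs(sp$L_train[held_lnc, ] - unname(net$L)[held_lnc, ])), 0)
})

test_that("exclude_train_negatives removes seen negatives from the test set", {
  gen <- generate_network(synthetic_config(n_l = 10, n_d = 10, n_m = 6,
                                           n_groups = 2, seed = 4))
  net <- gen$network
  sp <- make_cv_splits(net, 5, seed = 1, exclude_train_negatives = TRUE)[[1]]
  expect_equal(sum(sp$testing$labels == 0),
               sum(net$A == 0) - sum(sp$training$labels == 0))
})

test_that("confusion counts treat threshold ties as negative calls", {
  expect_equal(confusion_at_threshold(c(0.9, 0.1), c(1, 0), 0.5),
               c(TP = 1, FP = 0, TN = 1, FN = 0))
  expect_equal(confusion_at_threshold(c(0.7, 0.7, 0.2), c(1, 0, 0), 0.5),
               c(TP = 1, FP = 1, TN = 1, FN = 0))
  cm <- confusion_at_threshold(c(0.5, 0.9), c(1, 1), 0.5)
  expect_equal(unname(cm["TP"]), 1)   # tie at theta is a negative call
  expect_equal(confusion_at_threshold(c(0.3, 1), c(0, 1), 1)[c("TP", "FP")],
               c(TP = 0, FP = 0))
  expect_error(confusion_at_threshold(numeric(), numeric(), 0.5), "empty")
})

test_that("TPR and FPR are non-increasing in the threshold", {
  set.seed(5)
  scores <- runif(50)
  labels <- rbinom(50, 1, 0.3)
  thetas <- sort(unique(c(0, scores, 1)))
  cms <- vapply(thetas, function(th) confusion_at_threshold(scores, labels, th),
                numeric(4))
  tpr <- cms["TP", ] / (cms["TP", ] + cms["FN", ])
  fpr <- cms["FP", ] / (cms["FP", ] + cms["TN", ])
  expect_true(all(diff(tpr) <= 1e-12))
  expect_true(all(diff(fpr) <= 1e-12))
})

test_that("roc_auc matches examples and the pairwise-comparison oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(roc_auc(c(0.8, 0.6, 0.6, 0.2), c(1, 1, 0, 0)), 0.875)
  expect_error(roc_auc(c(0.5, 0.6), c(1, 1)), "undefined")
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(4:50, 1)
    scores <- round(runif(n), 2)          # rounding forces ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_identical(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(3)
  scores <- runif(30); labels <- rbinom(30, 1, 0.5)
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  a0 <- roc_auc(scores, labels)
  expect_equal(roc_auc(qlogis(scores), labels), a0)
  expect_equal(roc_auc(scores^3 + 2, labels), a0)
})

test_that("pr_auc follows the stepwise summation convention", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(pr_auc(rep(0.5, 4), c(1, 0, 0, 0)), 0.25)
  expect_equal(pr_auc(c(0.9, 0.8, 0.7), c(1, 0, 1)), 5 / 6)
  expect_error(pr_auc(c(0.2, 0.4), c(0, 0)), "without positives")
})

test_that("recall_at_topk counts ranked positives", {
  ## 4 positives at ranks 1, 5, 40, 100 of a 120-long list
  scores <- seq(1, 0, length.out = 120)
  labels <- rep(0, 120); labels[c(1, 5, 40, 100)] <- 1
  rc <- recall_at_topk(scores, labels, c(30, 60, 90, 120))
  expect_equal(unname(rc), c(0.5, 0.75, 0.75, 1))
  expect_true(all(diff(rc) >= 0))
  expect_equal(unname(recall_at_topk(scores, labels, 120)), 1)
  expect_equal(unname(recall_at_topk(scores, labels, 0)), 0)
  expect_warning(rcw <- recall_at_topk(scores[1:10], labels[1:10], 30),
                 "full list")
})

test_that("evaluate_model aggregates folds and diseases", {
  gen <- generate_network(synthetic_config(n_l = 12, n_d = 12, n_m = 8,
                                           n_groups = 2, seed = 6))
  net <- gen$network
  splits <- make_cv_splits(net, 5, seed = 2)
  ## oracle scorer: the true labels -> perfect metrics
  oracle_scores <- lapply(splits, function(sp) sp$testing$labels)
  res <- evaluate_model(oracle_scores, splits, k_values = c(5, 10))
  expect_equal(res$auc, 1)
  expect_equal(res$aupr, 1)
  expect_true(all(res$per_disease$auc == 1))
  ## disease list = diseases with a test positive (and a negative)
  d_with_pos <- sort(unique(unlist(lapply(splits, function(sp)
    sp$testing$pairs[sp$testing$labels == 1, 2]))))
  expect_setequal(res$per_disease$disease, d_with_pos)
  ## random scores hover near AUC 0.5
  set.seed(8)
  rand_scores <- lapply(splits, function(sp) runif(length(sp$testing$labels)))
  res_r <- evaluate_model(rand_scores, splits, k_values = c(5, 10))
  expect_gt(res_r$auc, 0.4); expect_lt(res_r$auc, 0.6)
  ## recall curves are nondecreasing in k in both modes
  res_p <- evaluate_model(rand_scores, splits, k_values = c(5, 10, 20),
                          recall_mode = "pooled")
  expect_true(all(diff(res_p$recall_curve) >= 0))
  expect_true(all(diff(res_r$recall_curve) >= 0))
})

test_that("paired Wilcoxon matches exact enumeration", {
  a <- c(2, 3, 4, 5, 6, 7); b <- a - 1
  expect_equal(paired_wilcoxon(a, b), 0.03125)
  expect_error(paired_wilcoxon(c(1, 2), c(1, 2)), "zero")
  set.seed(17)
  for (rep in 1:10) {
    x <- round(rnorm(8), 1); y <- round(rnorm(8), 1)
    d <- x - y
    if (all(d == 0)) next
    expect_equal(paired_wilcoxon(x, y), oracle_wilcoxon(x, y), tolerance = 1e-12)
  }
  ## agrees with the base implementation when it is exact (no ties)
  set.seed(23)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(paired_wilcoxon(x, y),
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
  ## large-n path returns a sane two-sided p-value
  set.seed(29)
  x <- rnorm(40); y <- x + rnorm(40, 0.8)
  p <- paired_wilcoxon(x, y)
  expect_gt(p, 0); expect_lt(p, 0.01)
})

test_that("predict_novel ranks only unobserved pairs, per disease", {
  gen <- generate_network(synthetic_config(n_l = 10, n_d = 10, n_m = 6,
                                           n_groups = 2, seed = 12))
  net <- gen$network
  cfg <- model_config(attention_hidden = 8L, seed = 3L, max_epochs = 5L)
  out <- predict_novel(net, cfg)
  expect_equal(nrow(out), sum(net$A == 0))
  expect_true(all(net$A[cbind(out$lncrna, out$disease)] == 0))
  ## per-disease ranks are 1..k in descending score order
  for (d in unique(out$disease)[1:3]) {
    sub <- out[out$disease == d, ]
    expect_equal(sub$rank, seq_len(nrow(sub)))
    expect_true(all(diff(sub$score) <= 1e-12))
    expect_equal(sub$lncrna[1],
                 sub$lncrna[which.max(sub$score)])
  }
  expect_true(all(out$score >= 0 & out$score <= 1))
})
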