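## Cross-validation protocol, metrics and comparisons.
##
## Protocol: known associations (positives) are partitioned into five folds
## by a seeded shuffle. Per fold, the training set holds the other four
## folds' positives (80%) plus an equal number of negatives sampled
## uniformly without replacement from the zero cells of A; the test set
## holds the fold's positives plus all zero cells. The lncRNA similarity
## is recomputed from the training-only associations so held-out labels
## never leak into the features, and the fold's test positives are zeroed
## in the association matrix used for feature construction.

#' Build cross-validation splits
#'
#' @param net a `hetero_network`.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed for the fold shuffle and negative sampling.
#' @param exclude_train_negatives drop the fold's training negatives from
#'   its test set (default `FALSE`: the test set keeps all zero cells, as
#'   the printed protocol states, at the price of re-scoring negatives
#'   already seen in training).
#' @return List of `n_folds` splits; each has `fold_id`, `training` and
#'   `testing` (lists with `pairs`, `labels`), `A_train` and `L_train`.
#' @export
make_cv_splits <- function(net, n_folds = 5L, seed = 1L,
                           exclude_train_negatives = FALSE) {
  A <- net$A
  pos <- which(A == 1, arr.ind = TRUE)
  neg <- which(A == 0, arr.ind = TRUE)
  dimnames(pos) <- NULL; dimnames(neg) <- NULL
  n_pos <- nrow(pos)
  if (n_pos < n_folds) stopf("need at least %d positives for %d folds", n_folds, n_folds)
  with_seed(seed, {
    fold_of <- sample(rep_len(seq_len(n_folds), n_pos))
    lapply(seq_len(n_folds), function(f) {
      test_pos_idx <- which(fold_of == f)
      train_pos <- pos[-test_pos_idx, , drop = FALSE]
      test_pos <- pos[test_pos_idx, , drop = FALSE]
      n_train_neg <- nrow(train_pos)
      if (n_train_neg > nrow(neg))
        stopf("fold %d: %d training negatives requested but only %d zero cells exist",
              f, n_train_neg, nrow(neg))
      neg_idx <- sample.int(nrow(neg), n_train_neg)
      train_neg <- neg[neg_idx, , drop = FALSE]
      test_neg <- if (exclude_train_negatives) neg[-neg_idx, , drop = FALSE] else neg
      A_train <- A
      A_train[test_pos] <- 0
      L_train <- lncrna_similarity_matrix(A_train, net$D)
      list(
        fold_id = f,
        training = list(pairs = rbind(train_pos, train_neg),
                        labels = rep(c(1, 0), c(nrow(train_pos), n_train_neg)),
                        role = "training"),
        testing = list(pairs = rbind(test_pos, test_neg),
                       labels = rep(c(1, 0), c(nrow(test_pos), nrow(test_neg))),
                       role = "testing"),
        A_train = A_train,
        L_train = L_train
      )
    })
  })
}

#' Confusion counts at a score threshold
#'
#' A sample is called positive when its score is strictly greater than
#' `theta`; ties at the threshold are negative calls.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels binary labels.
#' @param theta threshold.
#' @return Named vector `(TP, FP, TN, FN)`.
#' @export
confusion_at_threshold <- function(scores, labels, theta) {
  if (length(scores) == 0L) stopf("empty input")
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  called <- scores > theta
  c(TP = sum(called & labels == 1), FP = sum(called & labels == 0),
    TN = sum(!called & labels == 0), FN = sum(!called & labels == 1))
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formulation, which equals the area
#' under the threshold-swept (FPR, TPR) curve with tied scores counted by
#' midranks (half credit).
#'
#' @param scores numeric scores.
#' @param labels binary labels (both classes must be present).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels != 0)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stopf("AUC undefined: need at least one positive and one negative")
  r <- rank(scores)                       # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) summation over the ranked unique score
#' thresholds: `sum_t (R_t - R_{t-1}) * P_t` with samples retrieved at
#' score `>= t`. Equals average precision when scores are untied.
#'
#' @param scores numeric scores.
#' @param labels binary labels (at least one positive).
#' @return AUPR in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels != 0)
  n_pos <- sum(labels)
  if (n_pos == 0L) stopf("AUPR undefined without positives")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cum_tp <- cumsum(y)
  cum_n <- seq_along(y)
  ## last index of each tied block = points of the stepwise curve
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  recall <- cum_tp[last] / n_pos
  precision <- cum_tp[last] / cum_n[last]
  sum(diff(c(0, recall)) * precision)
}

#' Recall at top-k
#'
#' Fraction of all positives ranked within the top `k` of the
#' score-sorted list (ties broken by stable order).
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param k_values cutoffs (default `seq(30, 240, by = 30)`).
#' @return Named numeric vector of recalls, nondecreasing in `k`.
#' @export
recall_at_topk <- function(scores, labels, k_values = seq(30L, 240L, by = 30L)) {
  labels <- as.integer(labels != 0)
  n_pos <- sum(labels)
  if (n_pos == 0L) stopf("recall undefined without positives")
  n <- length(scores)
  if (any(k_values > n))
    warnf("k exceeds list length %d; recall computed against the full list", n)
  ranks <- order(order(scores, decreasing = TRUE))   # rank of each sample
  pos_ranks <- ranks[labels == 1]
  out <- vapply(k_values, function(k) sum(pos_ranks <= min(k, n)) / n_pos, 0)
  names(out) <- paste0("k", k_values)
  out
}

#' Evaluate per-fold score sets
#'
#' Computes fold-level AUC/AUPR (averaged over folds, the averaging-CV
#' convention), per-disease metrics restricted to each disease's test
#' candidates (reported when a disease has at least one test positive and
#' one test negative in the fold), and recall-at-k curves.
#'
#' @param fold_scores list with one numeric score vector per fold, aligned
#'   with `splits[[f]]$testing$pairs`.
#' @param splits output of [make_cv_splits()].
#' @param k_values recall cutoffs.
#' @param recall_mode `"per_disease"` (average each tested disease's own
#'   ranking, the default) or `"pooled"` (one ranking per fold).
#' @return List of class `eval_result`: `auc`, `aupr` (averaged), `fold_auc`,
#'   `fold_aupr`, `recall_curve`, `per_disease` (data.frame with mean
#'   per-disease AUC/AUPR across folds).
#' @export
evaluate_model <- function(fold_scores, splits, k_values = seq(30L, 240L, by = 30L),
                           recall_mode = c("per_disease", "pooled")) {
  recall_mode <- match.arg(recall_mode)
  n_folds <- length(splits)
  fold_auc <- numeric(n_folds); fold_aupr <- numeric(n_folds)
  recall_mat <- matrix(NA_real_, n_folds, length(k_values))
  per_d <- list()
  for (f in seq_len(n_folds)) {
    te <- splits[[f]]$testing
    sc <- fold_scores[[f]]
    fold_auc[f] <- roc_auc(sc, te$labels)
    fold_aupr[f] <- pr_auc(sc, te$labels)
    dis <- te$pairs[, 2]
    if (recall_mode == "pooled") {
      recall_mat[f, ] <- suppressWarnings(recall_at_topk(sc, te$labels, k_values))
    } else {
      dpos <- unique(dis[te$labels == 1])
      rc <- vapply(dpos, function(d) {
        sel <- dis == d
        suppressWarnings(recall_at_topk(sc[sel], te$labels[sel], k_values))
      }, numeric(length(k_values)))
      recall_mat[f, ] <- rowMeans(matrix(rc, nrow = length(k_values)))
    }
    for (d in unique(dis[te$labels == 1])) {
      sel <- dis == d
      if (length(unique(te$labels[sel])) < 2L) next
      per_d[[length(per_d) + 1L]] <- data.frame(
        fold = f, disease = d,
        auc = roc_auc(sc[sel], te$labels[sel]),
        aupr = pr_auc(sc[sel], te$labels[sel]))
    }
  }
  per_disease <- if (length(per_d) > 0L) {
    pd <- do.call(rbind, per_d)
    agg <- stats::aggregate(pd[, c("auc", "aupr")], by = list(disease = pd$disease), FUN = mean)
    agg[order(agg$disease), ]
  } else {
    data.frame(disease = integer(), auc = numeric(), aupr = numeric())
  }
  rc <- colMeans(recall_mat)
  names(rc) <- paste0("k", k_values)
  structure(list(auc = mean(fold_auc), aupr = mean(fold_aupr),
                 fold_auc = fold_auc, fold_aupr = fold_aupr,
                 recall_curve = rc, per_disease = per_disease),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("cross-validation: mean AUC %.4f, mean AUPR %.4f over %d folds\n",
              x$auc, x$aupr, length(x$fold_auc)))
  cat("  fold AUC: ", paste(sprintf("%.4f", x$fold_auc), collapse = " "), "\n")
  invisible(x)
}

#' Run the full cross-validation pipeline
#'
#' Builds splits, recomputes per-fold similarities, trains one model per
#' fold on its training set, scores its test set and aggregates metrics.
#' Optionally also reports a permutation control: test labels shuffled
#' within each fold before computing the AUC, which must hover near 0.5
#' for any leak-free pipeline.
#'
#' @param net a `hetero_network`.
#' @param cfg a `model_config`; its `seed` drives everything.
#' @param n_folds number of folds (default 5).
#' @param k_values recall cutoffs.
#' @param exclude_train_negatives see [make_cv_splits()].
#' @param recall_mode see [evaluate_model()].
#' @param permutation_control also compute the label-permuted AUC (default
#'   `TRUE`).
#' @param verbose print fold progress.
#' @return An `eval_result` with extra fields `fold_scores`, `splits_seed`,
#'   `control_auc` (if requested) and `history` (per-fold loss histories).
#' @export
run_cv <- function(net, cfg, n_folds = 5L, k_values = seq(30L, 240L, by = 30L),
                   exclude_train_negatives = FALSE,
                   recall_mode = "per_disease",
                   permutation_control = TRUE, verbose = FALSE) {
  splits <- make_cv_splits(net, n_folds, seed = cfg$seed,
                           exclude_train_negatives = exclude_train_negatives)
  fold_scores <- vector("list", n_folds)
  histories <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    sp <- splits[[f]]
    if (verbose) message(sprintf("fold %d/%d: training on %d samples",
                                 f, n_folds, nrow(sp$training$pairs)))
    model <- train_model(net, sp$training, cfg,
                         L_active = sp$L_train, A_active = sp$A_train)
    histories[[f]] <- model$history
    fold_scores[[f]] <- predict_pairs(model, net, sp$testing$pairs,
                                      L_active = sp$L_train, A_active = sp$A_train)
  }
  res <- evaluate_model(fold_scores, splits, k_values, recall_mode)
  res$fold_scores <- fold_scores
  res$history <- histories
  res$splits_seed <- cfg$seed
  if (permutation_control) {
    res$control_auc <- with_seed(cfg$seed + 7919L, {
      mean(vapply(seq_len(n_folds), function(f) {
        roc_auc(fold_scores[[f]], sample(splits[[f]]$testing$labels))
      }, 0))
    })
  }
  res
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired per-disease metric vectors. Zero differences
#' are dropped. The null distribution of the signed-rank statistic is
#' computed exactly (by convolution over sign assignments, valid under
#' ties) for `n <= 25` informative pairs, and by the normal approximation
#' with continuity correction and tie-corrected variance above that.
#'
#' @param metric_a,metric_b equal-length paired numeric vectors.
#' @return Two-sided p-value.
#' @export
paired_wilcoxon <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b)) stopf("paired vectors differ in length")
  d <- metric_a - metric_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stopf("all paired differences are zero: no information")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    ## exact null: distribution of sum of ranks with independent signs.
    ## Work on doubled ranks so midranks become integers.
    r2 <- as.integer(round(2 * r))
    probs <- 1
    offset <- 0L
    for (ri in r2) {
      ## convolve with {0 w.p. 1/2, ri w.p. 1/2}
      m <- length(probs)
      new <- numeric(m + ri)
      new[seq_len(m)] <- probs / 2
      new[ri + seq_len(m)] <- new[ri + seq_len(m)] + probs / 2
      probs <- new
    }
    support <- (seq_along(probs) - 1L)          # value on doubled scale
    W2 <- round(2 * W)
    p_ge <- sum(probs[support >= W2])
    p_le <- sum(probs[support <= W2])
    min(1, 2 * min(p_ge, p_le))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Rank novel candidate associations
#'
#' Trains on all known positives plus an equal-count negative sample
#' (matching the cross-validation training recipe), scores every
#' unobserved (zero) cell of `A`, and returns per-disease descending
#' candidate lists. Known positives never appear as candidates.
#'
#' @param net a `hetero_network`.
#' @param cfg a `model_config`.
#' @param model optional pre-trained `cnnlda_model`; trained fresh when
#'   `NULL`.
#' @return data.frame with columns `disease`, `lncrna`, `score`, `rank`
#'   (rank within each disease), ordered by disease then rank; carries the
#'   trained model as attribute `"model"`.
#' @export
predict_novel <- function(net, cfg, model = NULL) {
  A <- net$A
  pos <- which(A == 1, arr.ind = TRUE)
  neg <- which(A == 0, arr.ind = TRUE)
  dimnames(pos) <- NULL; dimnames(neg) <- NULL
  if (is.null(model)) {
    neg_idx <- with_seed(cfg$seed, sample.int(nrow(neg), min(nrow(pos), nrow(neg))))
    samples <- list(pairs = rbind(pos, neg[neg_idx, , drop = FALSE]),
                    labels = rep(c(1, 0), c(nrow(pos), length(neg_idx))))
    model <- train_model(net, samples, cfg)
  }
  scores <- predict_pairs(model, net, neg)
  out <- data.frame(disease = neg[, 2], lncrna = neg[, 1], score = scores)
  out <- out[order(out$disease, -out$score), ]
  out$rank <- stats::ave(out$score, out$disease,
                         FUN = function(s) seq_along(s))
  rownames(out) <- NULL
  dn <- net$index$disease_names; ln <- net$index$lncrna_names
  out$disease_name <- dn[out$disease]
  out$lncrna_name <- ln[out$lncrna]
  attr(out, "model") <- model
  out
}
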