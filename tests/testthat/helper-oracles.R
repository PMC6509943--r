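## Independent oracles, deliberately written as naive loops so they share no
## code with the implementation they check.

## Best-match average similarity of two disease-index sets (brute force).
oracle_set_similarity <- function(a, b, D) {
  a <- unique(a); b <- unique(b)
  m <- length(a); n <- length(b)
  if (m == 0 || n == 0) return(0)
  s1 <- 0
  for (i in a) {
    best <- -Inf
    for (j in b) if (D[i, j] > best) best <- D[i, j]
    s1 <- s1 + best
  }
  s2 <- 0
  for (j in b) {
    best <- -Inf
    for (i in a) if (D[j, i] > best) best <- D[j, i]
    s2 <- s2 + best
  }
  (s1 + s2) / (m + n)
}

## Valid cross-correlation + bias + relu, by quadruple loop.
oracle_conv <- function(X, W, b, relu = TRUE) {
  if (is.matrix(X)) X <- array(X, dim = c(1L, dim(X)))
  ch <- dim(X)[1]; h <- dim(X)[2]; w <- dim(X)[3]
  f <- dim(W)[1]; kh <- dim(W)[3]; kw <- dim(W)[4]
  out <- array(0, dim = c(f, h - kh + 1L, w - kw + 1L))
  for (k in seq_len(f)) {
    for (i in seq_len(h - kh + 1L)) {
      for (j in seq_len(w - kw + 1L)) {
        acc <- b[k]
        for (cc in seq_len(ch)) {
          for (u in seq_len(kh)) {
            for (v in seq_len(kw)) {
              acc <- acc + W[k, cc, u, v] * X[cc, i + u - 1L, j + v - 1L]
            }
          }
        }
        out[k, i, j] <- if (relu) max(acc, 0) else acc
      }
    }
  }
  out
}

## Stride-1 sliding max, by loop.
oracle_maxpool <- function(X, ng, np) {
  if (is.matrix(X)) X <- array(X, dim = c(1L, dim(X)))
  ch <- dim(X)[1]; h <- dim(X)[2]; w <- dim(X)[3]
  out <- array(0, dim = c(ch, h - ng + 1L, w - np + 1L))
  for (k in seq_len(ch)) {
    for (i in seq_len(h - ng + 1L)) {
      for (j in seq_len(w - np + 1L)) {
        out[k, i, j] <- max(X[k, i:(i + ng - 1L), j:(j + np - 1L)])
      }
    }
  }
  out
}

## AUC as the Mann-Whitney pairwise comparison count (ties count half).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

## Two-sided exact signed-rank p-value by enumeration of all sign patterns.
oracle_wilcoxon <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ws <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[1:n]
    ws[m + 1] <- sum(r[signs == 1])
  }
  p_ge <- mean(ws >= W)
  p_le <- mean(ws <= W)
  min(1, 2 * min(p_ge, p_le))
}

## Tiny deterministic network: 3 lncRNAs, 3 diseases, 2 miRNAs.
toy_network <- function() {
  D <- matrix(c(1, 0.5, 0.2,
                0.5, 1, 0.4,
                0.2, 0.4, 1), 3, 3,
              dimnames = list(c("d1", "d2", "d3"), c("d1", "d2", "d3")))
  assemble_network(
    ld_pairs = data.frame(l = c("l1", "l2", "l3", "l1"),
                          d = c("d1", "d2", "d3", "d2")),
    md_pairs = data.frame(m = c("m1", "m2"), d = c("d1", "d3")),
    lm_pairs = data.frame(l = c("l1", "l2"), m = c("m1", "m2")),
    D = D)
}

## Small random parameter set with non-degenerate biases (generic point in
## parameter space, away from the relu kinks that zero initialization sits
## on).
generic_params <- function(cfg, n_l, n_d, n_m, seed = 1) {
  params <- init_parameters(cfg, n_l, n_d, n_m)
  set.seed(seed)
  for (nm in grep("^b", names(params), value = TRUE)) {
    params[[nm]] <- stats::rnorm(length(params[[nm]]), sd = 0.3)
  }
  params
}

## Memoized study results shared by the end-to-end acceptance checks, so the
## expensive cross-validation runs happen once per test session.
.study_cache <- new.env(parent = emptyenv())

fixture_study <- function(decouple = FALSE, seeds = 1:3) {
  key <- paste0(if (decouple) "decoupled" else "coupled", "-",
                paste(seeds, collapse = ","))
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  runs <- lapply(seeds, function(s) {
    gen <- generate_network(synthetic_config(seed = s, decouple_mirna = decouple))
    cfg <- model_config(seed = s)
    r <- run_cv(gen$network, cfg, n_folds = 5, k_values = c(10, 20, 30))
    ## positive rate of a fold's test set (the baseline AUPR of a random
    ## ranking): one fifth of the positives against all zero cells
    npos <- sum(gen$network$A); nzero <- sum(gen$network$A == 0)
    prev <- (npos / 5) / (npos / 5 + nzero)
    list(auc = r$auc, aupr = r$aupr, prevalence = prev,
         control_auc = r$control_auc, recall = r$recall_curve)
  })
  out <- list(
    auc = mean(vapply(runs, `[[`, 0, "auc")),
    aupr = mean(vapply(runs, `[[`, 0, "aupr")),
    prevalence = mean(vapply(runs, `[[`, 0, "prevalence")),
    control_auc = mean(vapply(runs, `[[`, 0, "control_auc")),
    runs = runs)
  .study_cache[[key]] <- out
  out
}
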