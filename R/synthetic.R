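## Seeded generator of heterogeneous networks with planted structure.
##
## Entities of all three kinds are assigned to latent groups; associations
## and interactions (A, B, Y) fire with probability p_in for group-matched
## pairs and p_out otherwise, so the planted assignment is statistically
## recoverable from any of the three relations. The disease similarity D
## carries the same groups (s_in = 0.8 within, s_out = 0.2 across, plus
## truncated Gaussian noise), and L is derived from A and D through the
## disease-set similarity, exactly as for real data -- so the generator
## exercises the similarity computation, and L is informative but
## redundant with A, mirroring the real construction.

#' Synthetic network configuration
#'
#' Defaults describe the package's reference fixture: 40 lncRNAs, 40
#' diseases, 30 miRNAs in 4 groups, with within-group association
#' probability 0.6 against a 0.05 background, and similarity noise 0.05.
#'
#' @param n_l,n_d,n_m entity counts.
#' @param n_groups latent groups (must not exceed any entity count).
#' @param p_in,p_out association probabilities for group-matched and
#'   unmatched pairs (`0 <= p_out < p_in <= 1`).
#' @param s_in,s_out baseline disease similarity within / across groups.
#' @param sim_noise standard deviation of the similarity perturbation.
#' @param decouple_mirna sample the miRNA relations (B, Y) from independent
#'   random groups, removing the miRNA branch's signal (ablation analogue;
#'   default `FALSE`).
#' @param seed integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_l = 40L, n_d = 40L, n_m = 30L, n_groups = 4L,
                             p_in = 0.6, p_out = 0.05, s_in = 0.8, s_out = 0.2,
                             sim_noise = 0.05, decouple_mirna = FALSE, seed = 1L) {
  cfg <- list(n_l = as.integer(n_l), n_d = as.integer(n_d), n_m = as.integer(n_m),
              n_groups = as.integer(n_groups), p_in = p_in, p_out = p_out,
              s_in = s_in, s_out = s_out, sim_noise = sim_noise,
              decouple_mirna = isTRUE(decouple_mirna), seed = as.integer(seed))
  for (nm in c("n_l", "n_d", "n_m", "n_groups"))
    if (!is_count(cfg[[nm]])) stopf("%s must be a positive integer", nm)
  if (!(cfg$p_out >= 0 && cfg$p_out < cfg$p_in && cfg$p_in <= 1))
    stopf("need 0 <= p_out < p_in <= 1 (got p_in = %g, p_out = %g)", cfg$p_in, cfg$p_out)
  if (cfg$n_groups > min(cfg$n_l, cfg$n_d, cfg$n_m))
    stopf("n_groups (%d) exceeds the smallest entity count (%d)",
          cfg$n_groups, min(cfg$n_l, cfg$n_d, cfg$n_m))
  if (cfg$sim_noise < 0) stopf("sim_noise must be non-negative")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic heterogeneous network
#'
#' @param cfg a `synthetic_config`.
#' @return List with `network` (a `hetero_network`) and `groups` (list of
#'   integer group assignments `lncrna`, `disease`, `mirna`).
#' @export
generate_network <- function(cfg) {
  if (!inherits(cfg, "synthetic_config")) cfg <- do.call(synthetic_config, cfg)
  with_seed(cfg$seed, {
    gl <- sample.int(cfg$n_groups, cfg$n_l, replace = TRUE)
    gd <- sample.int(cfg$n_groups, cfg$n_d, replace = TRUE)
    gm <- sample.int(cfg$n_groups, cfg$n_m, replace = TRUE)

    bern_block <- function(g_row, g_col) {
      match_ <- outer(g_row, g_col, `==`)
      p <- ifelse(match_, cfg$p_in, cfg$p_out)
      matrix(as.numeric(stats::runif(length(p)) < p), nrow(p), ncol(p))
    }
    A <- bern_block(gl, gd)
    D <- ifelse(outer(gd, gd, `==`), cfg$s_in, cfg$s_out)
    if (cfg$sim_noise > 0) {
      noise <- matrix(stats::rnorm(cfg$n_d^2, sd = cfg$sim_noise), cfg$n_d)
      D <- D + (noise + t(noise)) / 2
    }
    D <- pmin(pmax(D, 0), 1)
    D <- (D + t(D)) / 2
    diag(D) <- 1

    ## independent groups for the miRNA relations when decoupled; drawn
    ## after A and D so the ablation leaves those two matrices untouched
    gm_rel <- if (cfg$decouple_mirna) sample.int(cfg$n_groups, cfg$n_m, replace = TRUE) else gm
    gd_rel <- if (cfg$decouple_mirna) sample.int(cfg$n_groups, cfg$n_d, replace = TRUE) else gd
    gl_rel <- if (cfg$decouple_mirna) sample.int(cfg$n_groups, cfg$n_l, replace = TRUE) else gl
    B <- bern_block(gm_rel, gd_rel)
    Y <- bern_block(gl_rel, gm_rel)
    L <- lncrna_similarity_matrix(A, D)

    idx <- entity_index(sprintf("l%03d", seq_len(cfg$n_l)),
                        sprintf("d%03d", seq_len(cfg$n_d)),
                        sprintf("m%03d", seq_len(cfg$n_m)))
    nm <- function(M, rn, cn) { dimnames(M) <- list(rn, cn); M }
    net <- structure(list(
      index = idx,
      A = nm(A, idx$lncrna_names, idx$disease_names),
      B = nm(B, idx$mirna_names, idx$disease_names),
      Y = nm(Y, idx$lncrna_names, idx$mirna_names),
      D = nm(D, idx$disease_names, idx$disease_names),
      L = nm(L, idx$lncrna_names, idx$lncrna_names)
    ), class = "hetero_network")
    viol <- validate_network(net)
    if (length(viol) > 0L) stopf("generated network violates invariants: %s",
                                 paste(viol, collapse = "; "))
    list(network = net, groups = list(lncrna = gl, disease = gd, mirna = gm))
  })
}

#' Randomly flip association cells
#'
#' Degrades a network for robustness testing by flipping a uniformly
#' chosen fraction of the cells of `A` (0 -> 1 and 1 -> 0). The lncRNA
#' similarity is recomputed from the corrupted associations.
#'
#' @param net a `hetero_network`.
#' @param flip_fraction fraction of cells to flip, in `[0, 1]`.
#' @param seed integer seed.
#' @return A degraded copy of the network.
#' @export
corrupt_network <- function(net, flip_fraction, seed = 1L) {
  if (flip_fraction < 0 || flip_fraction > 1)
    stopf("flip_fraction must lie in [0, 1]")
  out <- net
  n_cells <- length(net$A)
  n_flip <- round(flip_fraction * n_cells)
  if (n_flip > 0L) {
    with_seed(seed, {
      cells <- sample.int(n_cells, n_flip)
      out$A[cells] <- 1 - out$A[cells]
    })
    L <- lncrna_similarity_matrix(out$A, out$D)
    dimnames(L) <- dimnames(net$L)
    out$L <- L
  }
  out
}

#' Write a synthetic network with its ground truth
#'
#' Writes the network bundle plus `ground_truth.tsv` (kind, name, group).
#'
#' @param gen output of [generate_network()].
#' @param dir directory path.
#' @export
write_synthetic_bundle <- function(gen, dir) {
  write_network_bundle(gen$network, dir)
  idx <- gen$network$index
  gt <- rbind(
    data.frame(kind = "lncrna", name = idx$lncrna_names, group = gen$groups$lncrna),
    data.frame(kind = "disease", name = idx$disease_names, group = gen$groups$disease),
    data.frame(kind = "mirna", name = idx$mirna_names, group = gen$groups$mirna)
  )
  utils::write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
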