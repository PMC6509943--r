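## Entity indexing, the five relation matrices and their tabular IO.
##
## A heterogeneous lncRNA-disease-miRNA network is held as five dense
## matrices over three named entity sets:
##   A (n_l x n_d)  binary lncRNA-disease associations
##   B (n_m x n_d)  binary miRNA-disease associations
##   Y (n_l x n_m)  binary lncRNA-miRNA interactions
##   D (n_d x n_d)  disease semantic similarities in [0, 1]
##   L (n_l x n_l)  lncRNA similarities in [0, 1]
## At the scale this model targets (a few hundred entities per set) dense
## storage is deliberate; sparse machinery would buy nothing.

SYM_TOL <- 1e-9

#' Create an entity index
#'
#' Holds the ordered name vectors of the three entity sets and their counts.
#' Row/column indices of every relation matrix refer to positions in these
#' vectors, so the index fixes the coordinate system of a network.
#'
#' @param lncrna_names,disease_names,mirna_names character vectors of unique,
#'   non-empty names.
#' @return An object of class `entity_index` with fields `lncrna_names`,
#'   `disease_names`, `mirna_names`, `n_l`, `n_d`, `n_m`.
#' @export
entity_index <- function(lncrna_names, disease_names, mirna_names) {
  check_names <- function(x, what) {
    x <- as.character(x)
    if (any(is.na(x) | !nzchar(x))) stopf("%s names must be non-empty", what)
    if (anyDuplicated(x)) stopf("duplicated %s names: %s", what,
                                paste(unique(x[duplicated(x)]), collapse = ", "))
    x
  }
  idx <- list(
    lncrna_names  = check_names(lncrna_names, "lncRNA"),
    disease_names = check_names(disease_names, "disease"),
    mirna_names   = check_names(mirna_names, "miRNA")
  )
  idx$n_l <- length(idx$lncrna_names)
  idx$n_d <- length(idx$disease_names)
  idx$n_m <- length(idx$mirna_names)
  structure(idx, class = "entity_index")
}

#' Read a two-column edge list
#'
#' Reads tab- or comma-separated `(left, right)` name pairs. A header row is
#' detected heuristically (both fields non-numeric and unrepeated names are
#' ambiguous, so the heuristic only fires when the first row equals common
#' column labels or `header = TRUE` is forced). Duplicate pairs collapse to
#' one with a warning.
#'
#' @param path file path.
#' @param header `"auto"` (default), `TRUE` or `FALSE`.
#' @param sep field separator; `NULL` (default) auto-detects tab then comma.
#' @return A data.frame with character columns `left` and `right`.
#' @export
load_edge_list <- function(path, header = "auto", sep = NULL) {
  if (!file.exists(path)) stopf("edge list file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("edge list file is empty: %s", path)
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    stopf("edge list %s: line %d has %d fields (expected 2)",
          path, which(nf != 2L)[1], nf[nf != 2L][1])
  }
  left  <- trimws(vapply(parts, `[[`, "", 1L))
  right <- trimws(vapply(parts, `[[`, "", 2L))
  drop_header <- isTRUE(header) ||
    (identical(header, "auto") &&
       tolower(left[1]) %in% c("lncrna", "mirna", "disease", "left", "source", "from", "name"))
  if (drop_header) {
    left <- left[-1]; right <- right[-1]
    if (length(left) == 0L) stopf("edge list %s contains only a header", path)
  }
  key <- paste(left, right, sep = "\r")
  if (anyDuplicated(key)) {
    warnf("edge list %s: %d duplicate pair(s) collapsed", path, sum(duplicated(key)))
    keep <- !duplicated(key)
    left <- left[keep]; right <- right[keep]
  }
  data.frame(left = left, right = right, stringsAsFactors = FALSE)
}

## Coerce various pair inputs (2-col data.frame/matrix/list) to a data.frame.
as_pairs <- function(x, what) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L)) {
    return(data.frame(left = character(), right = character(), stringsAsFactors = FALSE))
  }
  if (is.matrix(x)) x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!is.data.frame(x) || ncol(x) < 2L) stopf("%s must have two columns", what)
  data.frame(left = as.character(x[[1]]), right = as.character(x[[2]]),
             stringsAsFactors = FALSE)
}

#' Assemble a heterogeneous network from relation lists
#'
#' Builds the five relation matrices from three edge lists and a disease
#' similarity table. Entity universes are the unions over all inputs; names
#' are sorted lexicographically (C collation) so that indices are
#' deterministic across runs. When no lncRNA similarity table is supplied,
#' `L` is computed from `A` and `D` via [lncrna_similarity_matrix()].
#'
#' @param ld_pairs lncRNA-disease pairs (2 columns: lncRNA, disease).
#' @param md_pairs miRNA-disease pairs (2 columns: miRNA, disease).
#' @param lm_pairs lncRNA-miRNA pairs (2 columns: lncRNA, miRNA).
#' @param D named square disease-similarity matrix covering every disease
#'   appearing in the pair lists.
#' @param L optional named square lncRNA-similarity matrix; computed from
#'   `A` and `D` when `NULL`.
#' @param sort_names sort entity names lexicographically (default `TRUE`);
#'   otherwise first-appearance order is kept.
#' @return An object of class `hetero_network` with fields `index`, `A`,
#'   `B`, `Y`, `D`, `L`.
#' @export
assemble_network <- function(ld_pairs, md_pairs = NULL, lm_pairs = NULL,
                             D, L = NULL, sort_names = TRUE) {
  ld <- as_pairs(ld_pairs, "ld_pairs")
  md <- as_pairs(md_pairs, "md_pairs")
  lm <- as_pairs(lm_pairs, "lm_pairs")
  if (!is.matrix(D) || nrow(D) != ncol(D) || is.null(rownames(D)) || is.null(colnames(D)))
    stopf("D must be a square matrix with disease names on rows and columns")

  uniq <- function(x) unique(x[nzchar(x)])
  lnc <- uniq(c(ld$left, lm$left))
  dis <- uniq(c(ld$right, md$right))
  mir <- uniq(c(md$left, lm$right))
  if (sort_names) {
    lnc <- sort(lnc, method = "radix")
    dis <- sort(dis, method = "radix")
    mir <- sort(mir, method = "radix")
  }
  missing_d <- setdiff(dis, rownames(D))
  if (length(missing_d) > 0L)
    stopf("disease(s) absent from the similarity table: %s",
          paste(missing_d, collapse = ", "))
  extra_d <- setdiff(rownames(D), dis)
  if (length(extra_d) > 0L)
    warnf("%d disease(s) in the similarity table appear in no relation list and are dropped",
          length(extra_d))
  idx <- entity_index(lnc, dis, mir)

  fill <- function(nr, nc, rn, cn, lefts, rights, what) {
    M <- matrix(0, nr, nc, dimnames = list(rn, cn))
    if (length(lefts) > 0L) {
      i <- match(lefts, rn); j <- match(rights, cn)
      bad <- is.na(i) | is.na(j)
      if (any(bad)) stopf("%s: unknown entity in pair (%s, %s)", what,
                          lefts[bad][1], rights[bad][1])
      M[cbind(i, j)] <- 1
    }
    M
  }
  A <- fill(idx$n_l, idx$n_d, lnc, dis, ld$left, ld$right, "ld_pairs")
  B <- fill(idx$n_m, idx$n_d, mir, dis, md$left, md$right, "md_pairs")
  Y <- fill(idx$n_l, idx$n_m, lnc, mir, lm$left, lm$right, "lm_pairs")

  Dm <- D[dis, dis, drop = FALSE]
  if (max(abs(Dm - t(Dm))) > SYM_TOL)
    stopf("disease similarity matrix is asymmetric beyond tolerance %g", SYM_TOL)
  Dm <- (Dm + t(Dm)) / 2
  diag(Dm) <- 1

  if (is.null(L)) {
    Lm <- lncrna_similarity_matrix(A, Dm)
    dimnames(Lm) <- list(lnc, lnc)
  } else {
    missing_l <- setdiff(lnc, rownames(L))
    if (length(missing_l) > 0L)
      stopf("lncRNA(s) absent from the similarity table: %s",
            paste(missing_l, collapse = ", "))
    Lm <- L[lnc, lnc, drop = FALSE]
    if (max(abs(Lm - t(Lm))) > SYM_TOL)
      stopf("lncRNA similarity matrix is asymmetric beyond tolerance %g", SYM_TOL)
    Lm <- (Lm + t(Lm)) / 2
    diag(Lm) <- 1
  }

  net <- structure(list(index = idx, A = A, B = B, Y = Y, D = Dm, L = Lm),
                   class = "hetero_network")
  viol <- validate_network(net)
  if (length(viol) > 0L) stopf("assembled network violates invariants: %s",
                               paste(viol, collapse = "; "))
  net
}

#' Validate a heterogeneous network
#'
#' Checks every structural invariant (binarity of A/B/Y, symmetry, range and
#' unit diagonal of D/L, dimension agreement with the entity index) and
#' returns the violations found. Never throws; an empty character vector
#' means the network is valid.
#'
#' @param net a `hetero_network`.
#' @return Character vector of violation descriptions (empty if valid).
#' @export
validate_network <- function(net) {
  v <- character()
  idx <- net$index
  chk_dim <- function(M, nr, nc, what) {
    if (!is.matrix(M) || nrow(M) != nr || ncol(M) != nc)
      sprintf("%s must be %d x %d", what, nr, nc)
    else NULL
  }
  v <- c(v,
         chk_dim(net$A, idx$n_l, idx$n_d, "A"),
         chk_dim(net$B, idx$n_m, idx$n_d, "B"),
         chk_dim(net$Y, idx$n_l, idx$n_m, "Y"),
         chk_dim(net$D, idx$n_d, idx$n_d, "D"),
         chk_dim(net$L, idx$n_l, idx$n_l, "L"))
  for (nm in c("A", "B", "Y")) {
    if (is.matrix(net[[nm]]) && !is_binary(net[[nm]]))
      v <- c(v, sprintf("%s contains entries outside {0, 1}", nm))
  }
  for (nm in c("D", "L")) {
    M <- net[[nm]]
    if (!is.matrix(M) || nrow(M) != ncol(M)) next
    if (max(abs(M - t(M))) > SYM_TOL)
      v <- c(v, sprintf("%s is asymmetric beyond tolerance %g", nm, SYM_TOL))
    if (any(M < 0 | M > 1))
      v <- c(v, sprintf("%s has entries outside [0, 1]", nm))
    if (nrow(M) > 0 && any(abs(diag(M) - 1) > SYM_TOL))
      v <- c(v, sprintf("%s diagonal entries differ from 1", nm))
  }
  v
}

#' @export
print.hetero_network <- function(x, ...) {
  idx <- x$index
  cat(sprintf("hetero_network: %d lncRNAs, %d diseases, %d miRNAs\n",
              idx$n_l, idx$n_d, idx$n_m))
  cat(sprintf("  known lncRNA-disease associations: %d\n", sum(x$A)))
  cat(sprintf("  known miRNA-disease associations:  %d\n", sum(x$B)))
  cat(sprintf("  known lncRNA-miRNA interactions:   %d\n", sum(x$Y)))
  invisible(x)
}

#' Write / read a square similarity matrix
#'
#' The tabular format has entity names as the first row and first column;
#' cell `(i, j)` holds the similarity. Values are written with 6 significant
#' digits.
#'
#' @param M named square numeric matrix.
#' @param path file path.
#' @rdname similarity_io
#' @export
write_similarity_matrix <- function(M, path) {
  df <- data.frame(name = rownames(M), signif(M, 6), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname similarity_io
#' @export
read_similarity_matrix <- function(path) {
  if (!file.exists(path)) stopf("similarity matrix file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- as.character(df[[1]])
  storage.mode(M) <- "double"
  M
}

#' Write / read a network bundle directory
#'
#' A bundle is a directory holding `A.tsv`, `B.tsv`, `Y.tsv`, `D.tsv`,
#' `L.tsv` (square tabular format with names) plus `entities.tsv` listing
#' `(kind, name)` in index order.
#'
#' @param net a `hetero_network`.
#' @param dir directory path (created if absent).
#' @rdname bundle_io
#' @export
write_network_bundle <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("A", "B", "Y", "D", "L"))
    write_similarity_matrix(net[[nm]], file.path(dir, paste0(nm, ".tsv")))
  ent <- rbind(
    data.frame(kind = "lncrna",  name = net$index$lncrna_names),
    data.frame(kind = "disease", name = net$index$disease_names),
    data.frame(kind = "mirna",   name = net$index$mirna_names)
  )
  utils::write.table(ent, file.path(dir, "entities.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname bundle_io
#' @export
read_network_bundle <- function(dir) {
  ent_path <- file.path(dir, "entities.tsv")
  if (!file.exists(ent_path)) stopf("not a network bundle (no entities.tsv): %s", dir)
  ent <- utils::read.table(ent_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  idx <- entity_index(ent$name[ent$kind == "lncrna"],
                      ent$name[ent$kind == "disease"],
                      ent$name[ent$kind == "mirna"])
  mats <- lapply(c(A = "A", B = "B", Y = "Y", D = "D", L = "L"), function(nm) {
    read_similarity_matrix(file.path(dir, paste0(nm, ".tsv")))
  })
  net <- structure(c(list(index = idx), mats), class = "hetero_network")
  viol <- validate_network(net)
  if (length(viol) > 0L) stopf("bundle %s violates invariants: %s", dir,
                               paste(viol, collapse = "; "))
  net
}
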