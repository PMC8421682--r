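#' Pearson correlation network of gene profiles
#'
#' Computes the gene-by-gene Pearson correlation matrix of a profile matrix
#' (genes in rows, samples in columns). The diagonal is set to 0. Genes
#' with zero variance across samples get all their correlations set to 0,
#' with a warning.
#'
#' @param profiles a numeric matrix with genes in rows (rownames used as
#'   gene labels), or a data frame whose first column holds gene identifiers
#'   and remaining columns numeric sample values.
#' @return A symmetric gene x gene correlation matrix with zero diagonal and
#'   gene labels as dimnames.
#' @export
correlation_network <- function(profiles) {
  v <- as_profile_matrix(profiles)
  if (ncol(v) < 3) abort("at least 3 samples are required for correlation.")
  sds <- apply(v, 1, stats::sd)
  R <- suppressWarnings(stats::cor(t(v)))
  if (any(sds == 0)) {
    warn(sprintf("%d gene(s) with zero variance; their correlations set to 0.",
                 sum(sds == 0)))
    R[sds == 0, ] <- 0
    R[, sds == 0] <- 0
  }
  diag(R) <- 0
  R
}

## coerce matrix / gene-column data frame to a labelled genes x samples matrix,
## dropping rows with missing values (imputation is out of scope)
as_profile_matrix <- function(profiles) {
  if (is.data.frame(profiles)) {
    labels <- as.character(profiles[[1]])
    v <- as.matrix(profiles[, -1, drop = FALSE])
    storage.mode(v) <- "double"
    rownames(v) <- labels
  } else {
    v <- as.matrix(profiles)
    storage.mode(v) <- "double"
    if (is.null(rownames(v))) rownames(v) <- paste0("g", seq_len(nrow(v)))
  }
  drop <- rowSums(is.na(v)) > 0
  if (any(drop)) {
    inform(sprintf("dropped %d gene(s) with missing values.", sum(drop)))
    v <- v[!drop, , drop = FALSE]
  }
  if (anyDuplicated(rownames(v))) abort("duplicated gene labels.")
  v
}

#' PCIT noise filter for a correlation network
#'
#' Implements the partial-correlation-and-information-theory test of
#' Reverter & Chan. For every trio of genes `(x, y, z)` the three
#' first-order partial correlations are computed; the tolerance for judging
#' edge `(x, y)` against `z` is the average ratio of partial to direct
#' correlation of the two flanking edges,
#' `eps = 0.5 (|r_xz.y / r_xz| + |r_yz.x / r_yz|)`, and the trio flags
#' `(x, y)` when `|r_xy| < eps |r_xz|` and `|r_xy| < eps |r_yz|`. An edge
#' is removed only if **every** third gene flags it as the weakest of its
#' trio; surviving edges are weighted by `|r|`. Trios whose ratios are
#' undefined (direct correlation ~ 0) are skipped; partial correlations with
#' a degenerate denominator (`|r| = 1`) are treated as 0 with a warning.
#'
#' The filter never adds edges and is invariant to positive rescaling of
#' any gene's profile (it only sees correlations).
#'
#' @param corr symmetric correlation matrix with zero diagonal, as returned
#'   by [correlation_network()].
#' @return A symmetric, non-negative, zero-diagonal adjacency matrix (a
#'   valid [multinet] layer).
#' @export
pcit_filter <- function(corr) {
  R <- as.matrix(corr)
  n <- nrow(R)
  if (n != ncol(R) || any(abs(R - t(R)) > 1e-8)) {
    abort("`corr` must be a symmetric square matrix.")
  }
  diag(R) <- 0
  if (n <= 2) {
    A <- abs(R)
    diag(A) <- 0
    return(A)
  }
  tiny <- 1e-12
  degenerate <- FALSE
  ## P[, , g]: first-order partial correlations given gene g
  P <- array(0, dim = c(n, n, n))
  for (g in seq_len(n)) {
    cg <- R[, g]
    den2 <- outer(1 - cg^2, 1 - cg^2)
    bad <- den2 <= tiny
    if (any(bad[upper.tri(bad)])) degenerate <- TRUE
    den <- sqrt(pmax(den2, tiny))
    Pg <- (R - outer(cg, cg)) / den
    Pg[bad] <- 0
    Pg[g, ] <- 0
    Pg[, g] <- 0
    diag(Pg) <- 0
    P[, , g] <- Pg
  }
  if (degenerate) {
    warn("correlations with |r| = 1 encountered; partial correlations treated as 0.")
  }
  absR <- abs(R)
  flags <- matrix(0, n, n)  # trios flagging the edge as weakest
  valid <- matrix(0, n, n)  # trios with defined ratios
  for (z in seq_len(n)) {
    rz <- absR[, z]
    M1 <- abs(P[, z, ])              # M1[x, y] = |r_xz.y|
    ok <- rz > tiny                   # ratio defined for row x / col y
    Q <- M1 / ifelse(rz > tiny, rz, 1)
    Q[!ok, ] <- NA
    eps <- 0.5 * (Q + t(Q))           # eps[x, y], NA where undefined
    cond <- (absR < eps * rz) & (absR < eps * matrix(rz, n, n, byrow = TRUE))
    cond[is.na(cond)] <- FALSE
    cond[z, ] <- FALSE
    cond[, z] <- FALSE
    ok2 <- !is.na(eps)
    ok2[z, ] <- FALSE
    ok2[, z] <- FALSE
    flags <- flags + cond
    valid <- valid + ok2
  }
  removed <- valid > 0 & flags == valid
  A <- absR
  A[removed] <- 0
  A[absR == 0] <- 0
  diag(A) <- 0
  dimnames(A) <- dimnames(corr)
  A
}

#' Build a two-layer network from expression and methylation profiles
#'
#' Constructs the gene co-expression layer and the gene co-methylation layer
#' over the genes common to both profile matrices: each layer is the Pearson
#' correlation network of the profiles after the PCIT trio filter, with
#' `|r|` edge weights.
#'
#' @param expr,meth profile matrices (see [correlation_network()]).
#' @return A two-layer [multinet] over the sorted common genes (layer 1:
#'   `expr`, layer 2: `meth`).
#' @export
build_multinet <- function(expr, meth) {
  ve <- as_profile_matrix(expr)
  vm <- as_profile_matrix(meth)
  genes <- sort(intersect(rownames(ve), rownames(vm)))
  if (length(genes) < 10) {
    abort(sprintf("only %d gene(s) shared between the profiles; >= 10 required.",
                  length(genes)))
  }
  inform(sprintf("building layers over %d shared genes.", length(genes)))
  layer <- function(v) pcit_filter(correlation_network(v[genes, , drop = FALSE]))
  multinet(list(unname(layer(ve)), unname(layer(vm))), labels = genes)
}

#' Read a gene profile matrix from TSV
#'
#' Expects genes in rows; the first column holds gene identifiers and the
#' header row holds sample identifiers.
#'
#' @param path file path.
#' @return A numeric genes x samples matrix with gene rownames.
#' @export
read_profiles <- function(path) {
  t <- readr::read_tsv(path, col_types = readr::cols())
  as_profile_matrix(as.data.frame(t))
}
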