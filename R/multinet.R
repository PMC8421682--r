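#' Multilayer network over a shared vertex set
#'
#' A `multinet` holds an ordered collection of `M` symmetric, non-negative,
#' zero-diagonal weight matrices over one fixed vertex set of size `n`.
#' It is the container every fitting and scoring function in the package
#' operates on: the layers are typically a gene co-expression network and a
#' gene co-methylation network over the same genes, or snapshots of a
#' simulated benchmark.
#'
#' Layers are validated on construction: weights must be non-negative and
#' finite; small asymmetries (relative tolerance `1e-8`) are symmetrized as
#' `(W + t(W)) / 2` with a warning, larger ones are an error; any diagonal
#' entries (self-loops) are stripped with a warning.
#'
#' @param layers list of `n x n` numeric matrices, one per layer.
#' @param labels optional character vector of vertex labels; defaults to the
#'   dimnames of the first layer, or `v1..vn`.
#' @return An object of class `multinet` with fields `W` (list of layer
#'   matrices), `n`, `M` and `labels`.
#' @examples
#' A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
#' net <- multinet(list(A, A))
#' net
#' @export
multinet <- function(layers, labels = NULL) {
  if (!is.list(layers) || length(layers) == 0) {
    abort("`layers` must be a non-empty list of square matrices.")
  }
  layers <- lapply(layers, function(W) {
    W <- as.matrix(W)
    storage.mode(W) <- "double"
    W
  })
  n <- nrow(layers[[1]])
  for (m in seq_along(layers)) {
    W <- layers[[m]]
    if (nrow(W) != ncol(W) || nrow(W) != n) {
      abort(sprintf("layer %d is not a %d x %d square matrix.", m, n, n))
    }
    if (any(!is.finite(W))) {
      abort(sprintf("layer %d contains non-finite weights.", m))
    }
    asym <- abs(W - t(W)) > 1e-8 * pmax(1, abs(W))
    if (any(asym)) {
      abort(sprintf("layer %d is not symmetric within tolerance.", m))
    }
    if (any(W != t(W))) {
      warn(sprintf("layer %d symmetrized as (W + t(W)) / 2.", m))
      W <- (W + t(W)) / 2
    }
    if (any(diag(W) != 0)) {
      warn(sprintf("layer %d: self-loops stripped (diagonal zeroed).", m))
      diag(W) <- 0
    }
    if (any(W < 0)) {
      abort(sprintf("layer %d has negative weights.", m))
    }
    layers[[m]] <- unname(W)
  }
  if (is.null(labels)) {
    labels <- rownames(layers[[1]])
    if (is.null(labels)) labels <- paste0("v", seq_len(n))
  }
  if (length(labels) != n || anyDuplicated(labels)) {
    abort("`labels` must be `n` unique vertex identifiers.")
  }
  structure(
    list(W = layers, n = n, M = length(layers), labels = as.character(labels)),
    class = "multinet"
  )
}

#' @export
print.multinet <- function(x, ...) {
  edges <- vapply(x$W, function(W) sum(W[upper.tri(W)] > 0), numeric(1))
  cat(sprintf("<multinet> %d vertices, %d layer%s\n", x$n, x$M,
              if (x$M == 1) "" else "s"))
  for (m in seq_len(x$M)) {
    cat(sprintf("  layer %d: %d edges, total weight %.4g\n",
                m, edges[m], sum(x$W[[m]]) / 2))
  }
  invisible(x)
}

#' @export
#' @rdname multinet
is_multinet <- function(x) inherits(x, "multinet")

check_layer <- function(net, layer) {
  if (!is.numeric(layer) || length(layer) != 1 || layer < 1 || layer > net$M) {
    abort(sprintf("`layer` must be a single index in 1..%d.", net$M))
  }
  as.integer(layer)
}

check_vertices <- function(net, v) {
  if (is.character(v)) {
    idx <- match(v, net$labels)
    if (anyNA(idx)) abort("unknown vertex label(s).")
    return(idx)
  }
  v <- as.integer(v)
  if (any(v < 1 | v > net$n)) {
    abort(sprintf("vertex index out of range 1..%d.", net$n))
  }
  v
}

#' Convert a multilayer network to a tidy edge table
#'
#' @param x a [multinet].
#' @param ... unused.
#' @return A tibble with columns `layer`, `source`, `target`, `weight`, one
#'   row per undirected edge (upper triangle only).
#' @export
as_tibble.multinet <- function(x, ...) {
  purrr::map_dfr(seq_len(x$M), function(m) {
    W <- x$W[[m]]
    idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
    tibble(
      layer = m,
      source = x$labels[idx[, 1]],
      target = x$labels[idx[, 2]],
      weight = W[idx]
    )
  })
}

#' Read a multilayer network from per-layer edge-list files
#'
#' Each file is a tab-separated table with columns `source`, `target`,
#' `weight`. The vertex set is the union of all labels seen in any layer,
#' sorted lexicographically, and is identical across layers; vertices absent
#' from a layer's edge list are isolated in that layer.
#'
#' @param files character vector of file paths, one per layer, in layer order.
#' @return A [multinet].
#' @seealso [write_multinet()] for the inverse.
#' @export
read_multinet_edges <- function(files) {
  tabs <- lapply(files, function(f) {
    readr::read_tsv(f, col_types = readr::cols(
      source = readr::col_character(),
      target = readr::col_character(),
      weight = readr::col_double()
    ))
  })
  labels <- sort(unique(unlist(lapply(tabs, function(t) c(t$source, t$target)))))
  n <- length(labels)
  layers <- lapply(tabs, function(t) {
    W <- matrix(0, n, n, dimnames = list(labels, labels))
    i <- match(t$source, labels)
    j <- match(t$target, labels)
    W[cbind(i, j)] <- t$weight
    W[cbind(j, i)] <- t$weight
    W
  })
  multinet(layers, labels = labels)
}

#' Read a multilayer network from dense adjacency files
#'
#' Each file is a tab-separated square matrix with a header row and a first
#' column of vertex labels. All layers must present the same label set; rows
#' are reordered to the lexicographically sorted common order.
#'
#' @inheritParams read_multinet_edges
#' @return A [multinet].
#' @export
read_multinet_adjacency <- function(files) {
  layers <- lapply(files, function(f) {
    t <- readr::read_tsv(f, col_types = readr::cols())
    labels <- as.character(t[[1]])
    W <- as.matrix(t[, -1])
    storage.mode(W) <- "double"
    dimnames(W) <- list(labels, colnames(t)[-1])
    W <- W[, labels, drop = FALSE]  # align columns to row labels
    ord <- order(labels)
    W[ord, ord, drop = FALSE]
  })
  labels <- rownames(layers[[1]])
  for (W in layers) {
    if (!identical(rownames(W), labels)) abort("layers disagree on vertex labels.")
  }
  multinet(lapply(layers, unname), labels = labels)
}

#' Write a multilayer network as per-layer edge lists plus a vertex manifest
#'
#' Writes `prefix_1.tsv`, ..., `prefix_M.tsv` (columns `source`, `target`,
#' `weight`) and `prefix_vertices.tsv` recording the vertex order, so that
#' isolated vertices survive a round trip.
#'
#' @param net a [multinet].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix, default `"layer"`.
#' @return Invisibly, the written file paths.
#' @export
write_multinet <- function(net, dir, prefix = "layer") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  edges <- as_tibble(net)
  paths <- character(0)
  for (m in seq_len(net$M)) {
    p <- file.path(dir, sprintf("%s_%d.tsv", prefix, m))
    readr::write_tsv(dplyr::select(dplyr::filter(edges, .data$layer == m),
                                   "source", "target", "weight"), p)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, sprintf("%s_vertices.tsv", prefix))
  readr::write_tsv(tibble(vertex = net$labels), mp)
  invisible(c(paths, mp))
}
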