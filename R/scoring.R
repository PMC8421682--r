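#' Vertex degree in one layer
#'
#' The weighted degree of vertex `v` in layer `layer`: the sum of the
#' weights on its incident edges.
#'
#' @param net a [multinet].
#' @param layer layer index in `1..M`.
#' @param v vertex index (or label). If omitted, degrees of all vertices.
#' @return Numeric degree(s).
#' @export
vertex_degree <- function(net, layer, v = NULL) {
  layer <- check_layer(net, layer)
  d <- rowSums(net$W[[layer]])
  if (is.null(v)) return(setNames(d, net$labels))
  d[check_vertices(net, v)]
}

#' Shortest-path betweenness centrality in one layer
#'
#' Counts, over unordered vertex pairs (each pair once), the fraction of
#' shortest paths between the pair that pass through `v`. Paths are counted
#' on the unweighted support of the layer (an edge is any pair with weight
#' `> 0`); pairs with no connecting path contribute 0.
#'
#' @inheritParams vertex_degree
#' @return Numeric betweenness value(s).
#' @export
vertex_betweenness <- function(net, layer, v = NULL) {
  layer <- check_layer(net, layer)
  g <- igraph::graph_from_adjacency_matrix(net$W[[layer]] > 0, mode = "undirected")
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  if (is.null(v)) return(setNames(as.numeric(b), net$labels))
  as.numeric(b)[check_vertices(net, v)]
}

#' Edge density of a vertex set in one layer
#'
#' `2 |E(C)| / (|C| (|C| - 1))` where `E(C)` are the edges of the induced
#' subgraph. For weighted layers an edge is any pair with weight strictly
#' positive; weights themselves enter the modularity-density score instead.
#'
#' @inheritParams vertex_degree
#' @param C vertex indices or labels of the candidate module.
#' @return Density in `[0, 1]`; `0` with a warning when `|C| <= 1`.
#' @export
module_density <- function(net, layer, C) {
  layer <- check_layer(net, layer)
  C <- check_vertices(net, C)
  if (length(C) <= 1) {
    warn("module has fewer than 2 vertices; density defined as 0.")
    return(0)
  }
  S <- net$W[[layer]][C, C, drop = FALSE]
  edges <- sum(S[upper.tri(S)] > 0)
  2 * edges / (length(C) * (length(C) - 1))
}

#' Modularity density of a vertex set in one layer
#'
#' The connectivity score of module `C` in layer `m`:
#' \deqn{D_m(C) = \frac{L(C, C) - L(C, \bar C)}{\sum_{v_i \in C} d_{im}}}
#' where `L(C, C)` sums the weights between ordered pairs inside `C` (twice
#' the intra-module weight), `L(C, C-bar)` sums weights leaving `C`, and the
#' denominator is the total degree of `C` in the layer. The whole vertex set
#' of any layer with positive total weight scores exactly 1.
#'
#' @inheritParams module_density
#' @return A real score (can be negative); `0` with a warning when every
#'   vertex of `C` is isolated in the layer.
#' @export
modularity_density <- function(net, layer, C) {
  layer <- check_layer(net, layer)
  C <- check_vertices(net, C)
  W <- net$W[[layer]]
  deg <- sum(W[C, , drop = FALSE])
  if (deg <= 0) {
    warn("all vertices of the module are isolated in this layer; score 0.")
    return(0)
  }
  intra <- sum(W[C, C, drop = FALSE])          # both orientations
  inter <- deg - intra                          # weight leaving C
  (intra - inter) / deg
}

#' Multi-layer connectivity of a vertex set
#'
#' The geometric mean over layers of the per-layer modularity density,
#' \eqn{(\prod_m D_m(C))^{1/M}}. A common module must be well connected in
#' every layer simultaneously, so if any layer's score is non-positive the
#' geometric mean is defined as 0 (flooring the quality of modules that fail
#' in at least one layer).
#'
#' @inheritParams module_density
#' @return A score in `[0, 1]` for modules, `0` if any layer scores `<= 0`.
#' @export
multi_connectivity <- function(net, C) {
  d <- vapply(seq_len(net$M), function(m) modularity_density(net, m, C),
              numeric(1))
  if (any(d <= 0)) return(0)
  exp(mean(log(d)))
}

#' Quality of a full partition of a multilayer network
#'
#' The sum over modules of their multi-layer connectivity
#' ([multi_connectivity()]); the quantity the joint factorization seeks to
#' drive up. Invariant to relabeling of modules and to consistent
#' permutation of vertices across layers.
#'
#' @param net a [multinet].
#' @param p a [partition] (or plain assignment vector) over `net`'s vertices.
#' @return A non-negative real score.
#' @export
partition_score <- function(net, p) {
  p <- check_partition(net, p)
  sum(vapply(module_members(p), function(C) multi_connectivity(net, C),
             numeric(1)))
}

#' Per-module diagnostics table
#'
#' @param net a [multinet].
#' @param p a [partition] over `net`'s vertices.
#' @return A tibble with one row per module x layer: `module`, `size`,
#'   `multi_connectivity` (repeated across the module's rows), `layer`,
#'   `density`, `modularity_density`.
#' @export
module_diagnostics <- function(net, p) {
  p <- check_partition(net, p)
  members <- module_members(p)
  purrr::map_dfr(seq_along(members), function(l) {
    C <- members[[l]]
    mc <- suppressWarnings(multi_connectivity(net, C))
    purrr::map_dfr(seq_len(net$M), function(m) {
      tibble(
        module = l,
        size = length(C),
        multi_connectivity = mc,
        layer = m,
        density = suppressWarnings(module_density(net, m, C)),
        modularity_density = suppressWarnings(modularity_density(net, m, C))
      )
    })
  })
}
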