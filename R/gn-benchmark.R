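#' Configuration for the planted-partition (GN) multilayer benchmark
#'
#' The classic Girvan-Newman style benchmark: `n` vertices in `q` planted
#' communities of equal size `n / q`; every vertex has expected total degree
#' `degree`, of which `z_out` edges on average connect to other communities
#' ("noise") and `degree - z_out` stay inside. Edges are sampled
#' independently with `p_in = (degree - z_out) / (n/q - 1)` and
#' `p_out = z_out / (n - n/q)`, so the degree constraint holds in
#' expectation (the classic benchmark fixes average degree, not exact
#' regularity).
#'
#' @param n vertex count (default 128); must be divisible by `q`.
#' @param q number of planted communities (default 4).
#' @param degree expected per-vertex degree (default 16).
#' @param z_out expected inter-community edges per vertex (default 1);
#'   must satisfy `0 <= z_out <= degree` and yield edge probabilities in
#'   `[0, 1]`.
#' @param M number of layers (default 2).
#' @param seed master RNG seed (default 1); per-layer streams are derived
#'   from it so layers are independent but reproducible.
#' @return A `gn_config` list.
#' @export
gn_config <- function(n = 128, q = 4, degree = 16, z_out = 1, M = 2, seed = 1) {
  if (n %% q != 0) abort("`n` must be divisible by `q`.")
  if (z_out < 0 || z_out > degree) abort("`z_out` must lie in [0, degree].")
  check_gn_probs(n, q, degree, z_out)
  structure(list(n = as.integer(n), q = as.integer(q), degree = degree,
                 z_out = z_out, M = as.integer(M), seed = as.integer(seed)),
            class = "gn_config")
}

check_gn_probs <- function(n, q, degree, z_out) {
  size <- n / q
  p_in <- (degree - z_out) / (size - 1)
  p_out <- z_out / (n - size)
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1) {
    abort(sprintf("edge probabilities out of [0,1] (p_in = %.3f, p_out = %.3f).",
                  p_in, p_out))
  }
  c(p_in = p_in, p_out = p_out)
}

#' Sample one benchmark snapshot (a single layer)
#'
#' @param cfg a [gn_config()].
#' @param layer layer index; selects the derived RNG stream.
#' @param z_out optional noise override for this layer (used by the
#'   heterogeneous benchmark).
#' @return A list with `adjacency` (symmetric 0/1 matrix) and `partition`
#'   (the planted [partition]).
#' @export
gn_snapshot <- function(cfg, layer = 1, z_out = cfg$z_out) {
  size <- cfg$n / cfg$q
  p <- check_gn_probs(cfg$n, cfg$q, cfg$degree, z_out)
  truth <- rep(seq_len(cfg$q), each = size)
  W <- matrix(0, cfg$n, cfg$n)
  iu <- which(upper.tri(W))
  same <- (outer(truth, truth, "=="))[iu]
  prob <- ifelse(same, p["p_in"], p["p_out"])
  withr::with_seed(derive_seed(cfg$seed, layer), {
    W[iu] <- rbinom(length(prob), 1, prob)
  })
  W <- W + t(W)
  labels <- sprintf("v%0*d", nchar(cfg$n), seq_len(cfg$n))
  dimnames(W) <- list(labels, labels)
  list(adjacency = W, partition = partition(truth, labels = labels))
}

#' Homogeneous multilayer benchmark
#'
#' All `M` layers are independent snapshots with the same noise level
#' `z_out` and share the planted partition.
#'
#' @param cfg a [gn_config()].
#' @return A list with `net` (a [multinet]) and `partition` (the planted
#'   ground truth).
#' @export
gn_homo_net <- function(cfg) {
  snaps <- lapply(seq_len(cfg$M), function(m) gn_snapshot(cfg, layer = m))
  list(
    net = multinet(lapply(snaps, function(s) unname(s$adjacency)),
                   labels = attr(snaps[[1]]$partition, "labels")),
    partition = snaps[[1]]$partition
  )
}

#' Heterogeneous multilayer benchmark
#'
#' Layer 1 uses noise `z_fixed`; the remaining layers use `z_var`. All
#' layers share the planted partition (common modules must exist across
#' layers).
#'
#' @param cfg a [gn_config()] (its `z_out` field is ignored).
#' @param z_fixed noise level of the first layer (default 4).
#' @param z_var noise level of layers `2..M`.
#' @return As [gn_homo_net()].
#' @export
gn_heter_net <- function(cfg, z_fixed = 4, z_var = 1) {
  z <- c(z_fixed, rep(z_var, cfg$M - 1))
  snaps <- lapply(seq_len(cfg$M), function(m) {
    gn_snapshot(cfg, layer = m, z_out = z[m])
  })
  list(
    net = multinet(lapply(snaps, function(s) unname(s$adjacency)),
                   labels = attr(snaps[[1]]$partition, "labels")),
    partition = snaps[[1]]$partition
  )
}
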