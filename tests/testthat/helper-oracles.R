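## Independent oracles and fixture builders shared across the suite.
## Everything here is deliberately written from first principles (loops and
## direct sums), not via the package's own code paths.

## Entropy-based NMI oracle: 2 * I(A; B) / (H(A) + H(B)) from the joint
## label distribution, natural logs.
nmi_oracle <- function(a, b) {
  a <- as.integer(factor(a))
  b <- as.integer(factor(b))
  n <- length(a)
  pj <- table(a, b) / n
  pa <- rowSums(pj)
  pb <- colSums(pj)
  H <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  I <- 0
  for (i in seq_along(pa)) {
    for (j in seq_along(pb)) {
      if (pj[i, j] > 0) I <- I + pj[i, j] * log(pj[i, j] / (pa[i] * pb[j]))
    }
  }
  if (H(pa) + H(pb) == 0) {
    return(if (length(pa) == 1 && length(pb) == 1) 1 else 0)
  }
  as.numeric(2 * I / (H(pa) + H(pb)))
}

## Brute-force partition quality: per-module, per-layer connectivity
## (intra minus inter weight over module degree), geometric mean across
## layers floored at 0 when any layer is non-positive, summed over modules.
brute_score <- function(layers, assignment) {
  mods <- unique(assignment)
  total <- 0
  for (l in mods) {
    C <- which(assignment == l)
    ds <- numeric(length(layers))
    for (m in seq_along(layers)) {
      W <- layers[[m]]
      deg <- 0
      intra <- 0
      for (i in C) {
        deg <- deg + sum(W[i, ])
        for (j in C) intra <- intra + W[i, j]
      }
      ds[m] <- if (deg <= 0) 0 else (intra - (deg - intra)) / deg
    }
    total <- total + if (any(ds <= 0)) 0 else prod(ds)^(1 / length(ds))
  }
  total
}

## all assignments of n vertices into exactly k = 2 non-empty modules
## (each partition appears once; vertex 1 pinned to module 1)
all_two_partitions <- function(n) {
  out <- list()
  for (code in 1:(2^(n - 1) - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n - 1)]
    out[[length(out) + 1]] <- c(1L, bits + 1L)
  }
  out
}

## two disjoint 4-cliques, duplicated across `M` layers
two_clique_net <- function(M = 2) {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1
  W[5:8, 5:8] <- 1
  diag(W) <- 0
  multinet(rep(list(W), M))
}

## random symmetric non-negative zero-diagonal multilayer network
rand_multinet <- function(n, M, seed, density = 0.5) {
  set.seed(seed)
  layers <- lapply(seq_len(M), function(m) {
    W <- matrix(0, n, n)
    iu <- which(upper.tri(W))
    w <- runif(length(iu)) * (runif(length(iu)) < density)
    W[iu] <- w
    W + t(W)
  })
  multinet(layers)
}

## random strictly positive factor set matching a net
rand_factors <- function(net, k, seed, tri = TRUE) {
  set.seed(seed)
  list(
    B = matrix(runif(net$n * k) + 0.05, net$n, k),
    H = if (tri) matrix(runif(k * k) + 0.05, k, k) else NULL,
    F = lapply(seq_len(net$M), function(m) matrix(runif(k * net$n) + 0.05, k, net$n))
  )
}

## random partition of n vertices into at most kmax modules
rand_partition <- function(n, kmax) {
  partition(sample.int(kmax, n, replace = TRUE))
}
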