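#' Joint non-negative matrix factorization of a multilayer network
#'
#' Approximates every layer of a multilayer network with a shared
#' non-negative basis: `W_m ~ B F_m` (bi-factor mode, the default) or
#' `W_m ~ B H F_m` (tri-factor mode, with a free `k x k` factor `H`). The
#' shared basis `B` captures vertex-to-module affinities that must explain
#' **all** layers at once, which is what makes the extracted modules common
#' modules. Fitting minimizes the summed Frobenius error
#' \deqn{\sum_m \| W_m - B H F_m \|_F^2}
#' (with `H = I` in bi-factor mode) by multiplicative updates from random
#' strictly positive initializations, repeated over `restarts` independent
#' starts; the best final objective wins. Modules are read off `B` by row
#' argmax ([extract_modules()]).
#'
#' Iteration stops when the objective decrease in one sweep falls below the
#' absolute threshold `tol` (default `1e-2`) or after `max_iter` sweeps
#' (default `1000`). One sweep costs `O(k n^2 M)`.
#'
#' @param net a [multinet].
#' @param k number of modules/features, `2 <= k < n`. See [select_k()] for
#'   choosing it.
#' @param mode `"bi"` (default; `H` fixed at identity, never updated) or
#'   `"tri"` (free `H`).
#' @param restarts independent random restarts (default 50).
#' @param tol absolute objective-decrease termination threshold (default
#'   `1e-2`).
#' @param max_iter maximum sweeps per restart (default 1000).
#' @param seed master seed; restart streams are derived from it, so equal
#'   seeds give bitwise-identical results.
#' @return An object of class `jnmf_fit`: list with `factors` (`B`, `H`,
#'   `F`), `objective` (best final value), `objective_trace` (per-iteration
#'   values of the winning restart, starting at the initial objective),
#'   `iterations`, `converged` (`TRUE` if `tol` was reached before
#'   `max_iter`), `partition` (extracted modules), `k`, `mode`, `restarts`,
#'   `seed`, `best_restart`.
#' @examples
#' cfg <- gn_config(n = 32, q = 2, degree = 6, z_out = 1, M = 2, seed = 1)
#' sim <- gn_homo_net(cfg)
#' fit <- jnmf(sim$net, k = 2, restarts = 5, seed = 1)
#' nmi(fit$partition, sim$partition)
#' @export
jnmf <- function(net, k, mode = c("bi", "tri"), restarts = 50, tol = 1e-2,
                 max_iter = 1000, seed = 1) {
  mode <- match.arg(mode)
  if (!is_multinet(net)) abort("`net` must be a multinet.")
  k <- as.integer(k)
  if (k < 2 || k >= net$n) abort("`k` must satisfy 2 <= k < n.")
  if (restarts < 1) abort("`restarts` must be >= 1.")
  best <- NULL
  for (r in seq_len(restarts)) {
    fs <- jnmf_init(net, k, mode, derive_seed(seed, r))
    trace <- jnmf_objective(net, fs)
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      fs <- jnmf_update(net, fs)
      e <- jnmf_objective(net, fs)
      trace <- c(trace, e)
      if (trace[it] - e < tol) {
        converged <- TRUE
        break
      }
    }
    if (is.null(best) || e < best$objective) {
      best <- list(factors = fs, objective = e, objective_trace = trace,
                   iterations = it, converged = converged, best_restart = r)
    }
  }
  p <- extract_modules(best$factors$B, labels = net$labels)
  structure(
    c(best, list(partition = p, k = k, mode = mode, restarts = as.integer(restarts),
                 tol = tol, max_iter = as.integer(max_iter), seed = as.integer(seed))),
    class = "jnmf_fit"
  )
}

## random strictly positive init on (0, 1], scaled so the product matches the
## magnitude of the data: mean(W)^(1/3) per factor in tri mode, ^(1/2) in bi.
jnmf_init <- function(net, k, mode, seed) {
  n <- net$n
  M <- net$M
  mw <- mean(vapply(net$W, mean, numeric(1)))
  s <- if (mode == "tri") max(mw, 1e-12)^(1 / 3) else max(mw, 1e-12)^(1 / 2)
  withr::with_seed(seed, {
    B <- matrix(1 - runif(n * k), n, k) * s
    H <- if (mode == "tri") matrix(1 - runif(k * k), k, k) * s else NULL
    Fm <- lapply(seq_len(M), function(m) matrix(1 - runif(k * n), k, n) * s)
  })
  list(B = B, H = H, F = Fm)
}

#' Joint factorization objective
#'
#' The summed squared Frobenius reconstruction error
#' `sum_m || W_m - B H F_m ||_F^2`, with `H` taken as the identity when the
#' factor set has no `H` (bi-factor mode).
#'
#' @param net a [multinet].
#' @param factors list with `B` (`n x k`), optional `H` (`k x k`), and `F`
#'   (list of `M` `k x n` matrices).
#' @return A non-negative number.
#' @export
jnmf_objective <- function(net, factors) {
  check_factors(net, factors)
  BH <- if (is.null(factors$H)) factors$B else factors$B %*% factors$H
  sum(vapply(seq_len(net$M), function(m) {
    sum((net$W[[m]] - BH %*% factors$F[[m]])^2)
  }, numeric(1)))
}

check_factors <- function(net, factors) {
  B <- factors$B
  if (!is.matrix(B) || nrow(B) != net$n) abort("`B` must be an n x k matrix.")
  k <- ncol(B)
  if (!is.null(factors$H) &&
      (!is.matrix(factors$H) || any(dim(factors$H) != k))) {
    abort("`H` must be a k x k matrix.")
  }
  if (length(factors$F) != net$M) abort("one F matrix per layer is required.")
  for (m in seq_len(net$M)) {
    f <- factors$F[[m]]
    if (!is.matrix(f) || nrow(f) != k || ncol(f) != net$n) {
      abort(sprintf("F[[%d]] must be a k x n matrix.", m))
    }
  }
  invisible(k)
}

#' One multiplicative update sweep
#'
#' Applies one full sweep of multiplicative updates — `B`, then `H` (in
#' tri-factor mode), then each `F_m` — for the joint objective
#' ([jnmf_objective()]):
#' \deqn{B \gets B \odot \frac{\sum_m W_m F_m^T H^T}{B \sum_m (H F_m)(H F_m)^T}}
#' \deqn{H \gets H \odot \frac{B^T \sum_m W_m F_m^T}{B^T B \, H \sum_m F_m F_m^T}}
#' \deqn{F_m \gets F_m \odot \frac{H^T B^T W_m}{H^T B^T B H F_m}}
#' Divisions are elementwise with the denominator floored at `1e-12`, so
#' non-negativity is preserved and `0/0` never occurs. Each sweep leaves the
#' objective non-increasing; an exact factorization is a fixed point.
#'
#' @inheritParams jnmf_objective
#' @return The updated factor list.
#' @export
jnmf_update <- function(net, factors) {
  check_factors(net, factors)
  eps <- 1e-12
  B <- factors$B
  H <- factors$H
  Fm <- factors$F
  M <- net$M
  tri <- !is.null(H)
  guard <- function(X, what) {
    if (any(!is.finite(X))) {
      abort(sprintf("non-finite values produced by the %s update.", what))
    }
    X
  }
  if (tri) {
    SWFH <- Reduce(`+`, lapply(seq_len(M), function(m) {
      net$W[[m]] %*% t(Fm[[m]]) %*% t(H)
    }))
    SHFF <- Reduce(`+`, lapply(seq_len(M), function(m) {
      HF <- H %*% Fm[[m]]
      HF %*% t(HF)
    }))
    B <- guard(B * SWFH / pmax(B %*% SHFF, eps), "B")
    SWF <- Reduce(`+`, lapply(seq_len(M), function(m) net$W[[m]] %*% t(Fm[[m]])))
    SFF <- Reduce(`+`, lapply(seq_len(M), function(m) Fm[[m]] %*% t(Fm[[m]])))
    H <- guard(H * (crossprod(B, SWF)) / pmax(crossprod(B) %*% H %*% SFF, eps), "H")
    BH <- B %*% H
  } else {
    SWF <- Reduce(`+`, lapply(seq_len(M), function(m) net$W[[m]] %*% t(Fm[[m]])))
    SFF <- Reduce(`+`, lapply(seq_len(M), function(m) Fm[[m]] %*% t(Fm[[m]])))
    B <- guard(B * SWF / pmax(B %*% SFF, eps), "B")
    BH <- B
  }
  G <- crossprod(BH)
  Fm <- lapply(seq_len(M), function(m) {
    guard(Fm[[m]] * (crossprod(BH, net$W[[m]])) / pmax(G %*% Fm[[m]], eps),
          sprintf("F[[%d]]", m))
  })
  list(B = B, H = H, F = Fm)
}

#' Extract a hard partition from a basis matrix
#'
#' Assigns each vertex to the column of its maximal basis loading
#' (`j* = argmax_j B_ij`). Ties break to the lowest column index; a row of
#' all zeros goes to column 1 with a warning; columns that receive no
#' vertex are dropped (with a message), so the returned partition has no
#' empty modules and its `k` may be smaller than `ncol(B)`.
#'
#' @param B non-negative `n x k` basis matrix.
#' @param labels optional vertex labels.
#' @return A [partition].
#' @export
extract_modules <- function(B, labels = NULL) {
  B <- as.matrix(B)
  if (any(B < 0)) abort("`B` must be non-negative.")
  zero_rows <- rowSums(B) == 0
  if (any(zero_rows)) {
    warn(sprintf("%d vertex rows of B are all zero; assigned to module 1.",
                 sum(zero_rows)))
  }
  a <- apply(B, 1, which.max)  # ties -> lowest index
  used <- sort(unique(a))
  if (length(used) < ncol(B)) {
    inform(sprintf("%d empty basis column(s) dropped; k reduced to %d.",
                   ncol(B) - length(used), length(used)))
  }
  partition(match(a, used), labels = labels)
}

#' @export
print.jnmf_fit <- function(x, ...) {
  cat(sprintf(
    "<jnmf_fit> k = %d (%s-factor), %d restart%s\n  best objective %.6g after %d iterations (%s), %d modules extracted\n",
    x$k, x$mode, x$restarts, if (x$restarts == 1) "" else "s",
    x$objective, x$iterations,
    if (x$converged) "converged" else "iteration cap reached",
    n_modules(x$partition)))
  invisible(x)
}
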