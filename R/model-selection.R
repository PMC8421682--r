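#' Dissimilarity between two basis matrices
#'
#' The column-matching dissimilarity used by stability-driven NMF rank
#' selection: columns of both bases are L2-normalized, `C` is the `k x k`
#' matrix of column cosines, and the value is
#' `1 - (1 / 2k) (sum_i max_j C_ij + sum_j max_i C_ij)`.
#' It is 0 when the bases agree up to column permutation and positive
#' rescaling, 1 when every column of one basis is orthogonal to all columns
#' of the other, symmetric in its arguments.
#'
#' @param Ba,Bb non-negative `n x k` basis matrices of equal shape.
#' @return A dissimilarity in `[0, 1]`.
#' @export
factor_dissimilarity <- function(Ba, Bb) {
  Ba <- as.matrix(Ba)
  Bb <- as.matrix(Bb)
  if (!all(dim(Ba) == dim(Bb))) abort("`Ba` and `Bb` must have equal shape.")
  normalize <- function(B) {
    s <- sqrt(colSums(B^2))
    if (any(s == 0)) {
      warn("zero basis column; its cosines set to 0.")
      s[s == 0] <- 1
    }
    sweep(B, 2, s, "/")
  }
  C <- crossprod(normalize(Ba), normalize(Bb))
  k <- ncol(C)
  1 - (sum(apply(C, 1, max)) + sum(apply(C, 2, max))) / (2 * k)
}

#' Instability of the factorization at a given rank
#'
#' Runs the joint factorization `runs` times with a single random restart
#' each (independent derived seeds) and returns the mean
#' [factor_dissimilarity()] over all unordered pairs of resulting basis
#' matrices. Stable, well-determined module structure yields concordant
#' bases and instability near 0; an ill-chosen rank yields discordant local
#' optima and larger values.
#'
#' @param net a [multinet].
#' @param k candidate rank.
#' @param runs number of single-restart runs (default 50, the same count as
#'   the fitting protocol's restarts).
#' @param seed master seed; run seeds are derived from `(seed, k, run)`.
#' @param ... passed on to [jnmf()] (e.g. `mode`, `tol`, `max_iter`).
#' @return Mean pairwise dissimilarity (a non-negative number).
#' @export
nmf_instability <- function(net, k, runs = 50, seed = 1, ...) {
  if (runs < 2) abort("`runs` must be >= 2.")
  bases <- lapply(seq_len(runs), function(r) {
    fit <- tryCatch(
      jnmf(net, k, restarts = 1, seed = derive_seed(seed, k, r), ...),
      error = function(e) {
        abort(sprintf("fit failed in run %d at k = %d: %s", r, k,
                      conditionMessage(e)))
      }
    )
    fit$factors$B
  })
  pairs <- combn(runs, 2)
  mean(vapply(seq_len(ncol(pairs)), function(j) {
    factor_dissimilarity(bases[[pairs[1, j]]], bases[[pairs[2, j]]])
  }, numeric(1)))
}

#' Select the number of modules by factorization instability
#'
#' Scans candidate ranks `k_min..k_max`, computes [nmf_instability()] for
#' each, and returns the rank attaining the minimum (ties break toward the
#' smaller `k`, with a message).
#'
#' @param net a [multinet].
#' @param k_min,k_max candidate range (defaults 2 and 10).
#' @param runs single-restart runs per candidate (default 50).
#' @param seed master seed.
#' @param ... passed on to [jnmf()].
#' @return An object of class `k_selection`: list with `k_best` and
#'   `profile`, a tibble with columns `k` and `instability`.
#' @examples
#' sim <- gn_homo_net(gn_config(n = 32, q = 2, degree = 6, z_out = 1, seed = 1))
#' sel <- select_k(sim$net, k_min = 2, k_max = 4, runs = 8, seed = 1)
#' sel$k_best
#' @export
select_k <- function(net, k_min = 2, k_max = 10, runs = 50, seed = 1, ...) {
  if (!(2 <= k_min && k_min < k_max && k_max < net$n)) {
    abort("need 2 <= k_min < k_max < n.")
  }
  ks <- seq.int(k_min, k_max)
  inst <- vapply(ks, function(k) nmf_instability(net, k, runs = runs,
                                                 seed = seed, ...), numeric(1))
  best <- ks[which.min(inst)]  # which.min takes the first minimum: smaller k
  if (sum(inst == min(inst)) > 1) {
    inform(sprintf("instability tie; choosing the smallest k (%d).", best))
  }
  structure(
    list(k_best = as.integer(best),
         profile = tibble(k = as.integer(ks), instability = inst),
         runs = as.integer(runs), seed = as.integer(seed)),
    class = "k_selection"
  )
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> k* = %d (instability %.4f; %d runs per k)\n",
              x$k_best, x$profile$instability[x$profile$k == x$k_best], x$runs))
  print(x$profile)
  invisible(x)
}
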