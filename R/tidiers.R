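#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted joint factorization
#'
#' @param x a `jnmf_fit`.
#' @param ... unused.
#' @return One row per vertex: `vertex`, `module`, `loading` (the winning
#'   basis entry), plus `loading_1..loading_k` basis columns.
#' @export
tidy.jnmf_fit <- function(x, ...) {
  B <- x$factors$B
  p <- x$partition
  out <- tibble(
    vertex = attr(p, "labels"),
    module = as.integer(unclass(p)),
    loading = B[cbind(seq_len(nrow(B)), apply(B, 1, which.max))]
  )
  load_cols <- as_tibble(as.data.frame(B))
  names(load_cols) <- paste0("loading_", seq_len(ncol(B)))
  dplyr::bind_cols(out, load_cols)
}

#' One-row summary of a fitted joint factorization
#'
#' @param x a `jnmf_fit`.
#' @param ... unused.
#' @return A one-row tibble: `k`, `k_extracted`, `mode`, `objective`,
#'   `iterations`, `converged`, `restarts`, `best_restart`, `seed`.
#' @export
glance.jnmf_fit <- function(x, ...) {
  tibble(
    k = x$k,
    k_extracted = n_modules(x$partition),
    mode = x$mode,
    objective = x$objective,
    iterations = x$iterations,
    converged = x$converged,
    restarts = x$restarts,
    best_restart = x$best_restart,
    seed = x$seed
  )
}

#' Tidy a rank-selection result
#'
#' @param x a `k_selection`.
#' @param ... unused.
#' @return The instability profile tibble (`k`, `instability`) with a
#'   logical `selected` column.
#' @export
tidy.k_selection <- function(x, ...) {
  dplyr::mutate(x$profile, selected = .data$k == x$k_best)
}

#' @rdname tidy.k_selection
#' @export
glance.k_selection <- function(x, ...) {
  tibble(k_best = x$k_best,
         instability_min = min(x$profile$instability),
         runs = x$runs, seed = x$seed)
}
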