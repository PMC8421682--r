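#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_vline labs facet_wrap scale_y_log10 theme_minimal
#' @export
ggplot2::autoplot

#' Plot the objective trace of a fit
#'
#' @param object a `jnmf_fit`.
#' @param ... unused.
#' @return A ggplot: Frobenius objective of the winning restart per
#'   iteration (log scale).
#' @export
autoplot.jnmf_fit <- function(object, ...) {
  d <- tibble(iteration = seq_along(object$objective_trace) - 1,
              objective = object$objective_trace)
  ggplot(d, aes(.data$iteration, .data$objective)) +
    geom_line() +
    scale_y_log10() +
    labs(x = "iteration", y = "joint Frobenius objective",
         title = sprintf("k = %d (%s-factor), winning restart", object$k,
                         object$mode)) +
    theme_minimal()
}

#' Plot an instability profile
#'
#' @param object a `k_selection`.
#' @param ... unused.
#' @return A ggplot of instability versus candidate `k`, with the selected
#'   rank marked.
#' @export
autoplot.k_selection <- function(object, ...) {
  ggplot(object$profile, aes(.data$k, .data$instability)) +
    geom_line() +
    geom_point() +
    geom_vline(xintercept = object$k_best, linetype = "dashed") +
    labs(x = "number of modules k", y = "factorization instability",
         title = sprintf("selected k* = %d", object$k_best)) +
    theme_minimal()
}

#' Heatmap of the layer adjacency matrices
#'
#' Vertices can be ordered by a partition so modules appear as diagonal
#' blocks.
#'
#' @param object a [multinet].
#' @param partition optional [partition] used to order the vertices.
#' @param ... unused.
#' @return A ggplot, one facet per layer.
#' @export
autoplot.multinet <- function(object, partition = NULL, ...) {
  ord <- if (is.null(partition)) seq_len(object$n) else order(unclass(partition))
  d <- purrr::map_dfr(seq_len(object$M), function(m) {
    W <- object$W[[m]][ord, ord]
    idx <- which(W > 0, arr.ind = TRUE)
    tibble(layer = paste("layer", m), row = idx[, 1], col = idx[, 2],
           weight = W[idx])
  })
  ggplot(d, aes(.data$col, .data$row, fill = .data$weight)) +
    geom_tile() +
    facet_wrap(~layer) +
    ggplot2::scale_y_reverse() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}
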