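#' Hard partition of a vertex set into modules
#'
#' A `partition` assigns each of `n` vertices to exactly one of `k`
#' non-empty modules. Module identifiers are compressed to consecutive
#' integers `1..k` in order of first appearance of the original labels,
#' which guarantees the non-emptiness invariant by construction.
#'
#' @param assignment integer (or factor/character) vector of module
#'   memberships, one entry per vertex.
#' @param labels optional vertex labels (defaults to names of `assignment`
#'   or `v1..vn`).
#' @return An object of class `partition`: an integer vector in `1..k` with
#'   attributes `k` and `labels`.
#' @examples
#' p <- partition(c(1, 1, 2, 2))
#' p
#' indicator_matrix(p)
#' @export
partition <- function(assignment, labels = NULL) {
  if (is.null(labels)) labels <- names(assignment)
  f <- factor(as.vector(assignment), levels = unique(as.vector(assignment)))
  a <- as.integer(f)
  if (length(a) == 0 || anyNA(a)) abort("`assignment` must be complete (no NA).")
  n <- length(a)
  if (is.null(labels)) labels <- paste0("v", seq_len(n))
  if (length(labels) != n) abort("`labels` length must match `assignment`.")
  structure(a, k = max(a), labels = as.character(labels), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  sizes <- tabulate(unclass(x), attr(x, "k"))
  cat(sprintf("<partition> %d vertices in %d modules (sizes: %s)\n",
              length(x), attr(x, "k"), paste(sizes, collapse = ", ")))
  invisible(x)
}

#' @export
#' @rdname partition
is_partition <- function(x) inherits(x, "partition")

#' Number of modules of a partition
#' @param p a [partition].
#' @return Integer module count `k`.
#' @export
n_modules <- function(p) attr(p, "k")

#' Binary indicator matrix of a partition
#'
#' @param p a [partition] of `n` vertices into `k` modules.
#' @return An `n x k` 0/1 matrix `X` with unit row sums (each vertex in one
#'   module) and positive column sums (no empty module).
#' @export
indicator_matrix <- function(p) {
  stopifnot(is_partition(p))
  k <- attr(p, "k")
  X <- matrix(0L, length(p), k)
  X[cbind(seq_along(p), unclass(p))] <- 1L
  rownames(X) <- attr(p, "labels")
  X
}

#' Vertex sets of the modules
#' @param p a [partition].
#' @return A list of integer vertex-index vectors, one per module.
#' @export
module_members <- function(p) {
  split(seq_along(p), unclass(p))
}

#' @export
as_tibble.partition <- function(x, ...) {
  tibble(vertex = attr(x, "labels"), module = as.integer(unclass(x)))
}

#' Read / write a partition table
#'
#' The on-disk form is a tab-separated table with columns `vertex` and
#' `module` (`module` in `1..k`).
#'
#' @param p a [partition].
#' @param path file path.
#' @return `write_partition()` returns `path` invisibly; `read_partition()`
#'   returns a [partition].
#' @export
write_partition <- function(p, path) {
  readr::write_tsv(as_tibble(p), path)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  t <- readr::read_tsv(path, col_types = readr::cols(
    vertex = readr::col_character(),
    module = readr::col_integer()
  ))
  partition(t$module, labels = t$vertex)
}

## align a partition's vertex order to a multinet (by labels when available)
check_partition <- function(net, p) {
  if (!is_partition(p)) p <- partition(p)
  if (length(p) != net$n) {
    abort(sprintf("partition covers %d vertices but the network has %d.",
                  length(p), net$n))
  }
  p
}
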