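#' Contingency table of two partitions
#'
#' `N_ij` counts the vertices shared by module `i` of `p` and module `j` of
#' `pstar`. Entries are non-negative integers summing to `n`.
#'
#' @param p,pstar [partition]s over the same vertex set (same length and
#'   order).
#' @return An integer `|p| x |pstar|` matrix.
#' @export
contingency <- function(p, pstar) {
  if (!is_partition(p)) p <- partition(p)
  if (!is_partition(pstar)) pstar <- partition(pstar)
  if (length(p) != length(pstar)) {
    abort("partitions cover different numbers of vertices.")
  }
  N <- table(factor(unclass(p), levels = seq_len(n_modules(p))),
             factor(unclass(pstar), levels = seq_len(n_modules(pstar))))
  matrix(as.integer(N), nrow = n_modules(p), ncol = n_modules(pstar))
}

#' Normalized mutual information between two partitions
#'
#' \deqn{\mathrm{NMI}(P, P^*) = \frac{-2 \sum_{ij} N_{ij}
#'   \log\!\big(N_{ij} N / (N_{i.} N_{.j})\big)}
#'   {\sum_i N_{i.} \log(N_{i.}/N) + \sum_j N_{.j} \log(N_{.j}/N)}}
#' computed from the contingency table, with the convention
#' `0 log 0 = 0` and natural logarithms (the value is base-invariant).
#' Identical partitions (up to relabeling) score 1; independent ones score
#' near 0. When both partitions are trivial (a single module each, so the
#' denominator vanishes) the value is defined as 1; a trivial partition
#' against a non-trivial one scores 0.
#'
#' @inheritParams contingency
#' @return A value in `[0, 1]`.
#' @export
nmi <- function(p, pstar) {
  N <- contingency(p, pstar)
  n <- sum(N)
  Ni <- rowSums(N)
  Nj <- colSums(N)
  den <- sum(Ni[Ni > 0] * log(Ni[Ni > 0] / n)) +
    sum(Nj[Nj > 0] * log(Nj[Nj > 0] / n))
  if (den == 0) {
    return(if (nrow(N) == 1 && ncol(N) == 1) 1 else 0)
  }
  pos <- N > 0
  num <- -2 * sum(N[pos] * log(N[pos] * n / (Ni[row(N)[pos]] * Nj[col(N)[pos]])))
  val <- num / den
  ## clamp tiny numerical excursions
  min(max(val, 0), 1)
}
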