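# Pathway over-representation p-values: exact hypergeometric tail and its
# large-universe binomial approximation.

check_enrichment_query <- function(N, M, K, x) {
  if (N < 0 || M < 0 || K < 0 || x < 0) stop("all counts must be non-negative")
  if (M > N) stop("M (pathway genes) cannot exceed N (universe)")
  if (K > N) stop("K (selected genes) cannot exceed N (universe)")
  if (x > min(M, K)) stop("x cannot exceed min(M, K)")
}

#' Hypergeometric enrichment p-value
#'
#' Given a universe of `N` genes of which `M` belong to a pathway, and `K`
#' selected significant genes of which `x` fall in the pathway: the lower
#' tail is the probability of observing `x` or fewer pathway genes, the
#' upper tail the probability of `x` or more (the usual enrichment
#' direction). Tail masses are computed in log space, so large universes
#' are handled exactly.
#'
#' @param N Universe size.
#' @param M Pathway size.
#' @param K Number of selected genes.
#' @param x Observed pathway genes among the selection.
#' @param tail `"upper"` (default; enrichment) or `"lower"` (depletion).
#' @return p-value in `[0, 1]`.
#' @export
hypergeom_p <- function(N, M, K, x, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  check_enrichment_query(N, M, K, x)
  if (tail == "lower") {
    stats::phyper(x, M, N - M, K)
  } else {
    stats::phyper(x - 1, M, N - M, K, lower.tail = FALSE)
  }
}

#' Binomial approximation of the enrichment p-value
#'
#' For large universes the hypergeometric tail converges to the binomial:
#' p = P(X >= x) with X ~ Binomial(K, M/N), i.e.
#' 1 - sum over i < x of C(K, i) (M/N)^i (1 - M/N)^(K - i). By convention
#' x = 0 gives 1 (the empty sum).
#'
#' @inheritParams hypergeom_p
#' @return p-value in `[0, 1]`.
#' @export
binomial_p <- function(N, M, K, x) {
  if (N <= 0) stop("N must be positive")
  check_enrichment_query(N, M, K, x)
  if (x == 0) return(1)
  stats::pbinom(x - 1, K, M / N, lower.tail = FALSE)
}
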