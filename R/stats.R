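# Exact test engine shared across modules: the two-tailed binomial test on
# genome-fraction (or joint-probability) nulls. Two-sidedness uses
# minimum-likelihood summation -- the p-value is the total probability of all
# outcomes no more likely than the observed one -- which is well defined for
# asymmetric nulls, unlike tail doubling.

#' Exact two-tailed binomial test
#'
#' Computes `P(X in A)` where `X ~ Binomial(n, p0)` and `A` is the set of
#' outcomes with point probability no greater than that of the observed `k`
#' (minimum-likelihood summation, with the usual `1 + 1e-7` relative slack on
#' the density comparison to absorb floating-point noise). Degenerate nulls
#' `p0 = 0` or `p0 = 1` return p = 1 when the observation is forced and 0
#' otherwise.
#'
#' @param k Observed successes.
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @return list(k, n, p0, p_value, direction) with direction `"over"` when
#'   `k / n > p0`, else `"under"`.
#' @examples
#' binomialEnrichment(8, 10, 0.5)$p_value  # 0.109375
#' @export
binomialEnrichment <- function(k, n, p0) {
  if (length(k) != 1L || length(n) != 1L || length(p0) != 1L)
    stop("k, n and p0 must be scalars")
  if (!isTRUE(n >= 0 && k >= 0 && k <= n && k == round(k) && n == round(n)))
    stop("need integer 0 <= k <= n")
  if (!isTRUE(p0 >= 0 && p0 <= 1)) stop("p0 must lie in [0, 1]")
  direction <- if (n > 0 && k / n > p0) "over" else "under"
  if (p0 == 0) {
    p <- if (k == 0) 1 else 0
  } else if (p0 == 1) {
    p <- if (k == n) 1 else 0
  } else {
    d <- stats::dbinom(0:n, n, p0)
    p <- min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
  }
  list(k = as.integer(k), n = as.integer(n), p0 = p0, p_value = p,
       direction = direction)
}
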