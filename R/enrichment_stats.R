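#' Exact hypergeometric upper-tail probability
#'
#' P(X >= k) for X hypergeometric with population `N`, `K` marked items,
#' and `n` draws without replacement, computed exactly by summing
#' log-space binomial coefficients (no normal approximation):
#' \deqn{P(X \ge k) = \sum_{x \ge k} \binom{K}{x}\binom{N-K}{n-x} /
#'   \binom{N}{n}.}
#'
#' @param N population size.
#' @param K number of marked items in the population.
#' @param n number of draws.
#' @param k observed number of marked draws.
#' @return Upper-tail probability in `[0, 1]`.
#' @examples
#' hypergeom_sf(4, 2, 2, 2)  # 1/6
#' @export
hypergeom_sf <- function(N, K, n, k) {
  N <- as.integer(N); K <- as.integer(K)
  n <- as.integer(n); k <- as.integer(k)
  if (any(c(N, K, n, k) < 0L) || K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric counts (need 0 <= k <= min(K, n),",
         " K <= N, n <= N)")
  if (k <= max(0L, n - (N - K))) return(1)
  xs <- k:min(K, n)
  lp <- lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)
  min(1, sum(exp(lp)))
}

#' Positional enrichment test for a feature across cluster types
#'
#' Given counts of feature-positive intergenic regions among the 5'-SBP
#' and 3'-SBP cluster IRs, tests whether the feature (stem-loop or
#' promoter) is enriched on the side with the higher hit percentage, using
#' the one-sided exact hypergeometric tail over the pooled population.
#'
#' @param n_5p_IRs,n_3p_IRs number of (long) IRs in 5'-SBP and 3'-SBP
#'   clusters.
#' @param k_5p_hits,k_3p_hits feature-positive IRs on each side.
#' @param feature label, `"stemloop"` or `"promoter"`.
#' @return list of class `enrichment_result`: `feature`, `p_value`,
#'   `direction` (`five_prime_enriched`, `three_prime_enriched`, `none`),
#'   `pct_5p`, `pct_3p`, and the input counts.
#' @export
enrichment_test <- function(n_5p_IRs, n_3p_IRs, k_5p_hits, k_3p_hits,
                            feature = c("stemloop", "promoter")) {
  feature <- match.arg(feature)
  if (k_5p_hits > n_5p_IRs || k_3p_hits > n_3p_IRs)
    stop("hits cannot exceed IR counts")
  N <- n_5p_IRs + n_3p_IRs
  K <- k_5p_hits + k_3p_hits
  pct_5p <- if (n_5p_IRs > 0) 100 * k_5p_hits / n_5p_IRs else NA_real_
  pct_3p <- if (n_3p_IRs > 0) 100 * k_3p_hits / n_3p_IRs else NA_real_
  if (isTRUE(pct_5p > pct_3p)) {
    direction <- "five_prime_enriched"
    p <- hypergeom_sf(N, K, n_5p_IRs, k_5p_hits)
  } else if (isTRUE(pct_3p > pct_5p)) {
    direction <- "three_prime_enriched"
    p <- hypergeom_sf(N, K, n_3p_IRs, k_3p_hits)
  } else {
    # tied percentages: no direction; evaluate the smaller side so the
    # result is invariant under swapping the two sides
    direction <- "none"
    p <- if (n_5p_IRs <= n_3p_IRs) hypergeom_sf(N, K, n_5p_IRs, k_5p_hits)
         else hypergeom_sf(N, K, n_3p_IRs, k_3p_hits)
  }
  structure(list(feature = feature, p_value = p, direction = direction,
                 pct_5p = pct_5p, pct_3p = pct_3p,
                 n_5p_IRs = n_5p_IRs, n_3p_IRs = n_3p_IRs,
                 k_5p_hits = k_5p_hits, k_3p_hits = k_3p_hits),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "%s: 5' %d/%d (%.1f%%) vs 3' %d/%d (%.1f%%); %s, P = %.3g\n",
    x$feature, x$k_5p_hits, x$n_5p_IRs, x$pct_5p,
    x$k_3p_hits, x$n_3p_IRs, x$pct_3p, x$direction, x$p_value))
  invisible(x)
}

#' Count promoter-positive IRs from a score table
#'
#' Promoter calls come from an external predictor's score table; an IR is
#' promoter-positive when its best score exceeds `cutoff` (strict),
#' the working threshold for a confident promoter call.
#'
#' @param scores data frame with columns `ir_id`, `score`.
#' @param cutoff numeric threshold (default 0.9, strict).
#' @return Character vector of promoter-positive ir_ids.
#' @export
promoter_positive_irs <- function(scores, cutoff = 0.9) {
  best <- tapply(scores$score, scores$ir_id, max)
  names(best)[best > cutoff]
}
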