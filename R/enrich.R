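#' Upper tail of the hypergeometric distribution
#'
#' Probability of observing an overlap at least as large as `k` between a
#' query of size `n` and a gene set of size `K` drawn from a universe of
#' size `N`: P(X >= k) for X ~ Hypergeometric(N, K, n).
#'
#' @param N Universe size.
#' @param K Gene-set size.
#' @param n Query size.
#' @param k Observed overlap. All four may be vectors (recycled).
#' @return Numeric vector of tail probabilities.
#' @examples
#' hypergeomTail(10, 5, 4, 3)  # 55/210
#' @export
hypergeomTail <- function(N, K, n, k) {
  if (any(K > N) || any(n > N) || any(k > pmin(K, n)) || any(k < 0))
    stop("inconsistent hypergeometric counts: need k <= min(K, n), K, n <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' One-sided Fisher exact enrichment p-value
#'
#' Enrichment-direction Fisher exact test on the 2x2 table
#' \[\[k, n-k\], \[K-k, N-K-n+k\]\]. Identical to [hypergeomTail()] by the
#' equivalence of the one-sided Fisher test and the hypergeometric tail;
#' computed independently through [stats::fisher.test] so the two routes
#' cross-check each other.
#'
#' @inheritParams hypergeomTail
#' @return Numeric vector of p-values.
#' @export
fisherEnrichment <- function(N, K, n, k) {
  args <- cbind(N, K, n, k)
  vapply(seq_len(nrow(args)), function(i) {
    N <- args[i, 1]; K <- args[i, 2]; n <- args[i, 3]; k <- args[i, 4]
    tab <- matrix(c(k, n - k, K - k, N - K - n + k), nrow = 2)
    if (any(tab < 0)) stop("negative cell in the 2x2 table")
    fisher.test(tab, alternative = "greater")$p.value
  }, numeric(1))
}

#' Gene-set enrichment of a query gene list
#'
#' For every set with a non-empty overlap with the query, reports the set
#' size K, overlap k, the ratio k/K (rounded to 4 decimals in the report
#' column), and the one-sided enrichment p-value by the chosen method.
#' Raw p-values are reported (no correction is applied to the significance
#' column); a BH-adjusted column is emitted alongside.
#'
#' @param query Character vector of gene ids.
#' @param sets Named list of gene-id vectors (e.g. from [readGmt()]).
#' @param universe Character vector: all genes on the platform.
#' @param method "hypergeom" (default) or "fisher".
#' @param alpha Significance level used for the `significant` flag.
#' @return Data frame sorted by ascending p: term_id, K, k, ratio_kK,
#'   p_value, p_adj, significant, N, n.
#' @examples
#' sets <- list(A = c("g1", "g2", "g3"), B = c("g4", "g5"))
#' enrichTerms(c("g1", "g2"), sets, paste0("g", 1:20))
#' @export
enrichTerms <- function(query, sets, universe,
                        method = c("hypergeom", "fisher"), alpha = 0.05) {
  method <- match.arg(method)
  if (!length(query)) stop("empty query gene list")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query genes outside the universe dropped")
    query <- intersect(query, universe)
    if (!length(query)) stop("no query genes left inside the universe")
  }
  query <- unique(query)
  N <- length(unique(universe))
  n <- length(query)
  K <- vapply(sets, function(s) length(intersect(s, universe)), integer(1))
  k <- vapply(sets, function(s) length(intersect(s, query)), integer(1))
  keep <- k >= 1
  if (!any(keep))
    return(data.frame(term_id = character(), K = integer(), k = integer(),
                      ratio_kK = numeric(), p_value = numeric(),
                      p_adj = numeric(), significant = logical(),
                      N = integer(), n = integer()))
  K <- K[keep]; k <- k[keep]
  p <- if (method == "hypergeom") hypergeomTail(N, K, n, k)
       else fisherEnrichment(N, K, n, k)
  res <- data.frame(term_id = names(sets)[keep], K = K, k = k,
                    ratio_kK = roundHalfEven(k / K, 4), p_value = p,
                    p_adj = p.adjust(p, "BH"), significant = p < alpha,
                    N = N, n = n, row.names = NULL,
                    stringsAsFactors = FALSE)
  res[order(res$p_value, res$term_id), , drop = FALSE]
}
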