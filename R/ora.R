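#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` query hits in a gene set of size `K` within a
#' background of size `N` when drawing `n` query genes. Evaluated through
#' the numerically stable distribution function in \pkg{stats}
#' ([stats::phyper()] with an upper-tail call, internally computed on the
#' log scale).
#'
#' @param k Observed hits in the set (vectorized).
#' @param n Query size.
#' @param K Set size within the background.
#' @param N Background size.
#' @return The one-sided over-representation p-value(s).
#' @export
#' @examples
#' hypergeom_tail(4, 4, 5, 10)  # choose(5,4)/choose(10,4) = 5/210
hypergeom_tail <- function(k, n, K, N) {
  if (any(k < 0) || any(n < 0) || any(K < 0) || any(N < 0) ||
      any(k > n) || any(n > N) || any(K > N) || any(k > K)) {
    abort("Inconsistent hypergeometric arguments: need 0 <= k <= min(n, K), n <= N, K <= N.")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of a query (e.g. the
#' significantly upregulated proteins at one time point) against a
#' background of quantified proteins. Matching uses the first gene symbol
#' of (possibly multi-gene) groups, case-insensitively. Sets are
#' restricted to the background before counting, so genes never quantified
#' cannot influence the test; query members outside the background are
#' dropped with a warning. P-values are BH-adjusted across the tested
#' sets.
#'
#' @param query Character vector of significant gene symbols (or protein
#'   groups; the first symbol is used).
#' @param sets Named list of gene-symbol vectors (see [read_gene_sets()]).
#' @param background Character vector of quantified gene symbols.
#' @param q_threshold Significance threshold on the adjusted p (default
#'   0.05).
#' @param min_set_size Sets with fewer background members are skipped
#'   (default 3).
#' @return Tibble `set`, `k` (hits), `n` (query size), `K` (set size in
#'   background), `N` (background size), `p`, `q`, `significant`, `hits`
#'   (list-column), ordered by `p`.
#' @export
run_ora <- function(query, sets, background, q_threshold = 0.05,
                    min_set_size = 3) {
  background <- unique(first_symbol(background))
  if (length(background) == 0) abort("`background` must be non-empty.")
  query <- unique(first_symbol(query))
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    warn(paste0(length(outside), " query gene(s) not in the background ",
                "were dropped: ", paste(head(outside, 5), collapse = ", "),
                if (length(outside) > 5) ", ..."))
    query <- intersect(query, background)
  }
  sets_bg <- lapply(sets, function(s) intersect(unique(toupper(s)), background))
  sizes <- lengths(sets_bg)
  keep <- sizes >= min_set_size
  sets_bg <- sets_bg[keep]
  if (length(sets_bg) == 0) {
    return(tibble::tibble(set = character(), k = integer(), n = integer(),
                          K = integer(), N = integer(), p = numeric(),
                          q = numeric(), significant = logical(),
                          hits = list()))
  }
  N <- length(background)
  n <- length(query)
  hits <- lapply(sets_bg, intersect, x = query)
  k <- lengths(hits)
  K <- lengths(sets_bg)
  p <- hypergeom_tail(k, n, K, N)
  out <- tibble::tibble(set = names(sets_bg), k = as.integer(k),
                        n = as.integer(n), K = as.integer(K),
                        N = as.integer(N), p = unname(p),
                        q = adjust_bh(unname(p)),
                        hits = unname(hits))
  out$significant <- out$q < q_threshold
  dplyr::arrange(out[, c("set", "k", "n", "K", "N", "p", "q", "significant",
                         "hits")], .data$p, .data$set)
}
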