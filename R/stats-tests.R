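#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum statistic of `x` (midranks under ties) with a two-sided p-value:
#' exact by enumeration when both samples are small (`min(n) <= 8`) and
#' tie-free, otherwise the normal approximation with tie and continuity
#' correction. The p-value computation is delegated to
#' [stats::wilcox.test()]; `W` here is the classical rank-sum of `x`
#' (Mann-Whitney U plus `n(n+1)/2`).
#'
#' @param x,y numeric vectors (both nonempty).
#' @param mode `"auto"` (the rule above), `"exact"` or `"approx"`.
#' @return list: `W` (rank-sum of `x`), `p` (two-sided), `mode` used.
#' @export
wilcoxonRankSum <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y))
    stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
    auto = min(length(x), length(y)) <= 8 && !ties,
    exact = TRUE,
    approx = FALSE)
  if (exact && ties)
    stop("exact mode is not defined under ties")
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  r <- rank(c(x, y))
  list(W = sum(r[seq_along(x)]), p = unname(ht$p.value),
       mode = if (exact) "exact" else "approx")
}

#' Hypergeometric tail probabilities
#'
#' For `X ~ Hypergeometric(N, K, n)` (a draw of `n` from `N` objects of
#' which `K` are successes): `upper` is `P(X >= k)` (enrichment), `lower`
#' `P(X <= k)` (depletion). Computed via [stats::phyper()], whose tail
#' accumulation works in log space internally; the complementary identity
#' `upper(k) + lower(k - 1) = 1` holds to machine precision.
#'
#' @param k observed successes in the draw.
#' @param K successes in the population.
#' @param n draw size.
#' @param N population size.
#' @param tail `"upper"` or `"lower"`.
#' @return the tail probability.
#' @export
hypergeometricTail <- function(k, K, n, N, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (K > N || n > N) stop("inconsistent counts: K and n must be <= N")
  if (k < 0 || k > min(n, K)) stop("k must be in [0, min(n, K)]")
  if (tail == "upper")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  else
    stats::phyper(k, K, N - K, n, lower.tail = TRUE)
}

# Compact letter display: groups sharing a letter are not significantly
# different. Maximal cliques of the non-significance graph, found by subset
# enumeration (group counts here are tiny).
.letterGroups <- function(groups, pairs, signif) {
  g <- length(groups)
  if (g == 1L) return(stats::setNames("a", groups))
  adj <- matrix(TRUE, g, g, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    adj[a, b] <- adj[b, a] <- !signif[i]
  }
  cliques <- list()
  for (bits in seq_len(2^g - 1L)) {
    members <- which(bitwAnd(bits, 2^(seq_len(g) - 1L)) > 0)
    sub <- adj[members, members, drop = FALSE]
    if (all(sub)) cliques[[length(cliques) + 1L]] <- members
  }
  sizes <- lengths(cliques)
  maximal <- Filter(function(cl) {
    !any(vapply(cliques, function(o)
      length(o) > length(cl) && all(cl %in% o), TRUE))
  }, cliques)
  # stable order: by first member
  maximal <- maximal[order(vapply(maximal, min, 1L))]
  letters_ <- letters[seq_along(maximal)]
  out <- stats::setNames(rep("", g), groups)
  for (i in seq_along(maximal))
    out[maximal[[i]]] <- paste0(out[maximal[[i]]], letters_[i])
  out
}
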