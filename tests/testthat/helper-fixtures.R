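# Shared fixtures and independent oracles used across the suite.

TREE5 <- "((tip1:1,tip2:1):1,(tip3:1,(tip4:1,tip5:1):0.5):1);"

# A window GRanges with given per-window depths, one chromosome per element
# of `depths` (a named list of numeric vectors), windowSize bp windows.
makeWindows <- function(depths, windowSize = 100) {
  if (!length(depths))
    return(GenomicRanges::GRanges(depth = numeric()))
  grs <- lapply(names(depths), function(ch) {
    n <- length(depths[[ch]])
    GenomicRanges::GRanges(ch, IRanges::IRanges(
      start = seq(1L, by = windowSize, length.out = n),
      width = windowSize), depth = depths[[ch]])
  })
  suppressWarnings(do.call(c, grs))
}

# Independent brute-force single-changepoint scan: literal two-loop sums of
# squared deviations, no prefix-sum algebra shared with the implementation.
bruteChangepoint <- function(y) {
  n <- length(y)
  costs <- vapply(seq_len(n - 1L), function(k) {
    l <- y[1:k]; r <- y[(k + 1):n]
    sum((l - mean(l))^2) + sum((r - mean(r))^2)
  }, 0)
  list(costs = costs, best = which.min(costs))
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# C(n+m, n) group assignments (tie-free inputs).
enumWilcoxP <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  wObs <- sum(r[seq_len(n)])
  combs <- utils::combn(length(pooled), n)
  ws <- apply(combs, 2L, function(i) sum(r[i]))
  mu <- n * (length(pooled) + 1) / 2
  mean(abs(ws - mu) >= abs(wObs - mu) - 1e-9)
}

# Exact hypergeometric tails by enumeration over the support.
enumHyperTail <- function(k, K, n, N, tail) {
  pm <- vapply(0:n, function(i)
    choose(K, i) * choose(N - K, n - i) / choose(N, n), 0)
  if (tail == "upper") sum(pm[(k:n) + 1L]) else sum(pm[(0:k) + 1L])
}

# Standard simulated genome for classification checks: 80 autosomal, 15 X,
# 5 Y scaffolds, 20 windows of 50 kb each.
simGenome100 <- function(seed, depthF = 20, depthM = 30, dispersion = 10) {
  lens <- stats::setNames(rep(1e6, 100), sprintf("scaf%03d", 1:100))
  cls <- stats::setNames(c(rep("autosome", 80), rep("ancX", 15),
                           rep("Y", 5)), names(lens))
  cov <- simulateCoverage(lens, cls, windowSize = 50000, depthF = depthF,
                          depthM = depthM, dispersion = dispersion,
                          seed = seed)
  truth <- stats::setNames(
    c(autosome = "autosomal", ancX = "X_linked", Y = "Y_linked")[cls],
    names(cls))
  list(cov = cov, truth = truth)
}

# Fused chromosome with a theta step for breakpoint checks (50 + 50 windows
# of 50 kb, three autosomal reference chromosomes).
simFusedX <- function(seed, theta = 0.8, depthF = 40, depthM = 60,
                      dispersion = 1000) {
  lens <- c(chrXfused = 5e6, a1 = 5e6, a2 = 5e6, a3 = 5e6)
  segs <- data.frame(chrom = "chrXfused", start = c(0, 2.5e6),
                     end = c(2.5e6, 5e6), class = c("ancX", "neoX"))
  cov <- simulateCoverage(lens, c(a1 = "autosome", a2 = "autosome",
                                  a3 = "autosome"),
                          segments = segs, windowSize = 50000,
                          depthF = depthF, depthM = depthM,
                          dispersion = dispersion, theta = theta,
                          seed = seed)
  fmRatio(cov$female, cov$male)
}

# Gene classes for expression simulations: nAuto autosomal + nX ancestral-X.
geneClassesAX <- function(nAuto = 2000, nX = 500) {
  stats::setNames(c(rep("autosome", nAuto), rep("ancX", nX)),
                  sprintf("g%05d", seq_len(nAuto + nX)))
}
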