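#' Locate an ancestral-X/neo-X breakpoint by changepoint analysis
#'
#' Scans every window boundary of one chromosome for the single changepoint
#' that minimizes the total within-segment squared error of the log2 F/M
#' ratio (an exhaustive least-squares scan, so the estimate is the global
#' optimum by construction). If the best split reduces the total cost by
#' less than `minGain` (fraction of the unsegmented cost), the chromosome is
#' reported as having no breakpoint. The confidence interval collects all
#' boundaries whose cost is within one mean per-window cost unit of the
#' minimum. Flagged/uninformative windows are dropped before the scan.
#'
#' The left/right segment classes reported alongside (by median ratio
#' against the usual X/Y thresholds) let a synteny-based element assignment
#' corroborate the coverage breakpoint, as is done when placing the
#' boundary between the ancestral-X and neo-X arms of a fused X.
#'
#' @param x an [FMRatioTable-class] object.
#' @param chrom chromosome to scan.
#' @param minGain minimum fractional cost reduction to accept a breakpoint.
#' @param xThreshold,yThreshold ratio thresholds used only to label the two
#'   segments.
#' @return a list of class `"breakpointEstimate"`: `chrom`, `position` (bp
#'   at the chosen window boundary, `NA` if no breakpoint), `boundaryIndex`
#'   (index among informative windows: the breakpoint lies after this
#'   window), `ci` (index range), `leftClass`, `rightClass`, `gainFrac`,
#'   `costs` (per-boundary segmentation costs), `n`, `note`.
#' @export
detectBreakpoint <- function(x, chrom, minGain = 0.1,
                             xThreshold = 1.6, yThreshold = 0.3) {
  stopifnot(is(x, "FMRatioTable"))
  win <- x@windows
  win <- win[as.character(GenomicRanges::seqnames(win)) == chrom]
  if (!length(win)) stop("no windows on chromosome ", chrom)
  inf <- !win$flagged & !is.na(win$log2ratio)
  if (!any(inf)) stop("all windows on ", chrom, " are flagged")
  win <- win[inf]
  win <- win[order(GenomicRanges::start(win))]
  y <- win$log2ratio
  n <- length(y)
  if (n < 10L) stop("need at least 10 informative windows, have ", n)

  sc <- .scanChangepoint(y)
  res <- list(chrom = chrom, position = NA_real_, boundaryIndex = NA_integer_,
              ci = c(NA_integer_, NA_integer_), leftClass = NA_character_,
              rightClass = NA_character_, gainFrac = sc$gain,
              costs = sc$costs, n = n, note = "")
  if (sc$cost0 == 0 || sc$gain < minGain) {
    res$note <- "no breakpoint"
    class(res) <- "breakpointEstimate"
    return(res)
  }
  k <- sc$best
  unit <- min(sc$costs) / n
  ciSet <- which(sc$costs <= min(sc$costs) + unit)
  segClass <- function(idx) {
    m <- stats::median(win$ratio[idx])
    if (m >= xThreshold) "X_linked"
    else if (m <= yThreshold) "Y_linked" else "autosomal"
  }
  res$position <- GenomicRanges::end(win)[k]  # == 0-based half-open end
  res$boundaryIndex <- k
  res$ci <- range(ciSet)
  res$leftClass <- segClass(seq_len(k))
  res$rightClass <- segClass((k + 1L):n)
  class(res) <- "breakpointEstimate"
  res
}

# Exhaustive single-changepoint scan on a numeric vector: cost of splitting
# after index k (k = 1..n-1) via prefix sums.
.scanChangepoint <- function(y) {
  n <- length(y)
  S <- cumsum(y)
  Q <- cumsum(y^2)
  k <- seq_len(n - 1L)
  left <- Q[k] - S[k]^2 / k
  right <- (Q[n] - Q[k]) - (S[n] - S[k])^2 / (n - k)
  costs <- left + right
  cost0 <- Q[n] - S[n]^2 / n
  best <- which.min(costs)
  list(costs = costs, best = best, cost0 = cost0,
       gain = if (cost0 > 0) (cost0 - costs[best]) / cost0 else 0)
}

#' @export
print.breakpointEstimate <- function(x, ...) {
  if (is.na(x$position)) {
    cat("breakpointEstimate: no breakpoint on", x$chrom,
        sprintf("(best gain %.1f%%)\n", 100 * x$gainFrac))
  } else {
    cat(sprintf(
      "breakpointEstimate: %s:%d (after window %d of %d; CI windows %d-%d)\n",
      x$chrom, x$position, x$boundaryIndex, x$n, x$ci[1L], x$ci[2L]))
    cat(sprintf("  left %s | right %s; cost reduction %.1f%%\n",
                x$leftClass, x$rightClass, 100 * x$gainFrac))
  }
  invisible(x)
}
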