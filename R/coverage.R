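#' Median depth per genomic window
#'
#' Collapses a per-interval depth stream (bedGraph-style constant-depth
#' runs, or per-base records) to one median per tiling window. Each interval
#' contributes its per-site depth weighted by the number of its sites inside
#' the window (expand-and-sort semantics without materializing per-base
#' vectors); sites not covered by any interval count as depth 0, matching
#' the bedGraph convention of omitting zero runs. Completely empty windows
#' get depth 0 and are flagged.
#'
#' @param depth `GRanges` with numeric metadata column `depth` (>= 0),
#'   non-overlapping within a chromosome (as from [readBedGraph()]).
#' @param windows `GRanges` window tiling, or `NULL` to build one from
#'   `chromLengths`.
#' @param chromLengths named numeric chromosome lengths (bp), used when
#'   `windows` is `NULL`.
#' @param windowSize tile width in bp when building the tiling.
#' @param sample,sex sample annotations stored on the output.
#' @return the window `GRanges` with metadata columns `depth`, `flagged`,
#'   `sample`, `sex`.
#' @export
windowMedians <- function(depth, windows = NULL, chromLengths = NULL,
                          windowSize = 50000, sample = NA_character_,
                          sex = NA_character_) {
  stopifnot(is(depth, "GRanges"), "depth" %in% names(mcols(depth)))
  if (any(depth$depth < 0)) stop("negative depth values in input")
  if (is.null(windows)) {
    if (is.null(chromLengths))
      stop("provide either windows or chromLengths")
    windows <- GenomicRanges::tileGenome(chromLengths,
                                         tilewidth = windowSize,
                                         cut.last.tile.in.chrom = TRUE)
  }
  bad <- setdiff(as.character(unique(GenomicRanges::seqnames(depth))),
                 as.character(unique(GenomicRanges::seqnames(windows))))
  if (length(bad))
    stop("depth intervals on unknown chromosome(s): ",
         paste(bad, collapse = ", "))
  self <- GenomicRanges::findOverlaps(depth, drop.self = TRUE,
                                      drop.redundant = TRUE)
  if (length(self))
    stop("overlapping depth intervals (e.g. intervals ",
         S4Vectors::queryHits(self)[1L], " and ",
         S4Vectors::subjectHits(self)[1L], ")")

  ov <- GenomicRanges::findOverlaps(windows, depth)
  pint <- GenomicRanges::pintersect(windows[S4Vectors::queryHits(ov)],
                                    depth[S4Vectors::subjectHits(ov)])
  w <- GenomicRanges::width(pint)
  v <- depth$depth[S4Vectors::subjectHits(ov)]
  q <- S4Vectors::queryHits(ov)

  med <- numeric(length(windows))
  covered <- as.vector(tapply(w, factor(q, levels = seq_along(windows)),
                              sum, default = 0))
  winWidth <- GenomicRanges::width(windows)
  idx <- split(seq_along(q), q)
  for (k in names(idx)) {
    i <- as.integer(k)
    zero <- winWidth[i] - covered[i]
    med[i] <- weightedMedian(c(v[idx[[k]]], if (zero > 0) 0),
                             c(w[idx[[k]]], if (zero > 0) zero))
  }
  out <- windows
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    depth = med, flagged = covered == 0, sample = sample, sex = sex)
  out
}

#' Normalized female/male coverage ratio table
#'
#' Divides each sample's window depths by its own normalization constant
#' (the genome-wide median window depth, or the median over a supplied
#' autosomal scaffold set) and forms the per-window female/male ratio and
#' the per-scaffold median-of-window ratio. With autosomal-mode
#' normalization the genome-wide modal ratio sits at ~1; an X-linked window
#' then sits at ~2 and a Y-derived window near 0. Windows whose normalized
#' male depth falls below `minMDepth` are flagged as candidate
#' female-specific sequence and excluded from scaffold medians.
#'
#' @param female,male window `GRanges` with a `depth` column on an identical
#'   tiling (from [windowMedians()] or [simulateCoverage()]).
#' @param normalization `"genome_median"` (single pass) or
#'   `"autosomal_median"` (re-normalize against `autosomalScaffolds`, e.g.
#'   after a first-pass classification).
#' @param minMDepth normalized male depth floor (default 0.1, i.e. ~2-3
#'   reads at 20-30x).
#' @param autosomalScaffolds character vector of scaffolds treated as
#'   autosomal; required for `"autosomal_median"`.
#' @return an [FMRatioTable-class] object.
#' @export
fmRatio <- function(female, male,
                    normalization = c("genome_median", "autosomal_median"),
                    minMDepth = 0.1, autosomalScaffolds = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(is(female, "GRanges"), is(male, "GRanges"))
  if (length(female) != length(male) ||
      !all(as.character(GenomicRanges::seqnames(female)) ==
           as.character(GenomicRanges::seqnames(male))) ||
      !all(GenomicRanges::start(female) == GenomicRanges::start(male)) ||
      !all(GenomicRanges::end(female) == GenomicRanges::end(male)))
    stop("female and male tracks must share an identical window tiling")

  if (!length(female)) {
    win <- GenomicRanges::granges(female)
    S4Vectors::mcols(win) <- S4Vectors::DataFrame(
      depthF = numeric(), depthM = numeric(), normF = numeric(),
      normM = numeric(), ratio = numeric(), log2ratio = numeric(),
      flagged = logical())
    return(new("FMRatioTable", windows = win,
               scaffolds = data.frame(scaffold = character(),
                                      medianRatio = numeric(),
                                      nWindows = integer(),
                                      nFlagged = integer()),
               normConst = c(F = NA_real_, M = NA_real_),
               normalization = normalization, minMDepth = minMDepth))
  }
  normSet <- seq_along(female)
  if (normalization == "autosomal_median") {
    if (is.null(autosomalScaffolds))
      stop("autosomal_median normalization needs autosomalScaffolds")
    normSet <- which(as.character(GenomicRanges::seqnames(female)) %in%
                       autosomalScaffolds)
    if (!length(normSet)) stop("no windows on the autosomal scaffolds")
  }
  cF <- stats::median(female$depth[normSet])
  cM <- stats::median(male$depth[normSet])
  if (cF == 0 || cM == 0)
    stop("zero normalization constant; depth tracks look empty")

  normF <- female$depth / cF
  normM <- male$depth / cM
  emptyFlag <- rep(FALSE, length(female))
  for (tr in list(female, male))
    if ("flagged" %in% names(mcols(tr)))
      emptyFlag <- emptyFlag | tr$flagged
  flagged <- normM < minMDepth | emptyFlag
  ratio <- ifelse(flagged, NA_real_, normF / normM)
  log2ratio <- ifelse(!is.na(ratio) & ratio > 0, log2(ratio), NA_real_)

  win <- GenomicRanges::granges(female)
  S4Vectors::mcols(win) <- S4Vectors::DataFrame(
    depthF = female$depth, depthM = male$depth,
    normF = normF, normM = normM,
    ratio = ratio, log2ratio = log2ratio, flagged = flagged)
  if ("class" %in% names(mcols(female)))
    win$class <- female$class

  sn <- as.character(GenomicRanges::seqnames(win))
  scaffolds <- do.call(rbind, lapply(unique(sn), function(s) {
    i <- sn == s
    inf <- i & !flagged & !is.na(ratio)
    data.frame(scaffold = s,
               medianRatio = if (any(inf)) stats::median(ratio[inf])
                             else NA_real_,
               nWindows = sum(inf), nFlagged = sum(i & flagged),
               stringsAsFactors = FALSE)
  }))
  rownames(scaffolds) <- NULL
  new("FMRatioTable", windows = win, scaffolds = scaffolds,
      normConst = c(F = cF, M = cM), normalization = normalization,
      minMDepth = minMDepth)
}

#' Classify scaffolds as autosomal, X- or Y-linked
#'
#' Applies the coverage rule: a scaffold whose median normalized F/M window
#' ratio is at least `xThreshold` (inclusive, default 1.6x) is X-linked; at
#' most `yThreshold` with male depth above the floor, Y-linked; scaffolds
#' with fewer than `minWindows` informative windows are ambiguous; the rest
#' are autosomal. The theoretical X expectation is 2.0; the 1.6 default
#' leaves headroom for mapping noise.
#'
#' @param x an [FMRatioTable-class] object.
#' @param xThreshold,yThreshold ratio thresholds
#'   (`yThreshold < 1 < xThreshold`).
#' @param minWindows minimum informative windows per scaffold.
#' @return data.frame: `scaffold`, `class` (`autosomal` / `X_linked` /
#'   `Y_linked` / `ambiguous`), `medianRatio`, `nWindows`, `note`.
#' @export
classifyScaffolds <- function(x, xThreshold = 1.6, yThreshold = 0.3,
                              minWindows = 3) {
  stopifnot(is(x, "FMRatioTable"))
  if (!(yThreshold < 1 && 1 < xThreshold))
    stop("need yThreshold < 1 < xThreshold")
  sc <- x@scaffolds
  if (!nrow(sc))
    return(data.frame(scaffold = character(), class = character(),
                      medianRatio = numeric(), nWindows = integer(),
                      note = character(), stringsAsFactors = FALSE))
  cls <- ifelse(sc$nWindows < minWindows, "ambiguous",
         ifelse(sc$medianRatio >= xThreshold, "X_linked",
         ifelse(sc$medianRatio <= yThreshold, "Y_linked", "autosomal")))
  note <- ifelse(sc$nWindows < minWindows & sc$nFlagged > sc$nWindows,
                 "candidate_female_specific",
          ifelse(cls == "ambiguous", "low_information", ""))
  data.frame(scaffold = sc$scaffold, class = cls,
             medianRatio = sc$medianRatio, nWindows = sc$nWindows,
             note = note, stringsAsFactors = FALSE)
}

#' Quantify neo-sex differentiation of a chromosome region
#'
#' Summarizes how far a region has differentiated from its homolog: mean
#' normalized male depth relative to an autosomal reference (which estimates
#' `(1 + theta) / 2`, the retained neo-Y homology), the fraction of windows
#' at or above the X-linkage ratio threshold, and the SD of the log2 ratio
#' (heterogeneity -- young neo-X chromosomes are patchy).
#'
#' @param x an [FMRatioTable-class] object.
#' @param chrom chromosome/scaffold to score.
#' @param start,end optional bp bounds (0-based half-open) restricting the
#'   region.
#' @param referenceScaffolds scaffolds forming the autosomal reference;
#'   default all scaffolds other than `chrom`.
#' @param xThreshold ratio threshold for the high-ratio fraction.
#' @param minWindows minimum informative windows required in the region.
#' @return list: `relMaleDepth`, `fracX`, `heterogeneity`, `nWindows`.
#' @export
differentiationScore <- function(x, chrom, start = NULL, end = NULL,
                                 referenceScaffolds = NULL,
                                 xThreshold = 1.6, minWindows = 3) {
  stopifnot(is(x, "FMRatioTable"))
  win <- x@windows
  sn <- as.character(GenomicRanges::seqnames(win))
  inReg <- sn == chrom
  if (!is.null(start)) inReg <- inReg & GenomicRanges::end(win) > start
  if (!is.null(end)) inReg <- inReg & GenomicRanges::start(win) <= end
  if (!any(inReg)) stop("region outside the window tiling")
  if (is.null(referenceScaffolds)) referenceScaffolds <- setdiff(sn, chrom)
  ref <- sn %in% referenceScaffolds
  if (!any(ref)) stop("empty autosomal reference")
  inf <- inReg & !win$flagged & !is.na(win$ratio)
  if (sum(inf) < minWindows)
    stop("region has fewer than ", minWindows, " informative windows")
  list(relMaleDepth = mean(win$normM[inReg]) / mean(win$normM[ref]),
       fracX = mean(win$ratio[inf] >= xThreshold),
       heterogeneity = stats::sd(win$log2ratio[inf]),
       nWindows = sum(inf))
}
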