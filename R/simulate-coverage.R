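#' Simulate sexed window coverage tracks
#'
#' Draws per-window median depths for one female and one male sample from a
#' negative binomial (overdispersed Poisson, as read mapping is), with the
#' class-specific expectations of an XY system:
#'
#' * `autosome`: female `depthF`, male `depthM`;
#' * `ancX` (fully degenerate Y homolog): female `depthF`, male `depthM/2`;
#' * `neoX` (neo-Y retains a fraction `theta` of homology): female `depthF`,
#'   male `depthM * (1 + theta) / 2` -- `theta = 1` is indistinguishable from
#'   an autosome, `theta = 0` from the ancestral X;
#' * `Y`: male `depthM/2`, female at a small noise floor
#'   (`noiseFloorFrac * depthF`) emulating repetitive cross-mapping rather
#'   than exact zeros.
#'
#' Class blocks may subdivide a chromosome (`segments`), which is how a fused
#' chromosome with an ancestral-X arm and a less-differentiated neo-X arm is
#' produced for breakpoint detection.
#'
#' @param chromLengths named numeric, chromosome lengths in bp.
#' @param chromClasses named character, class per chromosome (one of
#'   `autosome`, `ancX`, `neoX`, `Y`). Ignored for chromosomes covered by
#'   `segments`.
#' @param segments optional data.frame (`chrom`, `start`, `end`, `class`)
#'   of class-homogeneous blocks (0-based half-open bp) overriding
#'   `chromClasses` on those chromosomes; blocks must tile the chromosome.
#' @param windowSize window size in bp (default 50 kb; 10 kb is the usual
#'   fine-scale alternative).
#' @param depthF,depthM mean autosomal per-site depth of the female and male
#'   sample (reads/site, > 0).
#' @param dispersion negative-binomial size parameter (> 0; larger is closer
#'   to Poisson).
#' @param theta neo-Y homology fraction in `[0, 1]`.
#' @param noiseFloorFrac female depth on Y windows, as a fraction of
#'   `depthF`.
#' @param seed integer seed.
#' @return list with elements `female` and `male`: `GRanges` window tilings
#'   with metadata columns `depth`, `sample`, `sex`, `flagged` (all `FALSE`
#'   here) and `class` (the simulated truth).
#' @export
simulateCoverage <- function(chromLengths, chromClasses = NULL,
                             segments = NULL, windowSize = 50000,
                             depthF = 20, depthM = 30, dispersion = 10,
                             theta = 0, noiseFloorFrac = 0.01, seed = 1L) {
  if (windowSize <= 0) stop("windowSize must be > 0")
  if (depthF <= 0 || depthM <= 0) stop("depths must be > 0")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (theta < 0 || theta > 1) stop("theta must be in [0, 1]")
  classes <- c("autosome", "ancX", "neoX", "Y")
  if (!is.null(chromClasses) && !all(chromClasses %in% classes))
    stop("unknown chromosome class; use ", paste(classes, collapse = "/"))
  if (!is.null(segments) && !all(segments$class %in% classes))
    stop("unknown segment class")

  set.seed(as.integer(seed))
  win <- GenomicRanges::tileGenome(chromLengths, tilewidth = windowSize,
                                   cut.last.tile.in.chrom = TRUE)
  cls <- rep(NA_character_, length(win))
  if (!is.null(chromClasses)) {
    cls <- unname(chromClasses[as.character(GenomicRanges::seqnames(win))])
  }
  if (!is.null(segments)) {
    seg <- GenomicRanges::GRanges(
      segments$chrom,
      IRanges::IRanges(segments$start + 1L, segments$end))
    mid <- GenomicRanges::resize(win, width = 1L, fix = "center")
    ov <- GenomicRanges::findOverlaps(mid, seg, select = "first")
    cls[!is.na(ov)] <- segments$class[ov[!is.na(ov)]]
  }
  if (anyNA(cls))
    stop("no class for chromosome(s): ",
         paste(unique(as.character(GenomicRanges::seqnames(win))[is.na(cls)]),
               collapse = ", "))

  muF <- ifelse(cls == "Y", depthF * noiseFloorFrac, depthF)
  muM <- c(autosome = depthM, ancX = depthM / 2,
           neoX = depthM * (1 + theta) / 2, Y = depthM / 2)[cls]
  n <- length(win)
  w <- GenomicRanges::width(win)
  # window depth = negative-binomial total read-bases over the window,
  # divided by window length: the per-window summary is near-continuous
  # (like a real median over tens of kb of sites) while the dispersion
  # parameter sets the window-to-window overdispersion (CV^2 ~ 1/size).
  draw <- function(mu) stats::rnbinom(n, size = dispersion, mu = mu * w) / w
  female <- win
  male <- win
  S4Vectors::mcols(female) <- S4Vectors::DataFrame(
    depth = draw(muF),
    sample = "femaleWGS", sex = "F", flagged = FALSE, class = cls)
  S4Vectors::mcols(male) <- S4Vectors::DataFrame(
    depth = draw(unname(muM)),
    sample = "maleWGS", sex = "M", flagged = FALSE, class = cls)
  list(female = female, male = male)
}
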