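#' Select samples of an expression experiment by metadata
#'
#' @param se `SummarizedExperiment` with `colData` columns `sex`,
#'   `compartment`, `tissue`.
#' @param sex,compartment,tissue optional filters; `NULL` means no
#'   restriction.
#' @return character vector of sample names.
#' @export
selectSamples <- function(se, sex = NULL, compartment = NULL,
                          tissue = NULL) {
  cd <- SummarizedExperiment::colData(se)
  keep <- rep(TRUE, nrow(cd))
  if (!is.null(sex)) keep <- keep & cd$sex %in% sex
  if (!is.null(compartment)) keep <- keep & cd$compartment %in% compartment
  if (!is.null(tissue)) keep <- keep & cd$tissue %in% tissue
  rownames(cd)[keep]
}

# per-gene group value = median over the group's samples (replicates)
.groupValue <- function(se, samples) {
  m <- SummarizedExperiment::assay(se)[, samples, drop = FALSE]
  apply(m, 1L, stats::median)
}

#' Filter to genes expressed in at least one of two groups
#'
#' Keeps genes whose group value (median over the group's replicates) is at
#' least `minValue` in either group -- the usual "FPKM >= 1 in either sex"
#' rule applied before sex-comparisons. Kept/dropped counts are stored in
#' `metadata(se)$expressionFilter`.
#'
#' @param se `SummarizedExperiment` with an `fpkm`-like assay.
#' @param groupA,groupB character vectors of sample names (see
#'   [selectSamples()]); both must be nonempty.
#' @param minValue inclusive threshold.
#' @return the filtered `SummarizedExperiment`.
#' @export
filterExpressed <- function(se, groupA, groupB, minValue = 1) {
  if (!length(groupA) || !length(groupB))
    stop("both scope groups must be nonempty")
  vA <- .groupValue(se, groupA)
  vB <- .groupValue(se, groupB)
  keep <- vA >= minValue | vB >= minValue
  out <- se[keep, ]
  S4Vectors::metadata(out)$expressionFilter <-
    list(kept = sum(keep), dropped = sum(!keep), minValue = minValue)
  out
}

#' Partition genes into chromosome strata
#'
#' Assigns every gene to `autosome`, `anc-X`, `neo-X`, `Y` or `excluded`
#' from its coordinates, the identity of the X (and optionally Y)
#' chromosome, and the ancestral-X/neo-X breakpoint. A gene is placed by
#' its start coordinate relative to the breakpoint.
#'
#' @param genes gene coordinate table: `GRanges` with a `gene_id` column
#'   (as from [readGeneBed()]), or a data.frame with `gene_id`, `chrom`,
#'   `start`.
#' @param xChrom the X chromosome id.
#' @param breakpoint bp position of the anc-X/neo-X boundary on `xChrom`
#'   (`NULL` puts the whole X in `anc-X`).
#' @param ancSide which side of the breakpoint is the ancestral X
#'   (`"left"` = coordinates below the breakpoint).
#' @param yChroms,excludeChroms optional chromosome sets for `Y` and
#'   `excluded`.
#' @return named character vector gene id -> stratum.
#' @export
chromPartition <- function(genes, xChrom, breakpoint = NULL,
                           ancSide = c("left", "right"),
                           yChroms = character(),
                           excludeChroms = character()) {
  ancSide <- match.arg(ancSide)
  if (is(genes, "GRanges")) {
    df <- data.frame(gene_id = genes$gene_id,
                     chrom = as.character(GenomicRanges::seqnames(genes)),
                     start = GenomicRanges::start(genes) - 1L,
                     stringsAsFactors = FALSE)
  } else df <- genes
  stratum <- rep("autosome", nrow(df))
  stratum[df$chrom %in% yChroms] <- "Y"
  stratum[df$chrom %in% excludeChroms] <- "excluded"
  onX <- df$chrom == xChrom
  if (is.null(breakpoint)) {
    stratum[onX] <- "anc-X"
  } else {
    left <- df$start < breakpoint
    stratum[onX & left] <- if (ancSide == "left") "anc-X" else "neo-X"
    stratum[onX & !left] <- if (ancSide == "left") "neo-X" else "anc-X"
  }
  stats::setNames(stratum, df$gene_id)
}

#' Classify genes as ovary-, testis-biased or unbiased
#'
#' A gene is gonad-biased when its expression in one gonad is strictly more
#' than `fold` times higher than in every other assayed tissue (per-tissue
#' value = median of replicates). The inequality is strict, so a gene at
#' exactly `fold`-times is unbiased, and all-zero genes are unbiased.
#'
#' @param se `SummarizedExperiment`; `colData` must identify an ovary
#'   (female gonad) and a testis (male gonad) tissue.
#' @param fold bias fold threshold (default 2).
#' @return data.frame: `gene_id`, `bias` (`ovary`/`testis`/`unbiased`),
#'   `ovary`, `testis`, `maxOtherOvary`, `maxOtherTestis`.
#' @export
classifyGonadBias <- function(se, fold = 2) {
  cd <- SummarizedExperiment::colData(se)
  tiss <- unique(data.frame(tissue = cd$tissue, sex = cd$sex,
                            compartment = cd$compartment,
                            stringsAsFactors = FALSE))
  ovary <- tiss$tissue[tiss$compartment == "gonad" & tiss$sex == "F"]
  testis <- tiss$tissue[tiss$compartment == "gonad" & tiss$sex == "M"]
  if (length(ovary) != 1L || length(testis) != 1L)
    stop("need exactly one ovary and one testis tissue in the sample sheet")
  if (nrow(tiss) < 3L)
    stop("need at least one non-gonad tissue")
  vals <- vapply(tiss$tissue, function(tt)
    .groupValue(se, selectSamples(se, tissue = tt)),
    numeric(nrow(se)))
  if (is.null(dim(vals)))
    vals <- matrix(vals, nrow = 1L,
                   dimnames = list(rownames(se), tiss$tissue))
  maxOther <- function(excl)
    apply(vals[, setdiff(tiss$tissue, excl), drop = FALSE], 1L, max)
  moO <- maxOther(ovary)
  moT <- maxOther(testis)
  bias <- ifelse(vals[, ovary] > fold * moO, "ovary",
          ifelse(vals[, testis] > fold * moT, "testis", "unbiased"))
  data.frame(gene_id = rownames(se), bias = bias,
             ovary = vals[, ovary], testis = vals[, testis],
             maxOtherOvary = moO, maxOtherTestis = moT,
             stringsAsFactors = FALSE, row.names = NULL)
}
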