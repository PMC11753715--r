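#' Default tissue panel for expression simulation
#'
#' Testis, ovary, gonadectomized carcasses and heads of both sexes, two
#' replicates each -- the standard sexed tissue panel for insect expression
#' work.
#'
#' @param replicates replicates per tissue.
#' @return data.frame with columns `tissue`, `sex`, `compartment`,
#'   `replicates`.
#' @export
defaultTissuePanel <- function(replicates = 2L) {
  data.frame(
    tissue = c("testis", "ovary", "gtM", "gtF", "headM", "headF"),
    sex = c("M", "F", "M", "F", "M", "F"),
    compartment = c("gonad", "gonad", "soma", "soma", "soma", "soma"),
    replicates = replicates,
    stringsAsFactors = FALSE
  )
}

#' Simulate an FPKM-like expression matrix with known dosage and bias truth
#'
#' Gene baselines are log-normal; each sample observation multiplies the
#' baseline by log-normal noise. Hemizygosity and its compensation are a
#' two-state (optionally intermediate) model applied to X-class genes
#' (`ancX`/`neoX`) in male samples: with no dosage compensation a male
#' carries one X copy and expression halves; complete compensation restores
#' it; partial compensation with parameter `lambda` scales by
#' `(1 + lambda) / 2`. Gonad-biased genes are spiked by `biasFold` in their
#' target gonad (ovary for ovary-biased, testis for testis-biased) only.
#'
#' @param geneClasses named character: gene id -> stratum (`autosome`,
#'   `ancX`, `neoX`; anything else is treated as autosomal for dosage).
#' @param tissues data.frame as [defaultTissuePanel()]; must contain at
#'   least one male and one female tissue.
#' @param meanLog,sdLog log-scale mean and sd of the gene baseline
#'   (default: median FPKM around `exp(3) ~ 20`).
#' @param noiseSd log-scale sd of per-sample noise.
#' @param dcMode `"complete"`, `"none"`, or a numeric `lambda` in `[0, 1]`
#'   for partial compensation.
#' @param fracOvaryBiased,fracTestisBiased fraction of genes that are
#'   ovary-/testis-biased; either a single number or a named vector per
#'   stratum. The two fractions must sum to <= 1 in every stratum.
#' @param biasFold fold-change of biased genes in their target gonad.
#' @param seed integer seed.
#' @return list with `se` (a `SummarizedExperiment`; assay `"fpkm"`,
#'   `colData` columns `sample`, `sex`, `compartment`, `tissue`,
#'   `replicate`) and `truth` (data.frame `gene_id`, `class`, `bias` with
#'   `bias` one of `ovary`/`testis`/`unbiased`).
#' @export
simulateExpression <- function(geneClasses, tissues = defaultTissuePanel(),
                               meanLog = 3, sdLog = 1, noiseSd = 0.2,
                               dcMode = "complete",
                               fracOvaryBiased = 0.1,
                               fracTestisBiased = 0.1,
                               biasFold = 4, seed = 1L) {
  if (nrow(tissues) < 1L || !all(c("M", "F") %in% tissues$sex))
    stop("need at least one male and one female tissue")
  if (is.null(names(geneClasses)) || !length(geneClasses))
    stop("geneClasses must be a named character vector")
  if (biasFold <= 1) stop("biasFold must be > 1")
  dc <- if (identical(dcMode, "complete")) 1 else
    if (identical(dcMode, "none")) 0.5 else
    if (is.numeric(dcMode) && dcMode >= 0 && dcMode <= 1) (1 + dcMode) / 2 else
    stop("dcMode must be 'complete', 'none' or lambda in [0, 1]")

  set.seed(as.integer(seed))
  genes <- names(geneClasses)
  nGenes <- length(genes)
  strata <- unique(geneClasses)
  fracFor <- function(frac, st)
    if (length(frac) == 1L && is.null(names(frac))) frac else
      ifelse(is.na(frac[st]), 0, frac[st])

  bias <- rep("unbiased", nGenes)
  names(bias) <- genes
  for (st in strata) {
    fo <- fracFor(fracOvaryBiased, st)
    ft <- fracFor(fracTestisBiased, st)
    if (fo + ft > 1) stop("bias fractions must sum to <= 1 per stratum")
    idx <- which(geneClasses == st)
    nb <- round(c(fo, ft) * length(idx))
    pick <- sample(idx, sum(nb))
    bias[pick[seq_len(nb[1L])]] <- "ovary"
    if (nb[2L] > 0) bias[pick[nb[1L] + seq_len(nb[2L])]] <- "testis"
  }

  baseline <- stats::rlnorm(nGenes, meanlog = meanLog, sdlog = sdLog)
  reps <- if ("replicates" %in% names(tissues)) tissues$replicates else 2L
  reps <- rep(reps, length.out = nrow(tissues))
  sheet <- data.frame(
    tissue = rep(tissues$tissue, reps),
    sex = rep(tissues$sex, reps),
    compartment = rep(tissues$compartment, reps),
    replicate = unlist(lapply(reps, seq_len), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  sheet$sample <- paste0(sheet$tissue, "_r", sheet$replicate)
  rownames(sheet) <- sheet$sample

  isX <- geneClasses %in% c("ancX", "neoX")
  mat <- matrix(0, nGenes, nrow(sheet),
                dimnames = list(genes, sheet$sample))
  for (j in seq_len(nrow(sheet))) {
    mu <- baseline
    if (sheet$sex[j] == "M") mu[isX] <- mu[isX] * dc
    target <- if (sheet$tissue[j] == "ovary") "ovary" else
      if (sheet$tissue[j] == "testis") "testis" else NA
    if (!is.na(target)) {
      hit <- bias == target
      mu[hit] <- mu[hit] * biasFold
    }
    mat[, j] <- mu * exp(stats::rnorm(nGenes, 0, noiseSd))
  }

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = mat),
    colData = S4Vectors::DataFrame(sheet))
  truth <- data.frame(gene_id = genes, class = unname(geneClasses),
                      bias = unname(bias), stringsAsFactors = FALSE)
  list(se = se, truth = truth)
}
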