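#' Dosage-compensation comparison across chromosome strata
#'
#' For each chromosome stratum, computes per-gene male and female values
#' (median over the chosen compartment's replicates), the stratum medians
#' and their M/F ratio (ratio of medians, the boxplot framing), then runs
#' all pairwise Wilcoxon rank-sum tests between the stratum-by-sex groups
#' with Bonferroni correction over the pairs tested, and summarizes them as
#' compact letter groups (groups sharing a letter are not significantly
#' different). A fully compensated X has an M/F ratio near 1 and a male
#' X-vs-autosome contrast that is not significant; an uncompensated X sits
#' near 0.5 and differs significantly.
#'
#' @param se filtered `SummarizedExperiment` (see [filterExpressed()]).
#' @param partition named character gene -> stratum (see
#'   [chromPartition()]); strata `excluded` are dropped, strata with < 2
#'   genes are dropped with a warning.
#' @param compartment compartment analyzed (default `"soma"`).
#' @param alpha significance level applied to Bonferroni-adjusted p-values.
#' @return list of class `"dosageResult"`: `strata` (per-stratum n and
#'   medians), `tests` (pairwise `groupA`, `groupB`, `W`, `p`, `padj`,
#'   `significant`), `letters`, `familySize`, `compartment`.
#' @export
dosageCompare <- function(se, partition, compartment = "soma",
                          alpha = 0.05) {
  genes <- intersect(rownames(se), names(partition))
  if (!length(genes)) stop("partition covers none of the matrix genes")
  se <- se[genes, ]
  strat <- partition[genes]
  keepStrat <- sort(setdiff(unique(strat), "excluded"))
  small <- keepStrat[vapply(keepStrat,
                            function(s) sum(strat == s) < 2L, TRUE)]
  if (length(small)) {
    warning("dropping strata with < 2 genes: ",
            paste(small, collapse = ", "))
    keepStrat <- setdiff(keepStrat, small)
  }
  mSamp <- selectSamples(se, sex = "M", compartment = compartment)
  fSamp <- selectSamples(se, sex = "F", compartment = compartment)
  if (!length(mSamp) || !length(fSamp))
    stop("no samples for compartment ", compartment)
  vM <- .groupValue(se, mSamp)
  vF <- .groupValue(se, fSamp)

  strataDf <- do.call(rbind, lapply(keepStrat, function(s) {
    i <- strat == s
    data.frame(stratum = s, n = sum(i),
               medianM = stats::median(vM[i]),
               medianF = stats::median(vF[i]),
               ratioMF = stats::median(vM[i]) / stats::median(vF[i]),
               stringsAsFactors = FALSE)
  }))

  groups <- list()
  for (s in keepStrat) {
    groups[[paste0(s, ".M")]] <- vM[strat == s]
    groups[[paste0(s, ".F")]] <- vF[strat == s]
  }
  gn <- names(groups)
  pairs <- t(utils::combn(gn, 2L))
  family <- nrow(pairs)
  tests <- do.call(rbind, lapply(seq_len(family), function(i) {
    ht <- wilcoxonRankSum(groups[[pairs[i, 1L]]], groups[[pairs[i, 2L]]],
                          mode = "auto")
    data.frame(groupA = pairs[i, 1L], groupB = pairs[i, 2L],
               W = ht$W, p = ht$p, stringsAsFactors = FALSE)
  }))
  tests$padj <- pmin(1, tests$p * family)
  tests$significant <- tests$padj < alpha
  letters <- .letterGroups(gn, pairs, tests$significant)

  structure(list(strata = strataDf, tests = tests, letters = letters,
                 familySize = family, compartment = compartment),
            class = "dosageResult")
}

#' @export
print.dosageResult <- function(x, ...) {
  cat("dosageResult (", x$compartment, "): ",
      nrow(x$strata), " strata, Bonferroni family of ",
      x$familySize, " pairwise tests\n", sep = "")
  df <- x$strata
  df$letters <- x$letters[paste0(df$stratum, ".M")]
  print(df, row.names = FALSE)
  invisible(x)
}

#' Neo-X expression versus its ancestral (proto-X) level
#'
#' Compares expression of neo-X genes in the focal species with the
#' expression of their 1:1 orthologs in an outgroup where the homologous
#' element is still autosomal (the proto-X). If dosage compensation has
#' restored the ancestral output, the neo-X/proto-X median ratio is near 1
#' in both sexes and the rank test is not significant; without
#' compensation, males sit near 0.5 while females remain near 1.
#'
#' @param focal,outgroup `SummarizedExperiment`s for the two species.
#' @param orthologMap data.frame with columns `focal` and `outgroup`
#'   (1:1 gene id pairs on the neo-X set).
#' @param neoXGenes focal gene ids on the neo-X.
#' @param compartment compartment analyzed.
#' @return data.frame, one row per sex: `sex`, `nPairs`, `medianFocal`,
#'   `medianOutgroup`, `ratio`, `W`, `p`.
#' @export
protoVsNeo <- function(focal, outgroup, orthologMap, neoXGenes,
                       compartment = "soma") {
  map <- orthologMap[orthologMap$focal %in% neoXGenes, , drop = FALSE]
  map <- map[map$focal %in% rownames(focal) &
               map$outgroup %in% rownames(outgroup), , drop = FALSE]
  if (anyDuplicated(map$focal) || anyDuplicated(map$outgroup))
    stop("ortholog map must be 1:1 on the neo-X set")
  if (nrow(map) < 20)
    warning("only ", nrow(map), " mapped neo-X pairs; estimates are noisy")
  if (!nrow(map)) stop("no mapped neo-X orthologs")
  do.call(rbind, lapply(c("M", "F"), function(sx) {
    fv <- .groupValue(focal[map$focal, ],
                      selectSamples(focal, sex = sx,
                                    compartment = compartment))
    ov <- .groupValue(outgroup[map$outgroup, ],
                      selectSamples(outgroup, sex = sx,
                                    compartment = compartment))
    ht <- wilcoxonRankSum(fv, ov, mode = "auto")
    data.frame(sex = sx, nPairs = nrow(map),
               medianFocal = stats::median(fv),
               medianOutgroup = stats::median(ov),
               ratio = stats::median(fv) / stats::median(ov),
               W = ht$W, p = ht$p, stringsAsFactors = FALSE)
  }))
}

#' Enrichment/depletion of gonad-biased genes per chromosome stratum
#'
#' Hypergeometric tests of each stratum against the genome-wide background:
#' for every stratum and bias class, the upper tail (enrichment) and lower
#' tail (depletion) are tested, Bonferroni-corrected over all
#' stratum-by-class-by-tail tests performed, and turned into a verdict.
#'
#' @param calls bias calls from [classifyGonadBias()] (or a data.frame with
#'   `gene_id`, `bias`). The genes in `calls` define the background `N`
#'   (typically the expression-filtered gene set).
#' @param partition named character gene -> stratum; `excluded` genes are
#'   dropped from both stratum and background.
#' @param alpha significance level on adjusted p-values.
#' @param tails `"both"`, `"upper"` or `"lower"`.
#' @param minStratum strata with fewer genes are skipped with a warning.
#' @return data.frame: `stratum`, `bias`, `k`, `n`, `K`, `N`,
#'   `pEnrichment`, `pDepletion`, `padjEnrichment`, `padjDepletion`,
#'   `verdict` (`enriched`/`depleted`/`ns`).
#' @export
testEnrichment <- function(calls, partition, alpha = 0.05,
                           tails = c("both", "upper", "lower"),
                           minStratum = 20) {
  tails <- match.arg(tails)
  df <- data.frame(gene_id = calls$gene_id, bias = calls$bias,
                   stringsAsFactors = FALSE)
  df$stratum <- unname(partition[df$gene_id])
  df <- df[!is.na(df$stratum) & df$stratum != "excluded", ]
  N <- nrow(df)
  strata <- sort(unique(df$stratum))
  small <- strata[table(df$stratum)[strata] < minStratum]
  if (length(small)) {
    warning("skipping strata with < ", minStratum, " genes: ",
            paste(small, collapse = ", "))
    strata <- setdiff(strata, small)
  }
  classes <- c("ovary", "testis")
  rows <- list()
  for (s in strata) for (cl in classes) {
    inS <- df$stratum == s
    K <- sum(df$bias == cl)
    k <- sum(inS & df$bias == cl)
    n <- sum(inS)
    pUp <- if (K == 0) 1 else hypergeometricTail(k, K, n, N, "upper")
    pLo <- if (K == 0) 1 else hypergeometricTail(k, K, n, N, "lower")
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = s, bias = cl, k = k, n = n, K = K, N = N,
      pEnrichment = pUp, pDepletion = pLo, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  family <- nrow(out) * if (tails == "both") 2L else 1L
  out$padjEnrichment <- if (tails == "lower") NA_real_ else
    pmin(1, out$pEnrichment * family)
  out$padjDepletion <- if (tails == "upper") NA_real_ else
    pmin(1, out$pDepletion * family)
  out$verdict <- "ns"
  if (tails != "lower")
    out$verdict[out$padjEnrichment < alpha] <- "enriched"
  if (tails != "upper")
    out$verdict[!is.na(out$padjDepletion) & out$padjDepletion < alpha &
                  out$verdict == "ns"] <- "depleted"
  attr(out, "familySize") <- family
  out
}
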