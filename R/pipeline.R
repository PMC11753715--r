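#' Pipeline configuration
#'
#' Builds and validates the configuration for [runPipeline()]. All
#' thresholds are checked up front, so an invalid configuration is rejected
#' before any stage runs. The configuration round-trips through YAML
#' unchanged ([writePipelineConfig()] / [readPipelineConfig()]).
#'
#' @param tree newick text for the simulated species tree.
#' @param nElements,genesPerElement,fusionRate,fissionRate,shuffleRate
#'   karyotype/ortholog simulation parameters.
#' @param tip tip whose genome is "sequenced" (default: first tip).
#' @param bpPerGene bp of chromosome per gene when laying simulated genes
#'   out on physical coordinates.
#' @param windowSize,depthF,depthM,dispersion,theta,minMDepth coverage
#'   simulation and ratio parameters.
#' @param xThreshold,yThreshold,minWindows scaffold classification
#'   thresholds.
#' @param minOrthologs,majorityFrac element assignment parameters.
#' @param dcMode,fracOvaryBiased,fracTestisBiased,biasFold expression
#'   simulation parameters.
#' @param minFpkm,fold,alpha expression analysis parameters.
#' @param normalization `"genome_median"` or `"autosomal_median"` (the
#'   latter re-normalizes once against first-pass autosomal calls).
#' @param seed single global seed; stage seeds are derived from it.
#' @return a validated list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(tree = "((tip1:1,tip2:1):1,(tip3:1,(tip4:1,tip5:1):0.5):1);",
                           nElements = 9, genesPerElement = 200,
                           fusionRate = 0.3, fissionRate = 0.15,
                           shuffleRate = 0.2, tip = NULL,
                           bpPerGene = 10000, windowSize = 50000,
                           depthF = 20, depthM = 30, dispersion = 10,
                           theta = 0.6, minMDepth = 0.1,
                           xThreshold = 1.6, yThreshold = 0.3,
                           minWindows = 3, minOrthologs = 20,
                           majorityFrac = 0.5, dcMode = "complete",
                           fracOvaryBiased = 0.1, fracTestisBiased = 0.1,
                           biasFold = 4, minFpkm = 1, fold = 2,
                           alpha = 0.05,
                           normalization = "genome_median",
                           seed = 1L) {
  cfg <- as.list(environment())
  validatePipelineConfig(cfg)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' @rdname pipelineConfig
#' @param config a configuration list.
#' @export
validatePipelineConfig <- function(config) {
  with(config, {
    if (!(xThreshold > 1)) stop("xThreshold must be > 1")
    if (!(yThreshold > 0 && yThreshold < 1))
      stop("yThreshold must be in (0, 1)")
    if (!(majorityFrac > 0 && majorityFrac < 1))
      stop("majorityFrac must be in (0, 1)")
    if (theta < 0 || theta > 1) stop("theta must be in [0, 1]")
    if (windowSize <= 0 || bpPerGene <= 0)
      stop("windowSize and bpPerGene must be > 0")
    if (minFpkm < 0) stop("minFpkm must be >= 0")
    if (fold <= 0) stop("fold must be > 0")
    if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
    if (!normalization %in% c("genome_median", "autosomal_median"))
      stop("unknown normalization mode: ", normalization)
  })
  invisible(TRUE)
}

#' @rdname pipelineConfig
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validatePipelineConfig(cfg)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Run the full demo pipeline
#'
#' Executes simulate -> sex-linkage -> elements -> dosage -> enrichment on
#' synthetic data with known ground truth and writes every result as a TSV
#' with a provenance header (tool version, configuration hash, seed). Given
#' the same configuration and seed the outputs are byte-identical across
#' runs. Any stage failure aborts with the stage name and cause.
#'
#' @param config a [pipelineConfig()].
#' @param outdir output directory (created if needed).
#' @return (invisibly) a list with all in-memory stage results and the
#'   output file paths.
#' @export
runPipeline <- function(config, outdir) {
  validatePipelineConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(tool = "karyoevolve",
            version = as.character(utils::packageVersion("karyoevolve")),
            config_hash = configHash(yaml::as.yaml(unclass(config))),
            seed = as.character(config$seed))
  logLines <- character()
  note <- function(...) logLines <<- c(logLines, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## 1. simulate karyotypes + orthologs ------------------------------------
  history <- stage("simulate", simulateKaryotypeHistory(
    config$tree, config$nElements, config$genesPerElement,
    config$fusionRate, config$fissionRate,
    seed = deriveSeed(config$seed, 1L)))
  ortho <- stage("simulate", simulateOrthologTable(
    history, config$shuffleRate, seed = deriveSeed(config$seed, 2L),
    includeRoot = TRUE))
  tip <- config$tip
  if (is.null(tip)) tip <- history@tree$tip.label[1L]
  note("simulate: ", length(history@geneElement), " genes, ",
       sum(lengths(history@events)), " events, tip=", tip)

  ## 2. coverage + sex-linkage ---------------------------------------------
  lay <- .tipLayout(history, tip, config$bpPerGene)
  chromLengths <- c(lay$chromLengths,
                    chrY = config$genesPerElement * config$bpPerGene / 2)
  cov <- stage("sexlink", simulateCoverage(
    chromLengths, chromClasses = c(chrY = "Y"), segments = lay$segments,
    windowSize = config$windowSize, depthF = config$depthF,
    depthM = config$depthM, dispersion = config$dispersion,
    theta = config$theta, seed = deriveSeed(config$seed, 3L)))
  fmt <- stage("sexlink", fmRatio(cov$female, cov$male,
                                  minMDepth = config$minMDepth))
  if (config$normalization == "autosomal_median") {
    firstPass <- classifyScaffolds(fmt, config$xThreshold,
                                   config$yThreshold, config$minWindows)
    fmt <- stage("sexlink", fmRatio(
      cov$female, cov$male, normalization = "autosomal_median",
      minMDepth = config$minMDepth,
      autosomalScaffolds =
        firstPass$scaffold[firstPass$class == "autosomal"]))
  }
  calls <- stage("sexlink", classifyScaffolds(
    fmt, config$xThreshold, config$yThreshold, config$minWindows))
  note("sexlink: ", nrow(calls), " scaffolds (",
       sum(calls$class == "X_linked"), " X, ",
       sum(calls$class == "Y_linked"), " Y)")

  xScaf <- calls[calls$class == "X_linked", ]
  bp <- NULL
  if (nrow(xScaf)) {
    best <- xScaf$scaffold[which.max(xScaf$nWindows)]
    bp <- tryCatch(detectBreakpoint(fmt, best,
                                    xThreshold = config$xThreshold,
                                    yThreshold = config$yThreshold),
                   error = function(e) NULL)
  }
  note("breakpoint: ",
       if (is.null(bp) || is.na(bp$position)) "none"
       else paste0(bp$chrom, ":", bp$position))

  ## 3. elements ------------------------------------------------------------
  targets <- history@tree$tip.label
  matrices <- stage("elements", lapply(
    stats::setNames(targets, targets),
    function(sp) buildHomologyMatrix(ortho, "ancestor", sp)))
  assignment <- stage("elements", assignElements(
    matrices, config$minOrthologs, config$majorityFrac, focalX = "ancX"))
  comp <- stage("elements", compositionTable(assignment))
  events <- stage("elements", countEvents(assignment))
  neoSex <- stage("elements", detectNeoSexElements(assignment, calls, tip))
  note("elements: ", sum(assignment@table$assigned), " of ",
       nrow(assignment@table), " focal groups assigned; ",
       nrow(neoSex), " sex-linked in ", tip)

  ## 4. dosage + bias --------------------------------------------------------
  expr <- stage("dosage", simulateExpression(
    lay$geneClasses, dcMode = config$dcMode,
    fracOvaryBiased = config$fracOvaryBiased,
    fracTestisBiased = config$fracTestisBiased,
    biasFold = config$biasFold, seed = deriveSeed(config$seed, 4L)))
  filtered <- stage("dosage", filterExpressed(
    expr$se,
    selectSamples(expr$se, sex = "M", compartment = "soma"),
    selectSamples(expr$se, sex = "F", compartment = "soma"),
    minValue = config$minFpkm))
  dosage <- stage("dosage", dosageCompare(
    filtered, lay$geneClasses, compartment = "soma",
    alpha = config$alpha))
  bias <- stage("enrich", classifyGonadBias(filtered, config$fold))
  enrich <- stage("enrich", testEnrichment(
    bias, lay$geneClasses, alpha = config$alpha))
  note("dosage: ", nrow(filtered), " expressed genes; ",
       sum(bias$bias != "unbiased"), " gonad-biased")

  ## 5. outputs --------------------------------------------------------------
  win <- fmt@windows
  winDf <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(win)),
    start = GenomicRanges::start(win) - 1L,
    end = GenomicRanges::end(win),
    as.data.frame(S4Vectors::mcols(win)),
    check.names = FALSE)
  bpDf <- if (is.null(bp)) {
    data.frame(chrom = NA_character_, position = NA_real_,
               leftClass = NA_character_, rightClass = NA_character_,
               note = "no X scaffold")
  } else {
    data.frame(chrom = bp$chrom, position = bp$position,
               leftClass = bp$leftClass, rightClass = bp$rightClass,
               note = bp$note)
  }
  paths <- c(
    orthologs = writeOrthologTable(ortho,
                                   file.path(outdir, "orthologs.tsv"), meta),
    windows = writeTsvWithHeader(winDf,
                                 file.path(outdir, "windows.tsv"), meta),
    scaffold_calls = writeTsvWithHeader(
      calls, file.path(outdir, "scaffold_calls.tsv"), meta),
    breakpoints = writeTsvWithHeader(
      bpDf, file.path(outdir, "breakpoints.tsv"), meta),
    composition = writeTsvWithHeader(
      comp, file.path(outdir, "composition.tsv"), meta),
    events = writeTsvWithHeader(
      events, file.path(outdir, "events.tsv"), meta),
    neo_sex = writeTsvWithHeader(
      neoSex, file.path(outdir, "neo_sex_elements.tsv"), meta),
    dosage_strata = writeTsvWithHeader(
      dosage$strata, file.path(outdir, "dosage_strata.tsv"), meta),
    dosage_tests = writeTsvWithHeader(
      dosage$tests, file.path(outdir, "dosage_tests.tsv"), meta),
    bias_calls = writeTsvWithHeader(
      bias, file.path(outdir, "bias_calls.tsv"), meta),
    enrichment = writeTsvWithHeader(
      enrich, file.path(outdir, "enrichment.tsv"), meta))
  writeLines(c(sprintf("# %s=%s", names(meta), meta), logLines),
             file.path(outdir, "run.log"))
  paths <- c(paths, log = file.path(outdir, "run.log"))

  invisible(list(history = history, orthologs = ortho, ratios = fmt,
                 calls = calls, breakpoint = bp, assignment = assignment,
                 composition = comp, events = events, neoSex = neoSex,
                 expression = filtered, dosage = dosage, bias = bias,
                 enrichment = enrich, paths = paths, log = logLines))
}

# Physical layout of a simulated tip genome: each gene occupies bpPerGene
# bp; class-homogeneous segments (ancX gene runs, neo arms on X-bearing
# chromosomes, autosomal blocks) for the coverage simulator, plus the true
# per-gene stratum labels for the expression stages.
.tipLayout <- function(history, tip, bpPerGene) {
  m <- tipKaryotype(history, tip)
  m <- m[order(m$chrom, m$position), ]
  xChroms <- unique(m$chrom[m$element == "X"])
  cls <- ifelse(m$element == "X", "ancX",
         ifelse(m$chrom %in% xChroms, "neoX", "autosome"))
  segs <- list()
  lens <- c()
  for (ch in unique(m$chrom)) {
    i <- which(m$chrom == ch)
    runs <- rle(cls[i])
    ends <- cumsum(runs$lengths)
    starts <- c(0L, utils::head(ends, -1L))
    segs[[ch]] <- data.frame(chrom = ch,
                             start = starts * bpPerGene,
                             end = ends * bpPerGene,
                             class = runs$values,
                             stringsAsFactors = FALSE)
    lens[ch] <- length(i) * bpPerGene
  }
  list(segments = do.call(rbind, segs),
       chromLengths = lens,
       geneClasses = stats::setNames(cls, m$gene_id))
}
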