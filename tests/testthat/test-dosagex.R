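makeSE <- function(mat, sheet) {
  colnames(mat) <- sheet$sample
  rownames(sheet) <- sheet$sample
  SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = mat), colData = S4Vectors::DataFrame(sheet))
}

simpleSheet <- function() {
  data.frame(sample = c("testis_r1", "ovary_r1", "headM_r1", "headF_r1"),
             tissue = c("testis", "ovary", "headM", "headF"),
             sex = c("M", "F", "M", "F"),
             compartment = c("gonad", "gonad", "soma", "soma"),
             replicate = 1L, stringsAsFactors = FALSE)
}

test_that("expression filter keeps genes at >= 1 FPKM in either group", {
  sheet <- simpleSheet()
  mat <- rbind(g1 = c(0.5, 0.5, 0.5, 0.5),
               g2 = c(0, 0, 1.0, 0.0),
               g3 = c(5, 5, 0.99, 0.99),
               g4 = c(9, 9, 3, 2))
  se <- makeSE(mat, sheet)
  gM <- selectSamples(se, sex = "M", compartment = "soma")
  gF <- selectSamples(se, sex = "F", compartment = "soma")
  kept <- filterExpressed(se, gM, gF, minValue = 1)
  # g2 kept (1.0 in male soma, inclusive); g1/g3 dropped (< 1 in both)
  expect_setequal(rownames(kept), c("g2", "g4"))
  expect_equal(S4Vectors::metadata(kept)$expressionFilter$dropped, 2L)
  expect_error(filterExpressed(se, character(), gF), "nonempty")
})

test_that("Wilcoxon rank-sum matches full enumeration", {
  # the canonical small example: all x below all y, n=m=2 -> p = 2/6
  ht <- wilcoxonRankSum(c(1.2, 3.4), c(5.6, 7.8))
  expect_equal(ht$p, 1 / 3, tolerance = 1e-12)
  expect_equal(ht$W, 3)  # ranks 1 + 2
  expect_equal(ht$mode, "exact")
  # identical multisets: p = 1 under the approximation (forced by ties)
  ht2 <- wilcoxonRankSum(c(1, 2, 3), c(3, 2, 1))
  expect_gt(ht2$p, 0.9)
  # random draws vs enumeration oracle, n = m = 5
  set.seed(31)
  for (i in 1:5) {
    x <- round(rnorm(5), 3); y <- round(rnorm(5, 0.5), 3)
    ht <- wilcoxonRankSum(x, y, mode = "exact")
    expect_equal(ht$p, enumWilcoxP(x, y), tolerance = 1e-12)
  }
  # exact matches enumeration for all n + m <= 12 shapes tried
  for (nm in list(c(2, 9), c(4, 6), c(6, 6))) {
    x <- rnorm(nm[1L]); y <- rnorm(nm[2L])
    expect_equal(wilcoxonRankSum(x, y, mode = "exact")$p,
                 enumWilcoxP(x, y), tolerance = 1e-12)
  }
  # normal approximation close to exact for tie-free n = m = 8 (the
  # continuity-corrected normal deviates by up to ~0.01-0.02 mid-range)
  x <- rnorm(8); y <- rnorm(8, 0.8)
  expect_lt(abs(wilcoxonRankSum(x, y, mode = "approx")$p -
                  enumWilcoxP(x, y)), 0.02)
  expect_error(wilcoxonRankSum(numeric(), 1:3), "nonempty")
})

test_that("hypergeometric tails are exact and complementary", {
  # N=10, K=4, n=5: P(X >= 4) = 6/252, P(X <= 0) = 6/252
  expect_equal(hypergeometricTail(4, 4, 5, 10, "upper"), 6 / 252,
               tolerance = 1e-12)
  expect_equal(hypergeometricTail(0, 4, 5, 10, "lower"), 6 / 252,
               tolerance = 1e-12)
  # degenerate all-success draw
  expect_equal(hypergeometricTail(5, 5, 5, 5, "upper"), 1)
  # enumeration oracle over many configurations with N <= 30
  set.seed(17)
  for (i in 1:20) {
    N <- sample(5:30, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    for (k in unique(c(0, max(0, K + n - N), min(n, K)))) {
      expect_equal(hypergeometricTail(k, K, n, N, "upper"),
                   enumHyperTail(k, K, n, N, "upper"), tolerance = 1e-12)
      expect_equal(hypergeometricTail(k, K, n, N, "lower"),
                   enumHyperTail(k, K, n, N, "lower"), tolerance = 1e-12)
      if (k >= 1)
        expect_equal(hypergeometricTail(k, K, n, N, "upper") +
                       hypergeometricTail(k - 1, K, n, N, "lower"), 1,
                     tolerance = 1e-12)
    }
  }
  expect_error(hypergeometricTail(6, 4, 5, 10), "k must")
  expect_error(hypergeometricTail(1, 11, 5, 10), "<= N")
})

test_that("gonad bias calls use a strict fold rule over all other tissues", {
  sheet <- simpleSheet()
  mat <- rbind(ovB = c(4.9, 10, 4.0, 3.0),   # 10 > 2 x 4.9 -> ovary
               edge = c(5.0, 10, 4.0, 3.0),  # 10 = 2 x 5.0 -> unbiased
               tesB = c(30, 2, 14, 1),       # 30 > 2 x 14 -> testis
               zero = c(0, 0, 0, 0),         # vacuously unbiased
               flat = c(5, 5, 5, 5))
  calls <- classifyGonadBias(makeSE(mat, sheet), fold = 2)
  expect_equal(stats::setNames(calls$bias, calls$gene_id),
               c(ovB = "ovary", edge = "unbiased", tesB = "testis",
                 zero = "unbiased", flat = "unbiased"))
  # missing gonad tissue is an error
  noGonad <- sheet[sheet$compartment == "soma", ]
  expect_error(classifyGonadBias(makeSE(mat[, 3:4], noGonad)), "testis|gonad|ovary")
})

test_that("chromosome partitions split the X at the breakpoint", {
  genes <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                      chrom = c("chr2", "chrX", "chrX", "chrY", "chrU"),
                      start = c(100, 100, 900, 10, 5))
  p <- chromPartition(genes, xChrom = "chrX", breakpoint = 500,
                      ancSide = "left", yChroms = "chrY",
                      excludeChroms = "chrU")
  expect_equal(unname(p), c("autosome", "anc-X", "neo-X", "Y", "excluded"))
  p2 <- chromPartition(genes, xChrom = "chrX", breakpoint = 500,
                       ancSide = "right")
  expect_equal(unname(p2[c("b", "c")]), c("neo-X", "anc-X"))
})

test_that("dosage comparison recovers the simulated compensation state", {
  gc <- geneClassesAX(1500, 500)
  for (cfg in list(list(mode = "complete", lo = 0.9, hi = 1.1, sig = FALSE),
                   list(mode = "none", lo = 0.45, hi = 0.55, sig = TRUE))) {
    sim <- simulateExpression(gc, dcMode = cfg$mode, seed = 4)
    filt <- filterExpressed(
      sim$se, selectSamples(sim$se, sex = "M", compartment = "soma"),
      selectSamples(sim$se, sex = "F", compartment = "soma"))
    d <- dosageCompare(filt, gc)
    xr <- d$strata$ratioMF[d$strata$stratum == "ancX"]
    expect_gte(xr, cfg$lo); expect_lte(xr, cfg$hi)
    t <- d$tests
    i <- (t$groupA == "ancX.M" & t$groupB == "autosome.M") |
         (t$groupA == "autosome.M" & t$groupB == "ancX.M")
    expect_equal(t$significant[i], cfg$sig)
  }
})

test_that("identical strata give p ~ 1 and a single letter group", {
  set.seed(5)
  gc <- stats::setNames(rep(c("autosome", "ancX"), each = 200),
                        sprintf("g%03d", 1:400))
  base <- rlnorm(400, 3, 1)
  sheet <- simpleSheet()
  mat <- matrix(rep(base, 4), ncol = 4)
  rownames(mat) <- names(gc)
  se <- makeSE(mat, sheet)
  d <- dosageCompare(se, gc)
  expect_true(all(d$tests$padj > 0.99))
  expect_equal(length(unique(d$letters)), 1L)
})

test_that("proto vs neo comparison reads out dosage compensation", {
  gc <- stats::setNames(rep("neoX", 400), sprintf("n%03d", 1:400))
  out <- stats::setNames(rep("autosome", 400), sprintf("o%03d", 1:400))
  map <- data.frame(focal = names(gc), outgroup = names(out),
                    stringsAsFactors = FALSE)
  for (cfg in list(list(mode = "complete", lo = 0.9, hi = 1.1),
                   list(mode = "none", lo = 0.45, hi = 0.55))) {
    focal <- simulateExpression(gc, dcMode = cfg$mode, fracOvaryBiased = 0,
                                fracTestisBiased = 0, seed = 2)$se
    og <- simulateExpression(out, dcMode = "complete", fracOvaryBiased = 0,
                             fracTestisBiased = 0, seed = 2)$se
    pv <- protoVsNeo(focal, og, map, names(gc))
    male <- pv[pv$sex == "M", ]
    female <- pv[pv$sex == "F", ]
    expect_gte(male$ratio, cfg$lo); expect_lte(male$ratio, cfg$hi)
    expect_gte(female$ratio, 0.9); expect_lte(female$ratio, 1.1)
  }
  # identity: outgroup = focal values -> ratio 1, p ~ 1
  focal <- simulateExpression(gc, seed = 3)$se
  same <- focal; rownames(same) <- names(out)
  pv <- protoVsNeo(focal, same, map, names(gc))
  expect_equal(pv$ratio, c(1, 1))
  expect_true(all(pv$p > 0.99))
})

test_that("bias classifier recall and precision reach 95% on simulations", {
  gc <- geneClassesAX(1500, 500)
  sim <- simulateExpression(gc, fracOvaryBiased = 0.1,
                            fracTestisBiased = 0.1, biasFold = 4,
                            noiseSd = 0.2, seed = 6)
  calls <- classifyGonadBias(sim$se, fold = 2)
  truth <- sim$truth$bias[match(calls$gene_id, sim$truth$gene_id)]
  biased <- truth != "unbiased"
  recall <- mean(calls$bias[biased] == truth[biased])
  called <- calls$bias != "unbiased"
  precision <- mean(calls$bias[called] == truth[called])
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("enrichment tests flag simulated depletion and match the oracle", {
  # toy: N=10 genes, K=4 ovary-biased, stratum of 5 holding 4 of them
  calls <- data.frame(
    gene_id = sprintf("g%02d", 1:10),
    bias = c(rep("ovary", 4), rep("unbiased", 6)),
    stringsAsFactors = FALSE)
  part <- stats::setNames(c(rep("s1", 4), "s1", rep("s2", 5)),
                          calls$gene_id)
  e <- testEnrichment(calls, part, minStratum = 2)
  expect_equal(e$pEnrichment[e$stratum == "s1" & e$bias == "ovary"],
               6 / 252, tolerance = 1e-12)
  # background-proportional stratum -> ns
  calls2 <- data.frame(gene_id = sprintf("g%02d", 1:100),
                       bias = rep(c("ovary", rep("unbiased", 9)), 10),
                       stringsAsFactors = FALSE)
  part2 <- stats::setNames(rep(c("s1", "s2"), each = 50), calls2$gene_id)
  e2 <- testEnrichment(calls2, part2, minStratum = 2)
  expect_true(all(e2$verdict == "ns"))
  # simulated anc-X depleted of testis-biased genes (2% vs 10% background)
  for (s in 1:3) {
    gc <- geneClassesAX(4500, 500)
    sim <- simulateExpression(gc, fracOvaryBiased = 0.1,
                              fracTestisBiased = c(autosome = 0.1,
                                                   ancX = 0.02),
                              biasFold = 4, noiseSd = 0.2, seed = s)
    cb <- classifyGonadBias(sim$se)
    ev <- testEnrichment(cb, gc)
    expect_equal(
      ev$verdict[ev$stratum == "ancX" & ev$bias == "testis"], "depleted")
  }
})

test_that("statistics are invariant to row and column order", {
  gc <- geneClassesAX(300, 100)
  sim <- simulateExpression(gc, seed = 8)
  se <- sim$se
  perm <- sample(nrow(se)); cperm <- sample(ncol(se))
  se2 <- se[perm, cperm]
  d1 <- dosageCompare(se, gc)
  d2 <- dosageCompare(se2, gc)
  expect_equal(d1$strata, d2$strata)
  c1 <- classifyGonadBias(se)
  c2 <- classifyGonadBias(se2)
  expect_equal(c1[order(c1$gene_id), ], c2[order(c2$gene_id), ],
               ignore_attr = TRUE)
})
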