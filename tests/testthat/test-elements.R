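# small hand-built ortholog tables ------------------------------------------

toyTable <- function(chromA, chromB, ids = sprintf("og%03d", seq_along(chromA))) {
  df <- data.frame(ortholog_id = ids,
                   spA.chrom = chromA, spA.pos = seq_along(chromA),
                   spB.chrom = chromB, spB.pos = seq_along(chromB),
                   stringsAsFactors = FALSE)
  attr(df, "species") <- c("spA", "spB")
  df
}

test_that("homology matrices count shared orthologs and drop missing rows", {
  tab <- toyTable(rep("LG1", 100), rep("chr7", 100))
  m <- buildHomologyMatrix(tab, "spA", "spB")
  expect_equal(m["LG1", "chr7"], 100L)
  expect_equal(sum(m), 100L)
  # missing placements are dropped and counted
  tab$spB.chrom[1:10] <- NA
  m2 <- buildHomologyMatrix(tab, "spA", "spB")
  expect_equal(sum(m2), 90L)
  expect_equal(attr(m2, "dropped"), 10L)
  expect_error(buildHomologyMatrix(tab, "spA", "nope"), "nope")
  expect_warning(
    buildHomologyMatrix(toyTable("LG1", NA), "spA", "spB"), "no orthologs")
})

test_that("majority rule assigns elements and leaves split groups out", {
  # 95/100 on one chromosome -> element; cell is 1(chr7)
  tab <- toyTable(rep("LGa", 100), c(rep("chr7", 95), rep("chr2", 5)))
  a <- assignElements(list(spB = buildHomologyMatrix(tab, "spA", "spB")))
  expect_true(assignmentTable(a)$assigned)
  cell <- elementCells(a)$LGa$spB
  expect_equal(cell$chrom, "chr7")
  expect_equal(cell$count, 95L)
  # 50/50 split in every species -> unassigned (tie is not a majority)
  tab2 <- toyTable(rep("LGa", 100), rep(c("c1", "c2"), 50))
  a2 <- assignElements(list(spB = buildHomologyMatrix(tab2, "spA", "spB")))
  expect_false(assignmentTable(a2)$assigned)
  expect_equal(assignmentTable(a2)$element, "-")
})

test_that("composition table formats k(ids) cells and zero rows", {
  # focal LGX (the X), LG1 conserved, LG2 split over 4 chromosomes in spB
  chromA <- c(rep("LGX", 40), rep("LG1", 40), rep("LG2", 80))
  chromB <- c(rep("cx", 40), rep("c1", 40),
              rep(c("c4", "c8", "c15", "c17"), each = 20))
  tab <- toyTable(chromA, chromB)
  a <- assignElements(list(spB = buildHomologyMatrix(tab, "spA", "spB")),
                      minOrthologs = 20, majorityFrac = 0.2)
  comp <- compositionTable(a)
  expect_equal(comp$element[1L], "X")   # X row first
  expect_equal(comp$spB[comp$focalLG == "LGX"], "1(cx)")
  expect_equal(comp$spB[comp$focalLG == "LG2"], "4(c15,c17,c4,c8)")
  # a group failing the majority everywhere gets a dash row of zeros
  chromB2 <- chromB
  chromB2[81:160] <- rep(sprintf("z%d", 1:8), each = 10)  # 10 < minOrthologs
  a2 <- assignElements(list(spB = buildHomologyMatrix(
    toyTable(chromA, chromB2), "spA", "spB")), minOrthologs = 20)
  comp2 <- compositionTable(a2)
  expect_equal(comp2$element[comp2$focalLG == "LG2"], "-")
  expect_equal(comp2$spB[comp2$focalLG == "LG2"], "0")
})

test_that("event counts are star parsimony against the ancestral state", {
  # one chromosome carries X and E, everything else dedicated -> 1 fusion
  chromA <- rep(c("LGX", "LGE", "LGF"), each = 50)
  chromB <- c(rep("fusedXE", 100), rep("c3", 50))
  a <- assignElements(list(spB = buildHomologyMatrix(
    toyTable(chromA, chromB), "spA", "spB")))
  ev <- countEvents(a)
  expect_equal(ev$nFusions, 1L)
  expect_equal(ev$nFissions, 0L)
  # element split over two chromosomes -> 1 fission (uneven split so the
  # larger part still carries a strict majority)
  chromB2 <- c(rep("cx", 50), rep("e1", 30), rep("e2", 20), rep("c3", 50))
  ev2 <- countEvents(assignElements(list(spB = buildHomologyMatrix(
    toyTable(chromA, chromB2), "spA", "spB"))))
  expect_equal(ev2$nFusions, 0L)
  expect_equal(ev2$nFissions, 1L)
  # all dedicated -> (0, 0)
  ev3 <- countEvents(assignElements(list(spB = buildHomologyMatrix(
    toyTable(chromA, rep(c("cx", "c2", "c3"), each = 50)), "spA", "spB"))))
  expect_equal(c(ev3$nFusions, ev3$nFissions), c(0L, 0L))
  expect_error(countEvents(a, "unknownSpecies"), "cover")
})

test_that("simulated histories are recovered exactly from ortholog tables", {
  for (s in 1:3) {
    h <- simulateKaryotypeHistory(TREE5, nElements = 9,
                                  genesPerElement = 200,
                                  fusionRate = 0.35, fissionRate = 0.2,
                                  seed = s)
    ot <- simulateOrthologTable(h, shuffleRate = 0.3, seed = s,
                                includeRoot = TRUE)
    tips <- names(tipMaps(h))
    mats <- lapply(stats::setNames(tips, tips), function(sp)
      buildHomologyMatrix(ot, "ancestor", sp))
    a <- assignElements(mats, focalX = "ancX")
    # every ortholog's inferred element equals its simulated element
    tab <- assignmentTable(a)
    lgToEl <- stats::setNames(tab$element, tab$focalLG)
    inferred <- lgToEl[ot$ancestor.chrom]
    expect_equal(unname(inferred),
                 unname(geneElements(h)[ot$ortholog_id]))
    # composition cells equal ground truth at the same resolution
    ev <- countEvents(a)
    for (tp in tips) {
      tc <- trueComposition(h, tp, minOrthologs = 20)
      for (el in ancestralElements(h)) {
        lg <- tab$focalLG[tab$element == el]
        cell <- elementCells(a)[[lg]][[tp]]
        expect_equal(cell$chrom, tc$cells[[el]]$chrom)
        expect_equal(cell$count, tc$cells[[el]]$count)
      }
      expect_equal(ev$nFusions[ev$species == tp], tc$nFusions)
      expect_equal(ev$nFissions[ev$species == tp], tc$nFissions)
    }
  }
})

test_that("assignment is invariant to species order and chromosome renaming", {
  h <- simulateKaryotypeHistory(TREE5, nElements = 5, genesPerElement = 100,
                                fusionRate = 0.4, fissionRate = 0.2,
                                seed = 12)
  ot <- simulateOrthologTable(h, seed = 1, includeRoot = TRUE)
  tips <- names(tipMaps(h))
  mats <- lapply(stats::setNames(tips, tips), function(sp)
    buildHomologyMatrix(ot, "ancestor", sp))
  a1 <- assignmentTable(assignElements(mats, focalX = "ancX"))
  a2 <- assignmentTable(assignElements(rev(mats), focalX = "ancX"))
  expect_equal(a1, a2)
  # renaming a target species' chromosomes changes ids, not structure
  ot2 <- ot
  ot2$tip1.chrom <- paste0("scaffold_", ot$tip1.chrom)
  mats2 <- mats
  mats2$tip1 <- buildHomologyMatrix(ot2, "ancestor", "tip1")
  a3 <- assignElements(mats2, focalX = "ancX")
  expect_equal(assignmentTable(a3)$element, a1$element)
})

test_that("conserved X orthologs intersect calls across species", {
  tab <- toyTable(c(rep("x1", 4), rep("a1", 4)),
                  c(rep("xb", 2), rep("ab", 4), rep("xb", 2)))
  # spA X = x1, spB X = xb: only the first two orthologs are X in both
  got <- conservedSexOrthologs(tab, list(spA = "x1", spB = "xb"))
  expect_equal(got, sprintf("og%03d", 1:2))
  # disjoint X sets -> empty
  tabDisjoint <- toyTable(c(rep("x1", 4), rep("a1", 4)),
                          c(rep("ab", 4), rep("xb", 4)))
  expect_length(conservedSexOrthologs(
    tabDisjoint, list(spA = "x1", spB = "xb")), 0L)
  expect_error(conservedSexOrthologs(tab, list(spA = "x1")), "2")
  expect_error(conservedSexOrthologs(
    tab, list(spA = "x1", spB = character())), "without")
})

test_that("conserved X orthologs on a clean simulation are the X genes", {
  h <- simulateKaryotypeHistory(TREE5, nElements = 4, genesPerElement = 50,
                                fusionRate = 0, fissionRate = 0, seed = 2)
  ot <- simulateOrthologTable(h, seed = 3)
  xGenes <- names(geneElements(h))[geneElements(h) == "X"]
  calls <- lapply(tipMaps(h), function(m)
    unique(m$chrom[m$element == "X"]))
  expect_setequal(conservedSexOrthologs(ot, calls), xGenes)
})

test_that("mislabeling noise erodes the conserved set at the expected rate", {
  # 5 species, 5% per-species false X->autosome loss: retention ~ 0.95^5
  set.seed(11)
  nX <- 400
  ids <- sprintf("x%03d", 1:nX)
  tab <- data.frame(ortholog_id = ids, stringsAsFactors = FALSE)
  for (sp in sprintf("sp%d", 1:5)) {
    lost <- runif(nX) < 0.05
    tab[[paste0(sp, ".chrom")]] <- ifelse(lost, "auto", "chrX")
    tab[[paste0(sp, ".pos")]] <- seq_len(nX)
  }
  attr(tab, "species") <- sprintf("sp%d", 1:5)
  calls <- stats::setNames(rep(list("chrX"), 5), sprintf("sp%d", 1:5))
  kept <- length(conservedSexOrthologs(tab, calls))
  p <- 0.95^5
  ci <- qbinom(c(0.0005, 0.9995), nX, p)
  expect_gte(kept, ci[1L])
  expect_lte(kept, ci[2L])
})

test_that("neo-sex elements are detected from X calls", {
  h <- simulateKaryotypeHistory(TREE5, nElements = 4, genesPerElement = 50,
                                fusionRate = 0, fissionRate = 0, seed = 2)
  # force an X-B fusion on tip1's branch (an added neo-X element)
  ev <- list("n7->tip1" = list(list(
    type = "fusion", chroms = c("ancX", "ancB"),
    flip = c(FALSE, FALSE), newChrom = "fusXB")))
  hf <- KaryotypeHistory(h@tree, h@rootKaryotype, h@geneElement,
                         h@elements, events = ev)
  ot <- simulateOrthologTable(hf, seed = 4, includeRoot = TRUE)
  tips <- names(tipMaps(hf))
  a <- assignElements(lapply(stats::setNames(tips, tips), function(sp)
    buildHomologyMatrix(ot, "ancestor", sp)), focalX = "ancX")
  # the fused chromosome is chr1 at tip1 (largest); X-called
  neo <- detectNeoSexElements(a, "chr1", "tip1")
  expect_setequal(neo$element, c("X", "B"))
  expect_equal(neo$component[neo$element == "X"], "ancestral-X")
  expect_equal(neo$component[neo$element == "B"], "neo")
  # a tip without the fusion has only the ancestral X sex-linked
  xChrom <- unique(tipKaryotype(hf, "tip2")$chrom[
    tipKaryotype(hf, "tip2")$element == "X"])
  neo2 <- detectNeoSexElements(a, xChrom, "tip2")
  expect_equal(neo2$element, "X")
})
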