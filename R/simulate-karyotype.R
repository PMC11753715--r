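#' Simulate chromosome fusion/fission history along a species tree
#'
#' Starting from an ancestral karyotype with one chromosome per ancestral
#' element, draws fusion and fission events independently on every branch of
#' a rooted tree (counts Poisson with mean `rate * branch length`) and
#' replays them root-to-tip. Fusions join two uniformly chosen chromosomes
#' end-to-end with uniform orientation of each partner; fissions split a
#' uniformly chosen multi-gene chromosome at a uniform internal gene
#' boundary. Gene content is conserved along every lineage and every gene
#' keeps its element label, so tips differ only in how elements are packaged
#' into chromosomes -- the regime under which ancestral linkage groups are
#' recoverable from 1:1 ortholog placements.
#'
#' Infeasible events (fusion with a single chromosome left, fission when all
#' chromosomes are single-gene) are skipped and logged, not fatal.
#'
#' @param tree newick text, a path is not accepted -- pass the string -- or a
#'   `phylo` object. Must be rooted with >= 2 tips and positive branch
#'   lengths.
#' @param nElements number of ancestral elements (chromosomes) at the root;
#'   labelled `X`, `A`, `B`, ... (max 27).
#' @param genesPerElement genes per ancestral element.
#' @param fusionRate,fissionRate expected events per unit branch length
#'   (>= 0).
#' @param seed integer seed; identical inputs and seed give byte-identical
#'   histories.
#' @return a [KaryotypeHistory-class] object.
#' @examples
#' h <- simulateKaryotypeHistory("((A:1,B:1):1,C:2);", nElements = 3,
#'                               genesPerElement = 10, fusionRate = 0.5,
#'                               fissionRate = 0.2, seed = 1)
#' tipKaryotype(h, "A")[1:3, ]
#' @export
simulateKaryotypeHistory <- function(tree, nElements = 9,
                                     genesPerElement = 200,
                                     fusionRate = 0, fissionRate = 0,
                                     seed = 1L) {
  phy <- .asPhylo(tree)
  if (length(phy$tip.label) < 2L)
    stop("tree must have at least 2 tips")
  if (is.null(phy$edge.length) || any(phy$edge.length <= 0))
    stop("tree must have positive branch lengths")
  if (fusionRate < 0 || fissionRate < 0)
    stop("rates must be >= 0")
  if (nElements < 1L || nElements > 27L)
    stop("nElements must be between 1 and 27")
  if (genesPerElement < 1L)
    stop("genesPerElement must be >= 1")
  if (any(grepl(".", phy$tip.label, fixed = TRUE)))
    stop("tip labels must not contain '.'")

  set.seed(as.integer(seed))
  elements <- c("X", LETTERS)[seq_len(nElements)]
  rootKar <- lapply(elements, function(el)
    sprintf("%s%04d", el, seq_len(genesPerElement)))
  names(rootKar) <- paste0("anc", elements)
  geneElement <- rep(elements, each = genesPerElement)
  names(geneElement) <- unlist(rootKar, use.names = FALSE)

  # draw events edge by edge in preorder
  phy <- stats::reorder(phy, "cladewise")
  counter <- 0L
  events <- vector("list", nrow(phy$edge))
  log <- character()
  kar <- vector("list", max(phy$edge))
  root <- length(phy$tip.label) + 1L
  kar[[root]] <- rootKar
  edgeNames <- character(nrow(phy$edge))
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; ch <- phy$edge[i, 2L]
    len <- phy$edge.length[i]
    nFus <- stats::rpois(1L, fusionRate * len)
    nFis <- stats::rpois(1L, fissionRate * len)
    types <- c(rep("fusion", nFus), rep("fission", nFis))
    if (length(types) > 1L) types <- sample(types)
    k <- kar[[p]]
    ev <- list()
    for (ty in types) {
      if (ty == "fusion") {
        if (length(k) < 2L) {
          log <- c(log, sprintf("%s: fusion skipped (single chromosome)",
                                .nodeLabel(phy, ch)))
          next
        }
        pair <- sample(names(k), 2L)
        flip <- sample(c(TRUE, FALSE), 2L, replace = TRUE)
        counter <- counter + 1L
        e <- list(type = "fusion", chroms = pair, flip = flip,
                  newChrom = sprintf("fus%04d", counter))
        k <- .applyEvent(k, e)
        ev[[length(ev) + 1L]] <- e
      } else {
        big <- names(k)[lengths(k) >= 2L]
        if (!length(big)) {
          log <- c(log, sprintf("%s: fission skipped (all single-gene)",
                                .nodeLabel(phy, ch)))
          next
        }
        chrom <- if (length(big) == 1L) big else sample(big, 1L)
        counter <- counter + 1L
        e <- list(type = "fission", chrom = chrom,
                  breakAfter = sample.int(length(k[[chrom]]) - 1L, 1L),
                  newChroms = sprintf("fis%04d%s", counter, c("a", "b")))
        k <- .applyEvent(k, e)
        ev[[length(ev) + 1L]] <- e
      }
    }
    kar[[ch]] <- k
    events[[i]] <- ev
    edgeNames[i] <- paste0(.nodeLabel(phy, p), "->", .nodeLabel(phy, ch))
  }
  names(events) <- edgeNames

  KaryotypeHistory(phy, rootKar, geneElement, elements, events,
                   eventLog = log,
                   params = list(nElements = nElements,
                                 genesPerElement = genesPerElement,
                                 fusionRate = fusionRate,
                                 fissionRate = fissionRate,
                                 seed = as.integer(seed)))
}

#' Construct a KaryotypeHistory from explicit events
#'
#' Low-level constructor: replays a given per-edge event list from an
#' ancestral karyotype to obtain the tip chromosome maps. Used internally by
#' [simulateKaryotypeHistory()] and directly when a specific history (e.g. a
#' single forced fusion on one branch) is needed.
#'
#' @param tree a `phylo` object or newick text.
#' @param rootKaryotype named list: ancestral chromosome -> ordered gene ids.
#' @param geneElement named character gene id -> element label.
#' @param elements ordered element labels.
#' @param events named list (`"parent->child"`) of event lists; each event is
#'   `list(type = "fusion", chroms, flip, newChrom)` or
#'   `list(type = "fission", chrom, breakAfter, newChroms)`. Edges without an
#'   entry carry no events.
#' @param eventLog,params optional metadata.
#' @return a [KaryotypeHistory-class] object.
#' @export
KaryotypeHistory <- function(tree, rootKaryotype, geneElement, elements,
                             events = list(), eventLog = character(),
                             params = list()) {
  phy <- stats::reorder(.asPhylo(tree), "cladewise")
  tipMaps <- .replayEvents(phy, rootKaryotype, geneElement, events)
  new("KaryotypeHistory", tree = phy, elements = elements,
      geneElement = geneElement, rootKaryotype = rootKaryotype,
      events = events, tipMaps = tipMaps, eventLog = eventLog,
      params = params)
}

#' Replay the recorded events of a history
#'
#' Re-derives every tip chromosome map from the root karyotype and the
#' per-branch event records. By construction this must reproduce
#' `tipMaps(x)` exactly; exposed so that the determinism/conservation
#' invariants can be checked from outside.
#'
#' @param x a [KaryotypeHistory-class] object.
#' @return named list of tip data.frames, as [tipMaps()].
#' @export
replayKaryotype <- function(x) {
  stopifnot(is(x, "KaryotypeHistory"))
  .replayEvents(x@tree, x@rootKaryotype, x@geneElement, x@events)
}

.asPhylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (!is.character(tree) || length(tree) != 1L)
    stop("tree must be a phylo object or newick text")
  phy <- tryCatch(ape::read.tree(text = tree), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("malformed newick tree")
  phy
}

.nodeLabel <- function(phy, id) {
  nt <- length(phy$tip.label)
  if (id <= nt) return(phy$tip.label[id])
  lbl <- phy$node.label[id - nt]
  if (!is.null(lbl) && !is.na(lbl) && nzchar(lbl)) lbl else paste0("n", id)
}

.applyEvent <- function(kar, e) {
  if (e$type == "fusion") {
    a <- kar[[e$chroms[1L]]]; b <- kar[[e$chroms[2L]]]
    if (e$flip[1L]) a <- rev(a)
    if (e$flip[2L]) b <- rev(b)
    kar[e$chroms] <- NULL
    kar[[e$newChrom]] <- c(a, b)
  } else if (e$type == "fission") {
    g <- kar[[e$chrom]]
    kar[[e$chrom]] <- NULL
    kar[[e$newChroms[1L]]] <- g[seq_len(e$breakAfter)]
    kar[[e$newChroms[2L]]] <- g[(e$breakAfter + 1L):length(g)]
  } else stop("unknown event type: ", e$type)
  kar
}

.replayEvents <- function(phy, rootKar, geneElement, events) {
  phy <- stats::reorder(phy, "cladewise")
  kar <- vector("list", max(phy$edge))
  root <- length(phy$tip.label) + 1L
  kar[[root]] <- rootKar
  tipMaps <- list()
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; ch <- phy$edge[i, 2L]
    key <- paste0(.nodeLabel(phy, p), "->", .nodeLabel(phy, ch))
    k <- kar[[p]]
    for (e in if (is.null(events[[key]])) list() else events[[key]])
      k <- .applyEvent(k, e)
    kar[[ch]] <- k
    if (ch <= length(phy$tip.label))
      tipMaps[[phy$tip.label[ch]]] <- .tipMap(k, geneElement)
  }
  tipMaps[phy$tip.label]
}

# Relabel a karyotype's chromosomes chr1..chrN (largest first, ties by first
# gene id) and lay genes out as ordinal positions.
.tipMap <- function(kar, geneElement) {
  first <- vapply(kar, `[`, "", 1L)
  o <- order(-lengths(kar), first)
  kar <- kar[o]
  names(kar) <- paste0("chr", seq_along(kar))
  df <- data.frame(
    chrom = rep(names(kar), lengths(kar)),
    position = unlist(lapply(lengths(kar), seq_len), use.names = FALSE),
    gene_id = unlist(kar, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  df$element <- unname(geneElement[df$gene_id])
  df
}
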