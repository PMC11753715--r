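#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<-
NULL

setOldClass("phylo")

#' KaryotypeHistory: a simulated history of fusions and fissions
#'
#' Records the ancestral karyotype (one chromosome per ancestral linkage
#' group, or "element"), the fusion/fission events drawn on every branch of a
#' rooted species tree, and the resulting chromosome maps at each tip. Gene
#' content is conserved: every gene exists at every tip and carries exactly
#' one immutable element label, so the true gene-to-element map is always
#' available as ground truth for downstream inference.
#'
#' @slot tree rooted `phylo` with branch lengths in expected-event units.
#' @slot elements ordered element labels (ancestral X first, then A, B, ...).
#' @slot geneElement named character: gene id -> element label.
#' @slot rootKaryotype named list: ancestral chromosome -> ordered gene ids.
#' @slot events named list (one entry per edge, `"parent->child"`), each a
#'   list of fusion/fission event records with all sampled parameters, so the
#'   history can be replayed deterministically.
#' @slot tipMaps named list of data.frames (`chrom`, `position`, `gene_id`,
#'   `element`) giving the realized karyotype at each tip.
#' @slot eventLog character vector of skipped (infeasible) events.
#' @slot params list of the simulation parameters used.
#'
#' @exportClass KaryotypeHistory
setClass("KaryotypeHistory",
  representation(
    tree = "phylo",
    elements = "character",
    geneElement = "character",
    rootKaryotype = "list",
    events = "list",
    tipMaps = "list",
    eventLog = "character",
    params = "list"
  )
)

setValidity("KaryotypeHistory", function(object) {
  msg <- character()
  tips <- object@tree$tip.label
  if (!setequal(names(object@tipMaps), tips))
    msg <- c(msg, "tipMaps must be named by the tree's tip labels")
  allGenes <- sort(names(object@geneElement))
  for (tp in names(object@tipMaps)) {
    m <- object@tipMaps[[tp]]
    if (!setequal(m$gene_id, allGenes))
      msg <- c(msg, sprintf("tip '%s' does not conserve the gene set", tp))
    if (!all(m$element == unname(object@geneElement[m$gene_id])))
      msg <- c(msg, sprintf("tip '%s' has mutated element labels", tp))
  }
  if (!all(object@geneElement %in% object@elements))
    msg <- c(msg, "geneElement contains labels outside 'elements'")
  if (length(msg)) msg else TRUE
})

#' FMRatioTable: normalized female/male coverage ratios
#'
#' Per-window normalized female and male depths and their ratio, plus
#' per-scaffold median-of-window ratios -- the substrate for sex-linkage
#' classification. Windows whose normalized male depth falls below the floor
#' are flagged (candidate female-specific sequence) and excluded from
#' scaffold medians rather than ratio'd.
#'
#' @slot windows `GRanges` tiling with metadata columns `depthF`, `depthM`,
#'   `normF`, `normM`, `ratio`, `log2ratio`, `flagged`.
#' @slot scaffolds data.frame: `scaffold`, `medianRatio`, `nWindows`
#'   (informative windows), `nFlagged`.
#' @slot normConst named numeric, the per-sample normalization constants
#'   (`F`, `M`).
#' @slot normalization `"genome_median"` or `"autosomal_median"`.
#' @slot minMDepth normalized male depth floor below which a window is
#'   flagged.
#'
#' @exportClass FMRatioTable
setClass("FMRatioTable",
  representation(
    windows = "GRanges",
    scaffolds = "data.frame",
    normConst = "numeric",
    normalization = "character",
    minMDepth = "numeric"
  )
)

setValidity("FMRatioTable", function(object) {
  msg <- character()
  need <- c("normF", "normM", "ratio", "log2ratio", "flagged")
  if (!all(need %in% colnames(mcols(object@windows))))
    msg <- c(msg, "windows must carry normF/normM/ratio/log2ratio/flagged")
  r <- object@windows$ratio
  if (any(r < 0, na.rm = TRUE)) msg <- c(msg, "ratios must be >= 0")
  if (!setequal(names(object@normConst), c("F", "M")))
    msg <- c(msg, "normConst must be named F and M")
  if (length(msg)) msg else TRUE
})

#' ElementAssignment: ancestral elements anchored on a focal species
#'
#' The result of majority-rule assignment of focal linkage groups to
#' ancestral elements from cross-species 1:1 ortholog placements, together
#' with the per-species chromosome lists ("cells") that make up the
#' composition table.
#'
#' @slot focal focal species name.
#' @slot table data.frame, one row per focal linkage group: `focalLG`,
#'   `element` (label or `"-"`), `assigned`, `nPlaced` (orthologs placed in
#'   at least one target).
#' @slot cells nested list: `cells[[focalLG]][[species]]` is a data.frame
#'   (`chrom`, `count`) of target chromosomes carrying at least
#'   `minOrthologs` orthologs of the element.
#' @slot matrices the homology count matrices the assignment was computed
#'   from, keyed by target species.
#' @slot species target species names.
#' @slot params list: `minOrthologs`, `majorityFrac`.
#'
#' @exportClass ElementAssignment
setClass("ElementAssignment",
  representation(
    focal = "character",
    table = "data.frame",
    cells = "list",
    matrices = "list",
    species = "character",
    params = "list"
  )
)

setValidity("ElementAssignment", function(object) {
  msg <- character()
  tab <- object@table
  if (!all(c("focalLG", "element", "assigned", "nPlaced") %in% names(tab)))
    msg <- c(msg, "table must have focalLG/element/assigned/nPlaced")
  if (anyDuplicated(tab$element[tab$assigned]))
    msg <- c(msg, "assigned element labels must be unique")
  if (!all(names(object@cells) %in% tab$focalLG))
    msg <- c(msg, "cells must be keyed by focal linkage groups")
  if (length(msg)) msg else TRUE
})
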