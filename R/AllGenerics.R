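#' Accessors for KaryotypeHistory
#'
#' @param x a [KaryotypeHistory-class] object.
#' @param tip a tip label.
#' @return `tipMaps` returns the named list of per-tip chromosome maps;
#'   `tipKaryotype` one tip's map (data.frame `chrom`, `position`,
#'   `gene_id`, `element`); `geneElements` the named gene -> element vector;
#'   `ancestralElements` the element labels; `historyEvents` the per-branch
#'   event lists; `eventLog` the log of skipped events.
#' @name KaryotypeHistory-accessors
NULL

#' @rdname KaryotypeHistory-accessors
#' @export
setGeneric("tipMaps", function(x) standardGeneric("tipMaps"))
#' @rdname KaryotypeHistory-accessors
#' @export
setMethod("tipMaps", "KaryotypeHistory", function(x) x@tipMaps)

#' @rdname KaryotypeHistory-accessors
#' @export
setGeneric("tipKaryotype", function(x, tip) standardGeneric("tipKaryotype"))
#' @rdname KaryotypeHistory-accessors
#' @export
setMethod("tipKaryotype", "KaryotypeHistory", function(x, tip) {
  if (!tip %in% names(x@tipMaps))
    stop("unknown tip: ", tip)
  x@tipMaps[[tip]]
})

#' @rdname KaryotypeHistory-accessors
#' @export
setGeneric("geneElements", function(x) standardGeneric("geneElements"))
#' @rdname KaryotypeHistory-accessors
#' @export
setMethod("geneElements", "KaryotypeHistory", function(x) x@geneElement)

#' @rdname KaryotypeHistory-accessors
#' @export
setGeneric("ancestralElements",
           function(x) standardGeneric("ancestralElements"))
#' @rdname KaryotypeHistory-accessors
#' @export
setMethod("ancestralElements", "KaryotypeHistory", function(x) x@elements)

#' @rdname KaryotypeHistory-accessors
#' @export
setGeneric("historyEvents", function(x) standardGeneric("historyEvents"))
#' @rdname KaryotypeHistory-accessors
#' @export
setMethod("historyEvents", "KaryotypeHistory", function(x) x@events)

#' @rdname KaryotypeHistory-accessors
#' @export
setGeneric("eventLog", function(x) standardGeneric("eventLog"))
#' @rdname KaryotypeHistory-accessors
#' @export
setMethod("eventLog", "KaryotypeHistory", function(x) x@eventLog)

setMethod("show", "KaryotypeHistory", function(object) {
  nev <- sum(lengths(object@events))
  cat("KaryotypeHistory\n",
      "  ", length(object@tree$tip.label), " tips, ",
      length(object@elements), " ancestral elements (",
      paste(object@elements, collapse = ", "), ")\n",
      "  ", length(object@geneElement), " genes, ",
      nev, " events (", length(object@eventLog), " skipped)\n",
      "  chromosomes per tip: ",
      paste(sprintf("%s=%d", names(object@tipMaps),
                    vapply(object@tipMaps,
                           function(m) length(unique(m$chrom)), 1L)),
            collapse = ", "), "\n", sep = "")
})

#' Accessors for FMRatioTable
#'
#' @param x an [FMRatioTable-class] object.
#' @return `ratioWindows` the window-level `GRanges`; `scaffoldRatios` the
#'   per-scaffold summary data.frame; `normConstants` the named F/M
#'   normalization constants.
#' @name FMRatioTable-accessors
NULL

#' @rdname FMRatioTable-accessors
#' @export
setGeneric("ratioWindows", function(x) standardGeneric("ratioWindows"))
#' @rdname FMRatioTable-accessors
#' @export
setMethod("ratioWindows", "FMRatioTable", function(x) x@windows)

#' @rdname FMRatioTable-accessors
#' @export
setGeneric("scaffoldRatios", function(x) standardGeneric("scaffoldRatios"))
#' @rdname FMRatioTable-accessors
#' @export
setMethod("scaffoldRatios", "FMRatioTable", function(x) x@scaffolds)

#' @rdname FMRatioTable-accessors
#' @export
setGeneric("normConstants", function(x) standardGeneric("normConstants"))
#' @rdname FMRatioTable-accessors
#' @export
setMethod("normConstants", "FMRatioTable", function(x) x@normConst)

setMethod("show", "FMRatioTable", function(object) {
  cat("FMRatioTable (", object@normalization, " normalization)\n",
      "  ", length(object@windows), " windows on ",
      nrow(object@scaffolds), " scaffolds; ",
      sum(object@windows$flagged), " flagged (normM < ",
      object@minMDepth, ")\n",
      "  normalization constants: F=", round(object@normConst["F"], 3),
      " M=", round(object@normConst["M"], 3), "\n", sep = "")
})

#' Accessors for ElementAssignment
#'
#' @param x an [ElementAssignment-class] object.
#' @return `assignmentTable` the per-linkage-group assignment data.frame;
#'   `elementCells` the nested per-species chromosome lists;
#'   `homologyMatrices` the underlying count matrices.
#' @name ElementAssignment-accessors
NULL

#' @rdname ElementAssignment-accessors
#' @export
setGeneric("assignmentTable", function(x) standardGeneric("assignmentTable"))
#' @rdname ElementAssignment-accessors
#' @export
setMethod("assignmentTable", "ElementAssignment", function(x) x@table)

#' @rdname ElementAssignment-accessors
#' @export
setGeneric("elementCells", function(x) standardGeneric("elementCells"))
#' @rdname ElementAssignment-accessors
#' @export
setMethod("elementCells", "ElementAssignment", function(x) x@cells)

#' @rdname ElementAssignment-accessors
#' @export
setGeneric("homologyMatrices",
           function(x) standardGeneric("homologyMatrices"))
#' @rdname ElementAssignment-accessors
#' @export
setMethod("homologyMatrices", "ElementAssignment", function(x) x@matrices)

setMethod("show", "ElementAssignment", function(object) {
  tab <- object@table
  cat("ElementAssignment (focal: ",
      if (nzchar(object@focal)) object@focal else "<unnamed>", ")\n",
      "  ", nrow(tab), " focal linkage groups, ",
      sum(tab$assigned), " assigned to elements (",
      paste(tab$element[tab$assigned], collapse = ", "), ")\n",
      "  target species: ", paste(object@species, collapse = ", "),
      "\n", sep = "")
})
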