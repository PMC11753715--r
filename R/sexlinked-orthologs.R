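#' Orthologs X-linked in every listed species
#'
#' Intersects per-species sex-linkage calls over a 1:1 ortholog table: an
#' ortholog is conserved X-linked if it sits on an X-called
#' chromosome/scaffold in ALL listed species.
#'
#' @param table ortholog table.
#' @param xCalls named list, one entry per species: either a character
#'   vector of X-linked chromosome ids, or a [classifyScaffolds()]
#'   data.frame (rows with `class == "X_linked"` are used).
#' @return character vector of ortholog ids.
#' @export
conservedSexOrthologs <- function(table, xCalls) {
  if (length(xCalls) < 2L || is.null(names(xCalls)))
    stop("need X calls for at least 2 named species")
  keep <- rep(TRUE, nrow(table))
  for (sp in names(xCalls)) {
    calls <- xCalls[[sp]]
    if (is.data.frame(calls))
      calls <- calls$scaffold[calls$class == "X_linked"]
    if (!length(calls))
      stop("species without X calls: ", sp)
    chrom <- .orthoCol(table, sp, "chrom")
    keep <- keep & !is.na(chrom) & chrom %in% calls
  }
  table$ortholog_id[keep]
}

#' Which ancestral elements are sex-linked in a species
#'
#' Projects coverage-based X-linkage calls for one species onto the
#' element assignment: every element with at least `minOrthologs` orthologs
#' on X-called chromosomes is reported, split into the ancestral-X element
#' and autosome-derived (neo) elements. A species whose X calls hit only
#' element X has the ancestral karyotype; extra elements reveal neo-sex
#' fusions (one added element for a simple fusion, two when the fused arm
#' was itself a fusion product of two ancestral autosomes).
#'
#' @param assignment an [ElementAssignment-class] object.
#' @param xChroms X-linked chromosomes of `species`: a character vector or
#'   a [classifyScaffolds()] data.frame.
#' @param species target species the calls belong to.
#' @param minOrthologs minimum X-linked orthologs for an element to be
#'   reported; default the assignment's own threshold.
#' @return data.frame: `focalLG`, `element`, `nXLinked`, `component`
#'   (`"ancestral-X"` or `"neo"`).
#' @export
detectNeoSexElements <- function(assignment, xChroms, species,
                                 minOrthologs = NULL) {
  stopifnot(is(assignment, "ElementAssignment"))
  if (!species %in% assignment@species)
    stop("assignment does not cover species ", species)
  if (is.data.frame(xChroms))
    xChroms <- xChroms$scaffold[xChroms$class == "X_linked"]
  if (is.null(minOrthologs))
    minOrthologs <- assignment@params$minOrthologs
  m <- assignment@matrices[[species]]
  tab <- assignment@table
  res <- lapply(which(tab$assigned), function(i) {
    lg <- tab$focalLG[i]
    if (!lg %in% rownames(m)) return(NULL)
    nX <- sum(m[lg, intersect(colnames(m), xChroms)])
    if (nX < minOrthologs) return(NULL)
    data.frame(focalLG = lg, element = tab$element[i], nXLinked = nX,
               component = if (tab$element[i] == "X") "ancestral-X"
                           else "neo",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(focalLG = character(), element = character(),
                      nXLinked = integer(), component = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
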