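#' Shared-ortholog counts between two species' chromosomes
#'
#' Cross-tabulates 1:1 ortholog placements: entry `[i, j]` is the number of
#' orthologs on focal chromosome `i` that land on target chromosome `j`.
#' Rows missing a placement in either species are dropped and counted in
#' `attr(, "dropped")`.
#'
#' @param table ortholog table as from [simulateOrthologTable()] /
#'   [readOrthologTable()].
#' @param focal,target species names.
#' @return integer matrix (focal chromosomes x target chromosomes) with
#'   attributes `focal`, `target`, `dropped`.
#' @export
buildHomologyMatrix <- function(table, focal, target) {
  f <- .orthoCol(table, focal, "chrom")
  t <- .orthoCol(table, target, "chrom")
  keep <- !is.na(f) & !is.na(t)
  m <- unclass(table(factor(f[keep]), factor(t[keep])))
  storage.mode(m) <- "integer"
  names(dimnames(m)) <- NULL
  if (sum(m) == 0)
    warning("no orthologs placed in both ", focal, " and ", target)
  attr(m, "focal") <- focal
  attr(m, "target") <- target
  attr(m, "dropped") <- sum(!keep)
  m
}

#' Assign focal linkage groups to ancestral elements
#'
#' A focal linkage group is called an ancestral element if, in at least one
#' target species, strictly more than `majorityFrac` of its placed
#' orthologs (and at least `minOrthologs` of them) fall on a single target
#' chromosome -- the majority rule under which conserved linkage groups are
#' recognizable across species despite fusions and fissions. Groups that
#' fail everywhere (orthologs scattered across many chromosomes in every
#' species) stay unassigned. Labels: the focal X-bearing group gets `X`,
#' the remaining assigned groups `A`, `B`, ... in focal order.
#'
#' For every element and target species the "cells" record each target
#' chromosome carrying at least `minOrthologs` of the element, with counts;
#' these are the `k(chrom, ...)` entries of the composition table.
#'
#' @param matrices named list of homology matrices (one per target species,
#'   from [buildHomologyMatrix()], all sharing the focal species).
#' @param minOrthologs minimum orthologs for a chromosome to count as
#'   carrying an element (and for the majority winner).
#' @param majorityFrac majority fraction (strict; a tie at exactly this
#'   fraction leaves the group unassigned).
#' @param focalX focal linkage group carrying the ancestral X, if known;
#'   by default any single group whose name contains "X".
#' @return an [ElementAssignment-class] object.
#' @export
assignElements <- function(matrices, minOrthologs = 20,
                           majorityFrac = 0.5, focalX = NULL) {
  if (!length(matrices) || is.null(names(matrices)))
    stop("need a named list of homology matrices (>= 1 target species)")
  lgs <- sort(unique(unlist(lapply(matrices, rownames))))
  species <- names(matrices)

  assigned <- logical(length(lgs))
  nPlaced <- integer(length(lgs))
  for (i in seq_along(lgs)) {
    lg <- lgs[i]
    placedAny <- 0L
    for (m in matrices) {
      if (!lg %in% rownames(m)) next
      row <- m[lg, ]
      placed <- sum(row)
      placedAny <- max(placedAny, placed)
      if (placed > 0 && max(row) >= minOrthologs &&
          max(row) / placed > majorityFrac)
        assigned[i] <- TRUE
    }
    nPlaced[i] <- placedAny
  }

  if (is.null(focalX)) {
    hit <- grep("X", lgs, ignore.case = TRUE, value = TRUE)
    focalX <- if (length(hit) == 1L) hit else NA_character_
  }
  labels <- rep("-", length(lgs))
  letterPool <- LETTERS
  nxt <- 1L
  ord <- order(!(lgs %in% focalX), lgs)  # X-bearing group first, then focal order
  for (i in ord) {
    if (!assigned[i]) next
    if (!is.na(focalX) && lgs[i] == focalX) {
      labels[i] <- "X"
    } else {
      labels[i] <- letterPool[nxt]
      nxt <- nxt + 1L
    }
  }

  cells <- list()
  for (i in which(assigned)) {
    lg <- lgs[i]
    percell <- lapply(matrices, function(m) {
      if (!lg %in% rownames(m))
        return(data.frame(chrom = character(), count = integer(),
                          stringsAsFactors = FALSE))
      row <- m[lg, ]
      keep <- row >= minOrthologs
      d <- data.frame(chrom = colnames(m)[keep],
                      count = as.integer(row[keep]),
                      stringsAsFactors = FALSE)
      d[order(-d$count, d$chrom), , drop = FALSE]
    })
    cells[[lg]] <- percell
  }

  tab <- data.frame(focalLG = lgs, element = labels, assigned = assigned,
                    nPlaced = nPlaced, stringsAsFactors = FALSE)
  new("ElementAssignment",
      focal = attr(matrices[[1L]], "focal") %||% "",
      table = tab, cells = cells, matrices = matrices,
      species = species,
      params = list(minOrthologs = minOrthologs,
                    majorityFrac = majorityFrac))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Element composition table across species
#'
#' The per-species breakdown of every focal linkage group: each cell is
#' `k(chrom1,chrom2,...)` -- the number of target chromosomes carrying the
#' element (at the assignment's `minOrthologs` resolution) and their ids.
#' Unassigned groups get a `-` element label and `0` cells.
#'
#' @param assignment an [ElementAssignment-class] object.
#' @return data.frame with columns `focalLG`, `element`, then one column
#'   per target species; the numeric chromosome counts are in
#'   `attr(, "counts")` (matrix, same row order).
#' @export
compositionTable <- function(assignment) {
  stopifnot(is(assignment, "ElementAssignment"))
  tab <- assignment@table
  if (!nrow(tab)) stop("empty assignment")
  ord <- order(tab$element == "-",                 # assigned first
               tab$element != "X",                 # X row on top
               tab$element)
  tab <- tab[ord, ]
  species <- assignment@species
  out <- data.frame(focalLG = tab$focalLG, element = tab$element,
                    stringsAsFactors = FALSE)
  counts <- matrix(0L, nrow(tab), length(species),
                   dimnames = list(tab$focalLG, species))
  for (sp in species) {
    cellStr <- character(nrow(tab))
    for (r in seq_len(nrow(tab))) {
      lg <- tab$focalLG[r]
      cell <- assignment@cells[[lg]][[sp]]
      if (is.null(cell) || !nrow(cell)) {
        cellStr[r] <- "0"
      } else {
        cellStr[r] <- sprintf("%d(%s)", nrow(cell),
                              paste(cell$chrom, collapse = ","))
        counts[r, sp] <- nrow(cell)
      }
    }
    out[[sp]] <- cellStr
  }
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  out
}

#' Count fusions and fissions against the ancestral karyotype
#'
#' Star parsimony relative to the one-chromosome-per-element ancestor,
#' ignoring event order: each extra chromosome carrying an element is one
#' fission; each extra element sharing a chromosome is one fusion. Counts
#' use the assignment's cells, i.e. chromosomes carrying at least
#' `minOrthologs` orthologs of an element.
#'
#' @param assignment an [ElementAssignment-class] object.
#' @param species target species name(s); default all.
#' @return data.frame: `species`, `nFusions`, `nFissions`.
#' @export
countEvents <- function(assignment, species = NULL) {
  stopifnot(is(assignment, "ElementAssignment"))
  if (is.null(species)) species <- assignment@species
  bad <- setdiff(species, assignment@species)
  if (length(bad))
    stop("assignment does not cover: ", paste(bad, collapse = ", "))
  do.call(rbind, lapply(species, function(sp) {
    chromElems <- list()
    nFis <- 0L
    for (lg in names(assignment@cells)) {
      cell <- assignment@cells[[lg]][[sp]]
      if (is.null(cell) || !nrow(cell)) next
      nFis <- nFis + nrow(cell) - 1L
      for (ch in cell$chrom)
        chromElems[[ch]] <- c(chromElems[[ch]], lg)
    }
    nFus <- sum(pmax(lengths(chromElems) - 1L, 0L))
    data.frame(species = sp, nFusions = nFus, nFissions = nFis,
               stringsAsFactors = FALSE)
  }))
}

#' Ground-truth composition and events from a simulated history
#'
#' Computes, directly from a tip's true chromosome map, which chromosomes
#' carry each ancestral element at the same `minOrthologs` reporting
#' resolution the inference uses -- the truth an ortholog-based assignment
#' should recover exactly when there is no translocation between elements.
#'
#' @param history a [KaryotypeHistory-class] object.
#' @param tip tip label.
#' @param minOrthologs reporting threshold, matched to the assignment's.
#' @return list: `cells` (per element, data.frame `chrom`, `count`),
#'   `nFusions`, `nFissions` (star parsimony on the true map).
#' @export
trueComposition <- function(history, tip, minOrthologs = 20) {
  m <- tipKaryotype(history, tip)
  cells <- list()
  chromElems <- list()
  nFis <- 0L
  for (el in history@elements) {
    cnt <- table(m$chrom[m$element == el])
    cnt <- cnt[cnt >= minOrthologs]
    d <- data.frame(chrom = names(cnt), count = as.integer(cnt),
                    stringsAsFactors = FALSE)
    d <- d[order(-d$count, d$chrom), , drop = FALSE]
    rownames(d) <- NULL
    cells[[el]] <- d
    if (nrow(d)) {
      nFis <- nFis + nrow(d) - 1L
      for (ch in d$chrom) chromElems[[ch]] <- c(chromElems[[ch]], el)
    }
  }
  list(cells = cells,
       nFusions = sum(pmax(lengths(chromElems) - 1L, 0L)),
       nFissions = nFis)
}
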