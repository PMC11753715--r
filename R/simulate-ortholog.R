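#' Simulate a 1:1 ortholog table from a karyotype history
#'
#' Turns the tip chromosome maps of a [KaryotypeHistory-class] into a
#' complete 1:1 ortholog table (every gene placed once in every species),
#' optionally perturbed by within-segment gene shuffling. A "segment" is a
#' maximal run of genes from the same ancestral element on a tip chromosome;
#' shuffling permutes the positions of the selected genes within their
#' segment, so gene order decays with `shuffleRate` but no gene ever crosses
#' a fusion boundary -- mirroring the empirical pattern of gene shuffling
#' within, but not between, the ancestral-X and neo-X arms of a fused
#' chromosome.
#'
#' @param history a [KaryotypeHistory-class] object.
#' @param shuffleRate per-gene probability in `[0, 1]` of taking part in the
#'   within-segment permutation.
#' @param seed integer seed.
#' @param includeRoot also emit the ancestral karyotype as a pseudo-species
#'   (useful as a focal species that is guaranteed to retain the ancestral
#'   element-per-chromosome packaging, as the red flour beetle does among
#'   real beetles).
#' @param rootName species name for the ancestral karyotype row.
#' @return a data.frame with column `ortholog_id` and, per species,
#'   `<species>.chrom` and `<species>.pos` (ordinal gene positions). The
#'   species names are in `attr(, "species")`.
#' @export
simulateOrthologTable <- function(history, shuffleRate = 0, seed = 1L,
                                  includeRoot = FALSE,
                                  rootName = "ancestor") {
  stopifnot(is(history, "KaryotypeHistory"))
  if (shuffleRate < 0 || shuffleRate > 1)
    stop("shuffleRate must be in [0, 1]")
  set.seed(as.integer(seed))

  ids <- sort(names(history@geneElement))
  out <- data.frame(ortholog_id = ids, stringsAsFactors = FALSE)
  species <- character()

  if (includeRoot) {
    rk <- history@rootKaryotype
    chrom <- rep(names(rk), lengths(rk))
    pos <- unlist(lapply(lengths(rk), seq_len), use.names = FALSE)
    gid <- unlist(rk, use.names = FALSE)
    i <- match(ids, gid)
    out[[paste0(rootName, ".chrom")]] <- chrom[i]
    out[[paste0(rootName, ".pos")]] <- pos[i]
    species <- rootName
  }

  for (tp in names(history@tipMaps)) {
    m <- history@tipMaps[[tp]]
    m <- m[order(m$chrom, m$position), ]
    for (ch in unique(m$chrom)) {
      sel <- which(m$chrom == ch)
      runs <- rle(m$element[sel])
      stopEnd <- cumsum(runs$lengths)
      start <- c(1L, head(stopEnd, -1L) + 1L)
      for (r in seq_along(runs$lengths)) {
        seg <- sel[start[r]:stopEnd[r]]
        pick <- seg[stats::runif(length(seg)) < shuffleRate]
        if (length(pick) >= 2L)
          m$position[pick] <- m$position[sample(pick)]
      }
    }
    i <- match(ids, m$gene_id)
    out[[paste0(tp, ".chrom")]] <- m$chrom[i]
    out[[paste0(tp, ".pos")]] <- m$position[i]
    species <- c(species, tp)
  }
  attr(out, "species") <- species
  out
}

# species names encoded in an ortholog table's column names
.orthoSpecies <- function(tab) {
  sp <- attr(tab, "species")
  if (!is.null(sp)) return(sp)
  unique(sub("\\.chrom$", "", grep("\\.chrom$", names(tab), value = TRUE)))
}

.orthoCol <- function(tab, species, what = c("chrom", "pos")) {
  what <- match.arg(what)
  col <- paste0(species, ".", what)
  if (!col %in% names(tab))
    stop("species not present in ortholog table: ", species)
  tab[[col]]
}
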