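#' Read and validate a bedGraph depth track
#'
#' Four whitespace-delimited columns (chrom, start, end, depth; 0-based
#' half-open, no track lines). Intervals are sorted (stably) per
#' chromosome; negative depths and overlapping intervals are errors naming
#' the offending line(s).
#'
#' @param path bedGraph file.
#' @return sorted `GRanges` with metadata column `depth`.
#' @export
readBedGraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  names(S4Vectors::mcols(gr))[names(S4Vectors::mcols(gr)) == "score"] <-
    "depth"
  if (any(gr$depth < 0))
    stop("negative depth at line(s): ",
         paste(utils::head(which(gr$depth < 0), 5L), collapse = ", "))
  ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                    drop.redundant = TRUE)
  if (length(ov))
    stop("overlapping intervals at lines ",
         S4Vectors::queryHits(ov)[1L], " and ",
         S4Vectors::subjectHits(ov)[1L])
  sort(gr)
}

#' Write a depth track as bedGraph
#'
#' @param gr `GRanges` with a `depth` (or `score`) metadata column.
#' @param path output path (0-based half-open coordinates).
#' @export
writeBedGraph <- function(gr, path) {
  if ("depth" %in% names(S4Vectors::mcols(gr)))
    gr$score <- gr$depth
  rtracklayer::export(gr[, "score"], path, format = "bedGraph")
  invisible(path)
}

#' Read a per-base depth TSV
#'
#' Three columns: chrom, 1-based position, depth. Returned as width-1
#' intervals so it can feed [windowMedians()] like a bedGraph.
#'
#' @param path TSV file (no header).
#' @return `GRanges` with metadata column `depth`.
#' @export
readDepthTSV <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "pos", "depth"))
  if (any(df$depth < 0)) stop("negative depth values")
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$pos, width = 1L),
                               depth = df$depth)
  sort(gr)
}

#' Read gene coordinates from BED or GFF3
#'
#' `readGeneBed` takes BED with >= 4 columns (0-based half-open, name =
#' gene id); `readGFF3` keeps `gene` features and uses their `ID` (GFF3 is
#' 1-based inclusive; both land on the same internal 1-based `GRanges`
#' representation). Duplicate gene ids are an error; missing strand is kept
#' as `*`.
#'
#' @param path input file.
#' @return `GRanges` with metadata column `gene_id`.
#' @export
readGeneBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name) || any(is.na(gr$name)))
    stop("BED file must have a name (gene id) column")
  if (anyDuplicated(gr$name))
    stop("duplicate gene ids: ",
         paste(unique(gr$name[duplicated(gr$name)]), collapse = ", "))
  gr$gene_id <- gr$name
  gr[, "gene_id"]
}

#' @rdname readGeneBed
#' @export
readGFF3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[gr$type == "gene"]
  ids <- gr$ID
  if (is.null(ids) || any(is.na(ids)))
    stop("GFF3 gene features must carry an ID attribute")
  if (anyDuplicated(ids))
    stop("duplicate gene ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gr$gene_id <- ids
  gr[, "gene_id"]
}

#' Read/write a 1:1 ortholog table
#'
#' TSV with column `ortholog_id` and, per species, `<species>.chrom` and
#' `<species>.pos`, plus optional `# key=value` header lines.
#'
#' @param path file path.
#' @param table ortholog table (see [simulateOrthologTable()]).
#' @param meta named character vector for the provenance header.
#' @return `readOrthologTable` returns the table with `attr(, "species")`.
#' @export
readOrthologTable <- function(path) {
  df <- readTsvWithHeader(path)
  if (!"ortholog_id" %in% names(df))
    stop("ortholog table must have an ortholog_id column")
  if (anyDuplicated(df$ortholog_id))
    stop("duplicated ortholog ids")
  attr(df, "species") <-
    unique(sub("\\.chrom$", "", grep("\\.chrom$", names(df), value = TRUE)))
  df
}

#' @rdname readOrthologTable
#' @export
writeOrthologTable <- function(table, path, meta = character()) {
  writeTsvWithHeader(table, path, meta)
}

#' Read/write an expression matrix with its sample sheet
#'
#' The matrix TSV has gene ids in the first column and one column per
#' sample; the sample sheet TSV has columns `sample`, `sex`,
#' `compartment`, `tissue`, `replicate`. Every sheet sample must appear in
#' the matrix.
#'
#' @param matrixPath,sheetPath input TSVs.
#' @param se `SummarizedExperiment` to write.
#' @param prefix output path prefix; writes `<prefix>_fpkm.tsv` and
#'   `<prefix>_samples.tsv`.
#' @param meta named character vector for provenance headers.
#' @return `readExpression` returns a `SummarizedExperiment` with assay
#'   `fpkm`.
#' @export
readExpression <- function(matrixPath, sheetPath) {
  m <- readTsvWithHeader(matrixPath)
  sheet <- readTsvWithHeader(sheetPath)
  mat <- as.matrix(m[, -1L, drop = FALSE])
  rownames(mat) <- m[[1L]]
  if (any(mat < 0)) stop("negative expression values")
  missing <- setdiff(sheet$sample, colnames(mat))
  if (length(missing))
    stop("samples in sheet but not in matrix: ",
         paste(missing, collapse = ", "))
  mat <- mat[, sheet$sample, drop = FALSE]
  rownames(sheet) <- sheet$sample
  SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = mat),
    colData = S4Vectors::DataFrame(sheet))
}

#' @rdname readExpression
#' @export
writeExpression <- function(se, prefix, meta = character()) {
  mat <- SummarizedExperiment::assay(se)
  writeTsvWithHeader(
    data.frame(gene_id = rownames(mat), mat, check.names = FALSE),
    paste0(prefix, "_fpkm.tsv"), meta)
  writeTsvWithHeader(
    as.data.frame(SummarizedExperiment::colData(se)),
    paste0(prefix, "_samples.tsv"), meta)
  invisible(prefix)
}
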