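#' Length-weighted median
#'
#' Median of a set of values where each value stands for `weights[i]`
#' observations (e.g. a constant-depth interval of that many sites). Ties are
#' resolved towards the lower value, so the result is always one of `values`.
#'
#' @param values numeric vector.
#' @param weights non-negative numeric vector, same length as `values`.
#' @return a single numeric value.
#' @keywords internal
weightedMedian <- function(values, weights) {
  stopifnot(length(values) == length(weights), all(weights >= 0))
  keep <- weights > 0
  if (!any(keep)) return(NA_real_)
  values <- values[keep]
  weights <- weights[keep]
  o <- order(values)
  values <- values[o]
  weights <- weights[o]
  cw <- cumsum(weights)
  values[which(cw >= sum(weights) / 2)[1L]]
}

# Deterministic stage seed derived from a single user-facing seed; kept well
# below 2^31 so it is always a valid R integer seed.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 12347) %% 2147480000)
}

# Polynomial rolling hash (mod 2^31 - 1) of a character string, returned as
# 8 hex digits. Used to stamp output files with a configuration fingerprint.
configHash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write / read a TSV with commented provenance header
#'
#' All pipeline outputs are plain TSVs preceded by `# key=value` lines
#' recording tool version, configuration hash and seed, so downstream tools
#' (and tests) can verify provenance.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param meta named character vector written as `# name=value` lines.
#' @return `readTsvWithHeader` returns the data.frame with the header
#'   key=value pairs in `attr(, "meta")`.
#' @export
writeTsvWithHeader <- function(df, path, meta = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(sprintf("# %s=%s", names(meta), as.character(meta)), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTsvWithHeader
#' @export
readTsvWithHeader <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- character()
  if (length(hdr)) {
    kv <- sub("^#\\s*", "", lines[hdr])
    kv <- strsplit(kv, "=", fixed = TRUE)
    meta <- vapply(kv, function(p) paste(p[-1], collapse = "="), "")
    names(meta) <- vapply(kv, `[[`, "", 1L)
  }
  df <- utils::read.table(text = lines[setdiff(seq_along(lines), hdr)],
                          header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  attr(df, "meta") <- meta
  df
}
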