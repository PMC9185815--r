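#' Read and write profile tables as TSV
#'
#' The on-disk dialect is a plain tab-separated table: optional leading
#' `#`-prefixed comment lines, one header row (the header itself may be
#' written as `#feature_id<TAB>sample1...`), the first column holding feature
#' identifiers and one numeric column per sample. Values are serialized at
#' full (round-trip) precision, so `readProfileTSV(writeProfileTSV(x))`
#' reproduces the matrix exactly.
#'
#' @param path file path.
#' @param countTable logical; if `TRUE` the values are validated as integer
#'   counts and a [MicrobiomeCounts-class] is returned.
#' @return [readProfileTSV()] returns a [MicrobiomeProfile-class] (or
#'   [MicrobiomeCounts-class]); [writeProfileTSV()] returns `path` invisibly.
#' @examples
#' m <- matrix(c(0.6, 0.4, 0.1, 0.9), nrow = 2,
#'             dimnames = list(c("spA", "spB"), c("s1", "s2")))
#' tf <- tempfile(fileext = ".tsv")
#' writeProfileTSV(MicrobiomeProfile(m), tf)
#' identical(abundances(readProfileTSV(tf)), m)
#' @export
readProfileTSV <- function(path, countTable = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty profile file: ", path)
  isComment <- grepl("^#", lines)
  firstData <- which(!isComment)[1]
  if (is.na(firstData)) stop("no data lines in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # the header is the last comment line if it is tab-delimited like the data,
  # otherwise the first non-comment line
  headerIdx <- firstData
  if (firstData > 1L && length(fields[[firstData - 1L]]) > 1L)
    headerIdx <- firstData - 1L
  header <- fields[[headerIdx]]
  header[1] <- sub("^#\\s*", "", header[1])
  dataStart <- if (headerIdx == firstData) firstData + 1L else firstData
  dataIdx <- seq.int(dataStart, length.out = max(0L, length(lines) - dataStart + 1L))
  dataIdx <- dataIdx[!isComment[dataIdx]]
  if (!length(dataIdx)) stop("profile file has a header but no rows: ", path)
  ncolExp <- length(header)
  sampleIds <- header[-1]
  if (anyDuplicated(sampleIds))
    stop("duplicated sample identifier(s) in header: ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  featIds <- character(length(dataIdx))
  vals <- matrix(NA_real_, nrow = length(dataIdx), ncol = ncolExp - 1L)
  for (k in seq_along(dataIdx)) {
    i <- dataIdx[k]
    f <- fields[[i]]
    if (length(f) != ncolExp)
      stop(sprintf("line %d: expected %d fields, found %d", i, ncolExp, length(f)))
    featIds[k] <- f[1]
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v))
      stop(sprintf("line %d: non-numeric value '%s'", i, f[-1][which(is.na(v))[1]]))
    vals[k, ] <- v
  }
  if (anyDuplicated(featIds))
    stop("duplicated feature identifier(s): ",
         paste(unique(featIds[duplicated(featIds)]), collapse = ", "))
  dimnames(vals) <- list(featIds, sampleIds)
  if (countTable) MicrobiomeCounts(vals) else MicrobiomeProfile(vals)
}

#' @rdname readProfileTSV
#' @param x a [MicrobiomeProfile-class], [MicrobiomeCounts-class] or named
#'   numeric matrix.
#' @param comments optional character vector written as leading `#` comment
#'   lines (used by [runPipeline()] to stamp outputs with seed and config
#'   hash).
#' @export
writeProfileTSV <- function(x, path, comments = character()) {
  m <- .asAbundance(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  writeLines(paste(c("#feature_id", colnames(m)), collapse = "\t"), con)
  # 17 significant digits round-trip IEEE doubles exactly
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t"), "")
  writeLines(body, con)
  invisible(path)
}

#' Read and write per-sample metadata tables
#'
#' Plain TSV with a `sample_id` column and the cohort metadata columns used
#' throughout the pipeline (`group`, `stage`, `age`, `sex`, `cohort`,
#' `ca199_level`, `ca199_code`, `depth`). Leading `#` comment lines are
#' ignored.
#'
#' @param path file path.
#' @return [readSampleMetadata()] returns a data.frame keyed by `sample_id`.
#' @export
readSampleMetadata <- function(path) {
  md <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(md))
    stop("metadata table must carry a 'sample_id' column")
  if (anyDuplicated(md$sample_id))
    stop("duplicated sample_id(s) in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  rownames(md) <- md$sample_id
  md
}

#' @rdname readSampleMetadata
#' @param md data.frame of per-sample metadata.
#' @param comments optional leading comment lines.
#' @export
writeSampleMetadata <- function(md, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  utils::write.table(md, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
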