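#' Binary marker (fragment presence/absence) matrix
#'
#' The central genotype object: a samples x loci matrix of 0/1 values, with
#' unique sample identifiers as row names and unique fragment (locus) labels
#' as column names. Dominant markers such as AFLP are scored this way: a 1
#' records that a sized fragment was observed in a sample, a 0 that it was
#' not. Missing data are not representable; replicate scoring noise is the
#' error model instead.
#'
#' @param x a matrix (or object coercible to one) of 0/1 values with row and
#'   column names.
#' @return an integer matrix of class `"marker_matrix"`.
#' @examples
#' m <- marker_matrix(matrix(c(1, 0, 1, 1), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("L1", "L2"))))
#' @export
marker_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop_hs("marker matrix needs at least 1 sample and 1 locus")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_hs("marker matrix needs sample ids (rownames) and locus labels (colnames)")
  if (anyDuplicated(rownames(x)))
    stop_hs("duplicate sample ids: ",
            paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop_hs("duplicate locus labels: ",
            paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  storage.mode(x) <- "integer"
  bad <- which(!(x %in% c(0L, 1L)) | is.na(x))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(x)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(x)) + 1L
    stop_hs("non-binary value at sample '", rownames(x)[i],
            "', locus '", colnames(x)[j], "'")
  }
  class(x) <- c("marker_matrix", class(x))
  x
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("marker_matrix:", nrow(x), "samples x", ncol(x), "loci;",
      sum(x), "presences\n")
  invisible(x)
}

#' Read a binary marker matrix from delimited text
#'
#' The first row holds locus labels, the first column sample ids. The
#' delimiter is auto-detected among tab, comma and semicolon.
#'
#' @param path file path.
#' @return a [marker_matrix()].
#' @export
read_marker_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop_hs("marker matrix file needs a header and at least one sample row")
  sep <- detect_delim(lines[1])
  fields <- strsplit(lines, sep, fixed = TRUE)
  loci <- trimws(fields[[1]][-1])
  rows <- fields[-1]
  ids <- vapply(rows, function(f) trimws(f[1]), character(1))
  vals <- lapply(seq_along(rows), function(k) {
    f <- trimws(rows[[k]][-1])
    if (length(f) != length(loci))
      stop_hs("row for sample '", ids[k], "' has ", length(f),
              " cells, expected ", length(loci))
    bad <- which(!f %in% c("0", "1"))
    if (length(bad))
      stop_hs("non-binary cell '", f[bad[1]], "' at sample '", ids[k],
              "', locus '", loci[bad[1]], "'")
    as.integer(f)
  })
  m <- do.call(rbind, vals)
  dimnames(m) <- list(ids, loci)
  marker_matrix(m)
}

#' Write a marker matrix as tab-delimited text
#'
#' @param m a [marker_matrix()].
#' @param path output file path.
#' @export
write_marker_matrix <- function(m, path) {
  stopifnot(inherits(m, "marker_matrix"))
  header <- paste(c("sample_id", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], m[i, ]), collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
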