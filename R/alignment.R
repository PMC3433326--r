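#' Aligned plastid haplotype sequences
#'
#' Holds an alignment of haplotype sequences over `{A,C,G,T,-,N}` together
#' with column regions to be excluded before analysis (typically poly-A
#' stretches whose length variation is not reliably alignable). Coordinates
#' of excluded regions are 1-based inclusive, the biologist-facing
#' convention; they are stored as given and only applied by
#' [code_alignment()].
#'
#' @param seqs named character vector of aligned sequences (equal length), or
#'   a character matrix with one row per sequence.
#' @param excluded_regions optional two-column matrix (start, end) of 1-based
#'   inclusive column intervals; must lie within the alignment and not
#'   overlap.
#' @return an object of class `"haplo_alignment"`: list with elements `seqs`
#'   (character matrix, rows = sequences), `excluded_regions`.
#' @export
haplo_alignment <- function(seqs, excluded_regions = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (is.null(names(seqs))) stop_hs("sequences must be named")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      tab <- table(lens)
      common <- as.integer(names(tab)[which.max(tab)])
      stop_hs("sequences differ in aligned length: ",
              paste(names(seqs)[lens != common], collapse = ", "))
    }
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(mat) <- names(seqs)
  }
  mat[] <- toupper(mat)
  if (nrow(mat) < 1L || ncol(mat) < 1L) stop_hs("empty alignment")
  bad <- !mat %in% c("A", "C", "G", "T", "-", "N")
  if (any(bad))
    stop_hs("invalid character(s) in alignment: ",
            paste(unique(mat[bad]), collapse = ", "))
  if (anyDuplicated(rownames(mat))) stop_hs("duplicate sequence ids")
  if (!is.null(excluded_regions)) {
    excluded_regions <- matrix(as.integer(excluded_regions), ncol = 2)
    colnames(excluded_regions) <- c("start", "end")
    if (any(excluded_regions[, 1] > excluded_regions[, 2]))
      stop_hs("excluded region with start > end")
    if (any(excluded_regions < 1L) || any(excluded_regions > ncol(mat)))
      stop_hs("excluded region outside alignment bounds (1..", ncol(mat), ")")
    o <- order(excluded_regions[, 1])
    excluded_regions <- excluded_regions[o, , drop = FALSE]
    if (nrow(excluded_regions) > 1L &&
        any(excluded_regions[-1, 1] <= excluded_regions[-nrow(excluded_regions), 2]))
      stop_hs("excluded regions overlap")
  }
  structure(list(seqs = mat, excluded_regions = excluded_regions),
            class = "haplo_alignment")
}

#' @export
print.haplo_alignment <- function(x, ...) {
  cat("haplo_alignment:", nrow(x$seqs), "sequences x", ncol(x$seqs), "columns;",
      if (is.null(x$excluded_regions)) 0L else nrow(x$excluded_regions),
      "excluded region(s)\n")
  invisible(x)
}

#' Read an aligned FASTA file of haplotype sequences
#'
#' @param path FASTA file with aligned sequences.
#' @param exclusions optional two-column matrix of 1-based inclusive column
#'   intervals to exclude later (stored, not applied).
#' @return a [haplo_alignment()].
#' @export
read_alignment <- function(path, exclusions = NULL) {
  dna <- suppressWarnings(ape::read.FASTA(path))
  if (!length(dna)) stop_hs("no sequences in ", path)
  chars <- lapply(as.character(dna), function(s) toupper(s))
  lens <- lengths(chars)
  if (length(unique(lens)) > 1L) {
    tab <- table(lens)
    common <- as.integer(names(tab)[which.max(tab)])
    stop_hs("sequences differ in aligned length: ",
            paste(names(chars)[lens != common], collapse = ", "))
  }
  seqs <- vapply(chars, paste, character(1), collapse = "")
  haplo_alignment(seqs, excluded_regions = exclusions)
}

#' Write a haplotype alignment to FASTA
#'
#' @param aln a [haplo_alignment()].
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "haplo_alignment"))
  ids <- rownames(aln$seqs)
  lines <- character(0)
  for (i in seq_along(ids)) {
    lines <- c(lines, paste0(">", ids[i]),
               paste(aln$seqs[i, ], collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Flow-cytometry ratio records
#'
#' One row per measured sample: the sample/standard G0/G1 fluorescence ratio,
#' the coefficient of variation (%) of the sample peak, and the species the
#' regression calibration is grouped by (ploidy attribution is per species,
#' since genome size per chromosome-set differs between species).
#'
#' @param df data frame with columns `sample_id`, `ratio`, `cv_percent`,
#'   `species`.
#' @return a data frame of class `"fcm_records"`.
#' @export
fcm_records <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "ratio", "cv_percent", "species")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_hs("fcm records missing column(s): ", paste(miss, collapse = ", "))
  df$ratio <- as.numeric(df$ratio)
  df$cv_percent <- as.numeric(df$cv_percent)
  if (any(!is.finite(df$ratio) | df$ratio <= 0)) stop_hs("fluorescence ratios must be > 0")
  if (any(!is.finite(df$cv_percent) | df$cv_percent < 0)) stop_hs("cv_percent must be >= 0")
  class(df) <- c("fcm_records", "data.frame")
  df
}

#' Read flow-cytometry records from delimited text
#' @param path file path.
#' @return an [fcm_records()] data frame.
#' @export
read_fcm <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) stop_hs("empty FCM file")
  sep <- detect_delim(first)
  fcm_records(read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, strip.white = TRUE))
}

#' Write flow-cytometry records as tab-delimited text
#' @param fcm an [fcm_records()] data frame.
#' @param path output file path.
#' @export
write_fcm <- function(fcm, path) {
  write.table(fcm, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
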