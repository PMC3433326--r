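#' Per-sample metadata
#'
#' A data frame with one row per sample carrying taxon, population and
#' locality codes, the cytotype (integer ploidy multiplier, `NA` = unknown),
#' the plastid haplotype code (`NA` = unknown), replicate annotations
#' (`replicate_of` names the sample a re-scored replicate belongs to), and an
#' exclusion flag with a mandatory reason (e.g. field misidentification
#' detected from clustering).
#'
#' @param df a data frame with at least `sample_id`, `taxon` and
#'   `population`; optional columns `cytotype`, `locality`, `haplotype`,
#'   `replicate_of`, `excluded`, `excluded_reason`.
#' @return a data frame of class `"sample_meta"` with all columns present.
#' @export
sample_meta <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  mandatory <- c("sample_id", "taxon", "population")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop_hs("metadata is missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop_hs("duplicate sample ids in metadata")
  if (is.null(df$cytotype)) df$cytotype <- NA_integer_
  df$cytotype <- as.integer(df$cytotype)
  for (col in c("locality", "haplotype", "replicate_of")) {
    if (is.null(df[[col]])) df[[col]] <- NA_character_
    df[[col]] <- as.character(df[[col]])
    df[[col]][!is.na(df[[col]]) & df[[col]] %in% c("", "unknown", "NA")] <- NA_character_
  }
  if (is.null(df$excluded)) df$excluded <- FALSE
  df$excluded <- tolower(as.character(df$excluded)) %in% c("true", "t", "1", "yes")
  if (is.null(df$excluded_reason)) df$excluded_reason <- NA_character_
  df$excluded_reason <- as.character(df$excluded_reason)
  df$excluded_reason[!is.na(df$excluded_reason) & df$excluded_reason == ""] <- NA_character_

  bad_rep <- !is.na(df$replicate_of) & !df$replicate_of %in% df$sample_id
  if (any(bad_rep))
    stop_hs("replicate_of points to unknown sample(s): ",
            paste(df$replicate_of[bad_rep], collapse = ", "))
  no_reason <- df$excluded & is.na(df$excluded_reason)
  if (any(no_reason))
    stop_hs("excluded sample(s) without a reason: ",
            paste(df$sample_id[no_reason], collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Read sample metadata from delimited text
#'
#' @param path file path; delimiter auto-detected among tab/comma/semicolon.
#' @return a [sample_meta()] data frame.
#' @export
read_metadata <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) stop_hs("empty metadata file")
  sep <- detect_delim(first)
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   strip.white = TRUE, quote = "\"", comment.char = "")
  sample_meta(df)
}

#' Write sample metadata as tab-delimited text
#'
#' @param meta a [sample_meta()] data frame.
#' @param path output file path.
#' @export
write_metadata <- function(meta, path) {
  stopifnot(inherits(meta, "sample_meta"))
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Summarise a metadata table
#'
#' Counts accessions, populations and taxa (a quick sampling overview).
#'
#' @param object a [sample_meta()] data frame.
#' @param ... unused.
#' @export
summary.sample_meta <- function(object, ...) {
  out <- list(n_accessions = nrow(object),
              n_populations = length(unique(object$population)),
              n_taxa = length(unique(object$taxon)),
              n_excluded = sum(object$excluded),
              n_replicates = sum(!is.na(object$replicate_of)))
  class(out) <- "summary.sample_meta"
  out
}

#' @export
print.summary.sample_meta <- function(x, ...) {
  cat(x$n_accessions, "accessions representing", x$n_populations,
      "populations and", x$n_taxa, "taxa;", x$n_excluded, "excluded,",
      x$n_replicates, "replicate scorings\n")
  invisible(x)
}

# Non-excluded sample ids, optionally intersected with a candidate set.
active_samples <- function(meta, ids = NULL) {
  keep <- meta$sample_id[!meta$excluded & is.na(meta$replicate_of)]
  if (!is.null(ids)) keep <- intersect(ids, keep)
  keep
}
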