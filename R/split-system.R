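#' Circular split system
#'
#' A weighted collection of bipartitions (splits) of a taxon set, all
#' compatible with one circular ordering of the taxa, as produced by
#' Neighbor-Net. Each split is stored as the set of taxon indices on one
#' side; compatibility means that side forms a contiguous arc of the
#' circular ordering.
#'
#' @param taxa character vector of taxon labels.
#' @param splits list of integer vectors (indices into `taxa`, one side of
#'   each split).
#' @param weights nonnegative numeric vector, one per split.
#' @param cycle integer permutation of `seq_along(taxa)` giving the circular
#'   ordering; defaults to the identity.
#' @return an object of class `"split_system"`.
#' @export
split_system <- function(taxa, splits, weights, cycle = seq_along(taxa)) {
  taxa <- as.character(taxa)
  n <- length(taxa)
  if (n < 2L) stop_hs("a split system needs at least 2 taxa")
  if (anyDuplicated(taxa)) stop_hs("duplicate taxon labels")
  if (length(splits) != length(weights))
    stop_hs("splits and weights differ in length")
  if (!length(splits)) stop_hs("empty split system")
  if (length(cycle) != n || !setequal(cycle, seq_len(n)))
    stop_hs("cycle must be a permutation of 1..", n)
  weights <- as.numeric(weights)
  if (any(weights < 0)) stop_hs("split weights must be nonnegative")
  pos <- integer(n); pos[cycle] <- seq_len(n)
  splits <- lapply(splits, function(s) {
    s <- sort(unique(as.integer(s)))
    if (!length(s) || length(s) >= n || any(s < 1L) || any(s > n))
      stop_hs("each split side must be a proper nonempty subset of the taxa")
    # canonical side: the one not containing the first taxon of the cycle
    if (cycle[1] %in% s) s <- sort(setdiff(seq_len(n), s))
    if (!is_arc(pos[s], n))
      stop_hs("split not compatible with the circular ordering")
    s
  })
  key <- vapply(splits, paste, character(1), collapse = ",")
  if (anyDuplicated(key)) stop_hs("duplicate splits")
  structure(list(taxa = taxa, splits = splits, weights = weights, cycle = cycle),
            class = "split_system")
}

# Are these cycle positions a contiguous arc on a circle of n positions?
is_arc <- function(p, n) {
  p <- sort(p)
  k <- length(p)
  if (p[k] - p[1] == k - 1L) return(TRUE)          # plain run
  # wrapped run: complement must be a plain run
  q <- sort(setdiff(seq_len(n), p))
  length(q) == 0L || (q[length(q)] - q[1] == length(q) - 1L)
}

#' @export
print.split_system <- function(x, ...) {
  nt <- sum(lengths(x$splits) > 1L & lengths(x$splits) < length(x$taxa) - 1L)
  cat("split_system:", length(x$taxa), "taxa,", length(x$splits),
      "splits (", nt, "nontrivial ), total weight",
      format(sum(x$weights), digits = 6), "\n")
  invisible(x)
}

#' Distance induced by a split system
#'
#' The split-system metric: `d(i, j)` is the sum of weights of the splits
#' separating taxa `i` and `j`. For distances coming from an additive tree
#' this reproduces the input distances.
#'
#' @param ss a [split_system()].
#' @return a symmetric numeric matrix with taxon labels.
#' @export
split_distance <- function(ss) {
  n <- length(ss$taxa)
  d <- matrix(0, n, n, dimnames = list(ss$taxa, ss$taxa))
  for (k in seq_along(ss$splits)) {
    s <- ss$splits[[k]]
    o <- setdiff(seq_len(n), s)
    d[s, o] <- d[s, o] + ss$weights[k]
    d[o, s] <- d[o, s] + ss$weights[k]
  }
  d
}

#' Write a split system as a SplitsTree-style NEXUS file
#'
#' Emits `Taxa` and `Splits` blocks, including the `CYCLE` line recording the
#' circular ordering, so the file can be opened in SplitsTree-class viewers.
#' Weights are written with 10 decimals.
#'
#' @param ss a [split_system()].
#' @param path output path.
#' @export
write_splits_nexus <- function(ss, path) {
  stopifnot(inherits(ss, "split_system"))
  n <- length(ss$taxa)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("#NEXUS")
  w("")
  w("BEGIN Taxa;")
  w("DIMENSIONS ntax=", n, ";")
  w("TAXLABELS")
  for (i in seq_len(n)) w("[", i, "] '", ss$taxa[i], "'")
  w(";")
  w("END; [Taxa]")
  w("")
  w("BEGIN Splits;")
  w("DIMENSIONS ntax=", n, " nsplits=", length(ss$splits), ";")
  w("FORMAT labels=no weights=yes confidences=no intervals=no;")
  w("CYCLE ", paste(ss$cycle, collapse = " "), ";")
  w("MATRIX")
  for (k in seq_along(ss$splits)) {
    s <- ss$splits[[k]]
    w("[", k, ", size=", length(s), "]\t", sprintf("%.10f", ss$weights[k]),
      "\t", paste(s, collapse = " "), ",")
  }
  w(";")
  w("END; [Splits]")
  invisible(path)
}

#' Read a split system from a SplitsTree-style NEXUS file
#'
#' Parses the dialect written by [write_splits_nexus()].
#'
#' @param path NEXUS file path.
#' @return a [split_system()].
#' @export
read_splits_nexus <- function(path) {
  lines <- readLines(path)
  tax_i <- grep("^\\[\\d+\\] '", lines)
  taxa <- sub("^\\[\\d+\\] '(.*)'$", "\\1", lines[tax_i])
  cyc_i <- grep("^CYCLE ", lines)
  if (!length(cyc_i)) stop_hs("no CYCLE line found")
  cycle <- as.integer(strsplit(sub("^CYCLE (.*);$", "\\1", lines[cyc_i[1]]), " ")[[1]])
  sp_i <- grep("^\\[\\d+, size=", lines)
  splits <- list(); weights <- numeric(0)
  for (ln in lines[sp_i]) {
    body <- sub("^\\[\\d+, size=\\d+\\]\t", "", ln)
    parts <- strsplit(sub(",$", "", body), "\t")[[1]]
    weights <- c(weights, as.numeric(parts[1]))
    splits <- c(splits, list(as.integer(strsplit(parts[2], " ")[[1]])))
  }
  split_system(taxa, splits, weights, cycle)
}
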