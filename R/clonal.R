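#' Pairwise band differences between genotypes
#'
#' Hamming distances between 0/1 rows: the number of loci at which two
#' samples differ.
#'
#' @param m a [marker_matrix()].
#' @param samples optional sample ids to restrict to (default: all rows).
#' @return a symmetric integer matrix with zero diagonal.
#' @export
pairwise_differences <- function(m, samples = NULL) {
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(m))
    if (length(missing)) stop_hs("unknown sample id(s): ", paste(missing, collapse = ", "))
    m <- m[samples, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop_hs("need at least 2 samples")
  d <- as.matrix(dist(unclass(m), method = "manhattan"))
  storage.mode(d) <- "integer"
  d
}

#' Suggest a clone-assignment threshold
#'
#' Two suggestions are returned and the caller picks. The replicate-based
#' suggestion is the largest difference observed among replicate scorings of
#' the same genotype (differences up to the scoring error must be tolerated).
#' The distribution-based suggestion scans the histogram of genotype pairwise
#' differences upward from the smallest observed value and reports the last
#' occupied integer bin before the first gap: within-clone noise and
#' between-clone differences form separated modes, and the gap's left edge
#' bounds the noise mode.
#'
#' @param replicate_diffs integer vector of replicate-pair differences (may
#'   be empty).
#' @param genotype_diffs integer vector of all genotype pairwise differences
#'   (may be empty).
#' @return list with `replicate_based` and `distribution_based` (either may
#'   be `NA` if its input was empty).
#' @export
suggest_threshold <- function(replicate_diffs, genotype_diffs) {
  if (!length(replicate_diffs) && !length(genotype_diffs))
    stop_hs("no replicate or genotype differences supplied")
  rb <- if (length(replicate_diffs)) max(as.integer(replicate_diffs)) else NA_integer_
  db <- NA_integer_
  if (length(genotype_diffs)) {
    v <- sort(unique(as.integer(genotype_diffs)))
    if (length(v) == 1L) {
      db <- v[1]
    } else {
      gaps <- which(diff(v) > 1L)
      db <- if (length(gaps)) v[gaps[1]] else v[length(v)]
    }
  }
  list(replicate_based = rb, distribution_based = db)
}

#' Assign samples to clones by threshold clustering
#'
#' Clones are the connected components of the graph joining every pair of
#' samples with at most `threshold` band differences (single linkage, so the
#' relation is transitively closed). `threshold = 0` reproduces the strict
#' rule of identical banding patterns.
#'
#' @param diffs symmetric difference matrix from [pairwise_differences()].
#' @param threshold maximum tolerated band difference (>= 0).
#' @return list of clusters (character vectors of sample ids), largest
#'   first.
#' @export
assign_clones <- function(diffs, threshold) {
  if (threshold < 0) stop_hs("threshold must be >= 0")
  adj <- diffs <= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  clusters <- split(names(comp), comp)
  o <- order(-lengths(clusters),
             vapply(clusters, function(x) sort(x)[1], character(1)))
  unname(lapply(clusters[o], sort))
}

#' Bias-corrected Nei genotype diversity
#'
#' `D_g = n / (n - 1) * (1 - sum((s_i / n)^2))` for clone sizes `s_i` with
#' `n = sum(s_i)`: the sample-size-corrected probability that two
#' individuals drawn from the population belong to different clones. Equals
#' 1 exactly when every individual is its own clone, and approaches 0 as a
#' single clone dominates. Reported to 3 decimals (half-up), matching
#' published tables.
#'
#' @param cluster_sizes positive integers; their sum must be >= 2.
#' @return `D_g`, rounded to 3 decimals.
#' @export
genotype_diversity <- function(cluster_sizes) {
  s <- as.numeric(cluster_sizes)
  if (!length(s) || any(s < 1)) stop_hs("cluster sizes must be positive")
  n <- sum(s)
  if (n < 2) stop_hs("need at least 2 individuals")
  round_half_up(n / (n - 1) * (1 - sum((s / n)^2)), 3)
}

#' Per-population clone partition and diversity table
#'
#' Runs [pairwise_differences()] and [assign_clones()] within each
#' population (excluded samples and replicate re-scorings dropped) and
#' tabulates the sample count `Nb`, the clone (genotype) count `Nb_geno`,
#' and the genotype diversity `D_g`.
#'
#' @param m a [marker_matrix()].
#' @param meta a [sample_meta()] data frame.
#' @param threshold band-difference threshold for clone assignment.
#' @param populations optional subset of population codes.
#' @return object of class `"clone_partition"`: list with `table` (data
#'   frame Nb / Nb_geno / D_g per population), `clusters` (per population),
#'   `threshold`.
#' @export
clonal_diversity <- function(m, meta, threshold, populations = NULL) {
  keep <- intersect(active_samples(meta), rownames(m))
  sub <- meta[match(keep, meta$sample_id), ]
  pops <- populations %||% unique(sub$population)
  clusters <- list()
  rows <- list()
  for (p in pops) {
    ids <- sub$sample_id[sub$population == p]
    if (length(ids) < 2L) next
    cl <- assign_clones(pairwise_differences(m, ids), threshold)
    clusters[[p]] <- cl
    rows[[p]] <- data.frame(population = p, Nb = length(ids),
                            Nb_geno = length(cl),
                            D_g = genotype_diversity(lengths(cl)),
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop_hs("no population with >= 2 samples")
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 clusters = clusters, threshold = threshold),
            class = "clone_partition")
}

#' @export
print.clone_partition <- function(x, ...) {
  cat("clone_partition (threshold =", x$threshold, "band differences)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Clones shared across populations
#'
#' Re-clusters the pooled samples of all populations at the same threshold
#' and reports clones whose members span more than one population —
#' evidence for clonal dispersal between sites.
#'
#' @param m a [marker_matrix()].
#' @param meta a [sample_meta()] data frame.
#' @param threshold band-difference threshold.
#' @param samples optional sample ids to pool (default: all active).
#' @return data frame with one row per shared clone (clone members and the
#'   populations spanned), or `NULL` when none.
#' @export
shared_clones <- function(m, meta, threshold, samples = NULL) {
  keep <- intersect(active_samples(meta, samples), rownames(m))
  if (length(keep) < 2L) return(NULL)
  cl <- assign_clones(pairwise_differences(m, keep), threshold)
  pops <- setNames(meta$population, meta$sample_id)
  out <- lapply(cl, function(ids) {
    p <- unique(pops[ids])
    if (length(p) > 1L)
      data.frame(members = paste(ids, collapse = ","),
                 populations = paste(sort(p), collapse = ","),
                 stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}
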