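# Small in-code fixtures shared across test files.

tiny_matrix <- function(values, samples = NULL, loci = NULL) {
  k <- if (is.null(loci)) 3L else length(loci)
  m <- matrix(values, ncol = k, byrow = TRUE)
  rownames(m) <- samples %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- loci %||% paste0("L", seq_len(ncol(m)))
  marker_matrix(m)
}

random_markers <- function(n, L, p = 0.5, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(n * L, 1, p), nrow = n,
              dimnames = list(paste0("s", seq_len(n)), paste0("L", seq_len(L))))
  # avoid all-zero rows (undefined Jaccard)
  m[rowSums(m) == 0, 1] <- 1L
  marker_matrix(m)
}

meta_for <- function(m, taxon = "T1", population = "Pop1") {
  sample_meta(data.frame(sample_id = rownames(m), taxon = taxon,
                         population = population, stringsAsFactors = FALSE))
}

# fragment_set built directly from a locus-label vector
fset <- function(label, fragments) {
  structure(list(label = label, members = label, fragments = fragments,
                 count = length(fragments)),
            class = "fragment_set")
}

# random additive tree metric on n taxa with its true split set
tree_metric <- function(n = 8, seed = 1) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.5))
  list(tree = tr, d = stats::cophenetic(tr))
}

# canonical string for a split given as a label subset
canon_split <- function(side, labels) {
  a <- sort(side); b <- sort(setdiff(labels, side))
  if (length(a) < length(b) || (length(a) == length(b) && a[1] < b[1]))
    paste(a, collapse = ",") else paste(b, collapse = ",")
}
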