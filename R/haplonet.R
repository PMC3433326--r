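#' Code an alignment into network characters
#'
#' Applies the region exclusions (poly-A stretches and the like), then codes
#' indels: every distinct gap run — a maximal set of alignment columns that
#' are gapped together, with identical start and end in every sequence that
#' carries the gap — becomes one binary presence/absence character, and the
#' run's columns are removed from the nucleotide matrix. Distinct gap runs
#' that overlap cannot be coded automatically and raise an error demanding
#' manual coding.
#'
#' @param a a [haplo_alignment()].
#' @return list of class `"coded_alignment"` with `chars` (character matrix:
#'   remaining nucleotide columns, then one `"0"/"1"` column per coded
#'   indel), `n_nucleotide`, `n_indel`, `n_characters`.
#' @export
code_alignment <- function(a) {
  stopifnot(inherits(a, "haplo_alignment"))
  seqs <- a$seqs
  if (!is.null(a$excluded_regions)) {
    drop <- unlist(lapply(seq_len(nrow(a$excluded_regions)), function(i)
      a$excluded_regions[i, 1]:a$excluded_regions[i, 2]))
    seqs <- seqs[, -drop, drop = FALSE]
  }
  # collect distinct gap runs (start, end) across sequences
  runs <- unique(do.call(rbind, lapply(seq_len(nrow(seqs)), function(r) {
    g <- seqs[r, ] == "-"
    if (!any(g)) return(NULL)
    rl <- rle(g)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    cbind(start = starts[rl$values], end = ends[rl$values])
  })))
  indel_chars <- NULL
  if (!is.null(runs) && nrow(runs)) {
    runs <- runs[order(runs[, 1], runs[, 2]), , drop = FALSE]
    if (nrow(runs) > 1L) {
      for (i in 2:nrow(runs)) {
        if (runs[i, 1] <= runs[i - 1, 2])
          stop_hs("overlapping gap runs at columns ", runs[i - 1, 1], "-",
                  runs[i - 1, 2], " and ", runs[i, 1], "-", runs[i, 2],
                  ": manual indel coding required")
      }
    }
    indel_chars <- vapply(seq_len(nrow(runs)), function(i) {
      cols <- seqs[, runs[i, 1]:runs[i, 2], drop = FALSE]
      gapped <- apply(cols == "-", 1, all)
      partial <- apply(cols == "-", 1, any) & !gapped
      if (any(partial))
        stop_hs("gap run ", runs[i, 1], "-", runs[i, 2],
                " is not identical across sequences: manual coding required")
      ifelse(gapped, "1", "0")
    }, character(nrow(seqs)))
    if (is.null(dim(indel_chars)))
      indel_chars <- matrix(indel_chars, nrow = nrow(seqs))
    colnames(indel_chars) <- paste0("indel", seq_len(ncol(indel_chars)))
    drop_cols <- unlist(lapply(seq_len(nrow(runs)), function(i)
      runs[i, 1]:runs[i, 2]))
    seqs <- seqs[, -drop_cols, drop = FALSE]
  }
  chars <- cbind(seqs, indel_chars)
  structure(list(chars = chars, n_nucleotide = ncol(seqs),
                 n_indel = if (is.null(indel_chars)) 0L else ncol(indel_chars),
                 n_characters = ncol(chars)),
            class = "coded_alignment")
}

#' Mutational step distance between coded haplotypes
#'
#' Substitutions and coded indel mismatches each count one step; `N`
#' (missing base) never counts.
#'
#' @param h1,h2 character vectors of equal length (rows of a coded
#'   alignment).
#' @return integer step count.
#' @export
step_distance <- function(h1, h2) {
  if (length(h1) != length(h2)) stop_hs("haplotypes differ in character count")
  ok <- h1 != "N" & h2 != "N"
  sum(h1[ok] != h2[ok])
}

#' All pairwise step distances of a coded alignment
#'
#' @param coded a `"coded_alignment"` from [code_alignment()].
#' @return symmetric integer matrix.
#' @export
step_distance_matrix <- function(coded) {
  ch <- coded$chars
  n <- nrow(ch)
  d <- matrix(0L, n, n, dimnames = list(rownames(ch), rownames(ch)))
  if (n > 1L) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- as.integer(step_distance(ch[i, ], ch[j, ]))
    }
  }
  d
}

# Parsimony-connection probability heuristic: chance that j observed steps
# between two haplotypes of L characters involve no superimposed or parallel
# change (each successive change must hit a so-far unchanged character and
# not revert one).
parsimony_connection_limit <- function(n_characters, conf = 0.95) {
  j <- 0L
  repeat {
    p <- prod((n_characters - 2 * (0:j)) / (n_characters - (0:j)))
    if (p < conf) return(max(j, 1L))
    j <- j + 1L
    if (j > n_characters %/% 2) return(j)
  }
}

#' Build a statistical-parsimony haplotype network
#'
#' Pairs of haplotypes are connected in order of increasing step distance; a
#' k-step connection inserts k - 1 inferred intermediate nodes (haplotypes
#' not observed but necessary to link the observed ones by unit steps).
#' Connections above the limit are not made, so the network decomposes into
#' connected components — the haplotype groups. Within a step level, every
#' connection that was not already implied by shorter paths is added, so
#' equal-step alternatives are retained as cycles (network, not tree).
#' `limit = "auto"` derives the limit from a parsimony-probability routine at
#' the 95% convention, given the number of characters.
#'
#' @param coded a `"coded_alignment"`, or a precomputed symmetric step-
#'   distance matrix with haplotype labels.
#' @param limit maximum number of steps accepted for a connection, or
#'   `"auto"`.
#' @param conf confidence level for the `"auto"` limit.
#' @return object of class `"haplo_network"`: list with `graph` (igraph,
#'   node attribute `observed`), `components` (named membership vector over
#'   observed haplotypes), `limit`, `step_matrix`.
#' @export
build_network <- function(coded, limit = "auto", conf = 0.95) {
  if (inherits(coded, "coded_alignment")) {
    d <- step_distance_matrix(coded)
    L <- coded$n_characters
  } else {
    d <- as.matrix(coded)
    L <- max(d)
  }
  if (is.null(rownames(d))) stop_hs("step matrix needs haplotype labels")
  if (identical(limit, "auto")) limit <- parsimony_connection_limit(L, conf)
  limit <- as.integer(limit)
  if (limit <= 0L) stop_hs("connection limit must be positive")
  haps <- rownames(d)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(haps), name = haps, observed = TRUE)
  n_int <- 0L
  if (length(haps) > 1L) {
    for (s in c(0L, seq_len(limit))) {
      pairs <- which(d == s & upper.tri(d), arr.ind = TRUE)
      if (!nrow(pairs)) next
      # distances before this level: additions within a level do not
      # suppress equal-step alternatives (cycles are retained)
      pre <- igraph::distances(g)
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        if (is.finite(pre[haps[i], haps[j]]) && pre[haps[i], haps[j]] <= s) next
        if (s <= 1L) {
          # identical haplotypes (0 steps) are joined directly as well
          g <- igraph::add_edges(g, c(haps[i], haps[j]))
        } else {
          inter <- paste0("med", n_int + seq_len(s - 1L))
          n_int <- n_int + s - 1L
          g <- igraph::add_vertices(g, s - 1L, name = inter, observed = FALSE)
          chain <- c(haps[i], inter, haps[j])
          g <- igraph::add_edges(g, as.vector(rbind(chain[-length(chain)], chain[-1])))
        }
      }
    }
  }
  memb <- igraph::components(g)$membership
  comp <- memb[haps]
  # relabel components 1..k in order of first appearance among observed nodes
  comp <- setNames(match(comp, unique(comp)), haps)
  structure(list(graph = g, components = comp, limit = limit, step_matrix = d),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("haplo_network:", sum(igraph::V(x$graph)$observed), "observed +",
      sum(!igraph::V(x$graph)$observed), "inferred haplotypes,",
      length(unique(x$components)), "group(s), connection limit",
      x$limit, "\n")
  invisible(x)
}

#' Haplotype groups of a network
#'
#' @param network a `"haplo_network"`.
#' @return named character vector mapping each observed haplotype to its
#'   group label (`"group1"`, `"group2"`, ... by component).
#' @export
haplotype_groups <- function(network) {
  setNames(paste0("group", network$components), names(network$components))
}

#' Haplotype occupancy table
#'
#' For every haplotype observed in the metadata: its carriers and the taxa
#' and populations they represent, plus the network group when a network is
#' given. Haplotypes without carriers are never emitted.
#'
#' @param meta a [sample_meta()] data frame (column `haplotype`).
#' @param network optional `"haplo_network"` for group labels.
#' @return data frame with one row per observed haplotype.
#' @export
haplotype_table <- function(meta, network = NULL) {
  sub <- meta[!is.na(meta$haplotype) & !meta$excluded & is.na(meta$replicate_of), ]
  if (!nrow(sub)) return(NULL)
  groups <- if (!is.null(network)) haplotype_groups(network) else NULL
  rows <- lapply(split(sub, sub$haplotype), function(h) {
    data.frame(haplotype = h$haplotype[1],
               group = if (is.null(groups)) NA_character_ else
                 unname(groups[h$haplotype[1]]),
               n_carriers = nrow(h),
               taxa = paste(sort(unique(h$taxon)), collapse = ","),
               populations = paste(sort(unique(h$population)), collapse = ","),
               carriers = paste(sort(h$sample_id), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$haplotype), ]
}

#' Export a haplotype network as GraphML
#'
#' @param network a `"haplo_network"`.
#' @param path output path.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}
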