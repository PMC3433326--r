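#' Per-group fragment sets
#'
#' A group (taxon, cytotype-qualified taxon, or hybrid lineage) carries a
#' fragment if at least one of its non-excluded members does — the
#' AFLPdat convention, which also reproduces published shared-fragment
#' arithmetic. Excluded samples and replicate re-scorings never contribute.
#'
#' @param m a [marker_matrix()].
#' @param meta a [sample_meta()] data frame.
#' @param by either the name of a metadata column to group by (e.g.
#'   `"taxon"`), or a named list of sample-id vectors defining the groups
#'   directly. With `by = "taxon"`, taxa holding several cytotypes are
#'   qualified as `"taxon (Nx)"`.
#' @return a named list of objects of class `"fragment_set"`, each with
#'   `label`, `members`, `fragments` (locus labels) and `count`.
#' @export
fragment_sets <- function(m, meta, by = "taxon") {
  if (is.list(by)) {
    groups <- by
  } else {
    keep <- active_samples(meta)
    keep <- intersect(keep, rownames(m))
    sub <- meta[match(keep, meta$sample_id), ]
    lab <- as.character(sub[[by]])
    if (by == "taxon") {
      multi <- tapply(sub$cytotype, sub$taxon,
                      function(x) length(unique(x[!is.na(x)])) > 1)
      q <- !is.na(multi[sub$taxon]) & multi[sub$taxon] & !is.na(sub$cytotype)
      lab[q] <- sprintf("%s (%dx)", sub$taxon[q], sub$cytotype[q])
    }
    groups <- split(keep, lab)
  }
  out <- lapply(names(groups), function(lab) {
    ids <- intersect(groups[[lab]], rownames(m))
    if (!length(ids)) stop_hs("group '", lab, "' has no members present in the matrix")
    sub <- m[ids, , drop = FALSE]
    frag <- colnames(m)[colSums(sub) > 0]
    structure(list(label = lab, members = ids, fragments = frag,
                   count = length(frag)),
              class = "fragment_set")
  })
  names(out) <- names(groups)
  out
}

#' Fragment totals and polymorphism
#'
#' Counts the loci present in at least one non-excluded sample, how many of
#' those are polymorphic (both a presence and an absence observed), and the
#' percentage polymorphic (two decimals, half-up as printed tables do);
#' optionally also per-group fragment counts.
#'
#' @param m a [marker_matrix()].
#' @param meta a [sample_meta()] data frame.
#' @param by optional grouping passed to [fragment_sets()] for per-group
#'   counts.
#' @return list with `total`, `polymorphic`, `percent_polymorphic`,
#'   `per_group` (named counts or `NULL`).
#' @export
fragment_totals <- function(m, meta, by = NULL) {
  keep <- intersect(active_samples(meta), rownames(m))
  if (!length(keep)) stop_hs("all samples are excluded")
  sub <- m[keep, , drop = FALSE]
  cs <- colSums(sub)
  total <- sum(cs > 0)
  poly <- sum(cs > 0 & cs < nrow(sub))
  per_group <- NULL
  if (!is.null(by)) {
    fs <- fragment_sets(m, meta, by)
    per_group <- vapply(fs, function(g) g$count, integer(1))
  }
  list(total = total, polymorphic = poly,
       percent_polymorphic = round_half_up(100 * poly / total, 2),
       per_group = per_group)
}

#' Fragments shared between two groups
#'
#' The count is the size of the intersection of the two fragment sets; the
#' percentage is relative to the FIRST group's fragment count (the printed
#' table convention: rows are candidates, the column group's total is the
#' denominator).
#'
#' @param a,b `"fragment_set"` objects from [fragment_sets()].
#' @return list with `count` and `percent` (two decimals, half-up).
#' @export
shared_fragments <- function(a, b) {
  if (!length(a$fragments) || !length(b$fragments))
    stop_hs("cannot compare an empty fragment set")
  n <- length(intersect(a$fragments, b$fragments))
  list(count = n, percent = round_half_up(100 * n / a$count, 2))
}

#' Table of fragments shared between focal groups and candidates
#'
#' One row per candidate, one column pair (count, percent) per focal group;
#' percentages use the focal group's fragment count as denominator.
#'
#' @param focal,candidates lists of fragment sets (see [fragment_sets()]).
#' @return a data frame.
#' @export
shared_fragment_table <- function(focal, candidates) {
  rows <- lapply(candidates, function(cand) {
    cells <- lapply(focal, function(f) shared_fragments(f, cand))
    stats <- unlist(lapply(cells, function(x) c(x$count, x$percent)))
    names(stats) <- as.vector(rbind(paste0(vapply(focal, `[[`, "", "label"), "_n"),
                                    paste0(vapply(focal, `[[`, "", "label"), "_pct")))
    c(list(candidate = cand$label, candidate_total = cand$count), as.list(stats))
  })
  do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
}

#' Private (group-specific) fragments
#'
#' A locus is private to a group if it is present in that group and absent
#' from every other listed group. For designated hybrid groups the function
#' additionally reports which of the parental groups' private fragments the
#' hybrid carries (the "k of n specific bands" accounting).
#'
#' @param groups list of fragment sets; memberships must be disjoint unless
#'   `allow_overlap = TRUE`.
#' @param hybrids optional list of fragment sets (e.g. hybrid lineages) to
#'   screen against the groups' private fragments.
#' @param allow_overlap allow samples to appear in several groups.
#' @return list with `private` (named list of locus vectors) and
#'   `hybrid_content` (data frame or `NULL`).
#' @export
private_fragments <- function(groups, hybrids = NULL, allow_overlap = FALSE) {
  if (length(groups) < 2L) stop_hs("need at least 2 groups")
  members <- unlist(lapply(groups, `[[`, "members"))
  if (!allow_overlap && anyDuplicated(members))
    stop_hs("groups share members; set allow_overlap = TRUE if intended")
  labs <- vapply(groups, `[[`, "", "label")
  private <- lapply(seq_along(groups), function(k) {
    others <- unique(unlist(lapply(groups[-k], `[[`, "fragments")))
    setdiff(groups[[k]]$fragments, others)
  })
  names(private) <- labs
  hybrid_content <- NULL
  if (!is.null(hybrids)) {
    hybrid_content <- do.call(rbind, lapply(hybrids, function(h) {
      do.call(rbind, lapply(seq_along(private), function(k) {
        data.frame(hybrid = h$label, group = labs[k],
                   carried = length(intersect(h$fragments, private[[k]])),
                   private_total = length(private[[k]]),
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(hybrid_content) <- NULL
  }
  list(private = private, hybrid_content = hybrid_content)
}

#' Replicate repeatability
#'
#' For every (sample, replicate) pair annotated in the metadata, the number
#' of differing bands and the repeatability `100 * (1 - diff / loci)`; plus
#' the mean repeatability over pairs. With no annotated replicates an
#' explicit empty result is returned rather than an error.
#'
#' @param m a [marker_matrix()].
#' @param meta a [sample_meta()] data frame.
#' @return list with `pairs` (data frame), `mean_repeatability`,
#'   `n_pairs`.
#' @export
replicate_error_rate <- function(m, meta) {
  reps <- meta[!is.na(meta$replicate_of), , drop = FALSE]
  reps <- reps[reps$sample_id %in% rownames(m) & reps$replicate_of %in% rownames(m), ,
               drop = FALSE]
  if (!nrow(reps))
    return(list(pairs = NULL, mean_repeatability = NA_real_, n_pairs = 0L))
  L <- ncol(m)
  diffs <- vapply(seq_len(nrow(reps)), function(i)
    sum(m[reps$sample_id[i], ] != m[reps$replicate_of[i], ]), integer(1))
  pairs <- data.frame(sample_id = reps$replicate_of, replicate = reps$sample_id,
                      differences = diffs,
                      repeatability = round_half_up(100 * (1 - diffs / L), 2),
                      stringsAsFactors = FALSE)
  list(pairs = pairs,
       mean_repeatability = round_half_up(mean(100 * (1 - diffs / L)), 2),
       n_pairs = nrow(pairs))
}
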