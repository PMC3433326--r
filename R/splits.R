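#' Jaccard distances on a binary marker matrix
#'
#' `d(i, j) = 1 - a / (a + b + c)` where `a` counts shared presences and
#' `b + c` the mismatches; shared absences carry no information for dominant
#' markers and are ignored. Undefined for a pair with no presences at all.
#'
#' @param m a [marker_matrix()] (or any 0/1 matrix with row names).
#' @return symmetric numeric distance matrix with zero diagonal.
#' @export
jaccard_distance <- function(m) {
  x <- unclass(m)
  if (any(rowSums(x) == 0))
    stop_hs("all-zero sample row(s): ",
            paste(rownames(x)[rowSums(x) == 0], collapse = ", "))
  a <- tcrossprod(x)                       # shared presences
  r <- rowSums(x)
  denom <- outer(r, r, "+") - a            # a + b + c
  d <- 1 - a / denom
  diag(d) <- 0
  d
}

#' Neighbor-Net circular split system
#'
#' Runs the Neighbor-Net agglomeration on a distance matrix and estimates
#' nonnegative split weights over the circular splits of the resulting taxon
#' ordering (the computation is delegated to \pkg{phangorn}'s
#' implementation of the published algorithm). Splits with weight at or
#' below `weight_floor` are dropped as numerical dust.
#'
#' @param d symmetric nonnegative distance matrix (zero diagonal, >= 4
#'   taxa).
#' @param weight_floor minimum retained split weight.
#' @return a [split_system()].
#' @export
neighbor_net <- function(d, weight_floor = 1e-6) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop_hs("distance matrix must be symmetric")
  if (nrow(d) < 4L) stop_hs("Neighbor-Net needs at least 4 taxa")
  if (any(d < 0)) stop_hs("distances must be nonnegative")
  nn <- phangorn::neighborNet(stats::as.dist(d))
  spl <- phangorn::as.splits(nn)
  labs <- attr(spl, "labels")
  w <- attr(spl, "weights")
  cyc <- attr(spl, "cycle") %||% seq_along(labs)
  keep <- w > weight_floor
  split_system(taxa = labs, splits = spl[keep], weights = w[keep], cycle = cyc)
}

#' Group separation in a split system
#'
#' For each predefined group: does some retained split isolate exactly that
#' group, or a super-group (a side that is a union of whole groups
#' containing it)? Also reports mean within- and between-group distances.
#'
#' @param ss a [split_system()].
#' @param d the distance matrix the splits were estimated from.
#' @param groups named list of taxon-label vectors partitioning the taxa.
#' @return data frame with one row per group: `isolated`,
#'   `isolated_super`, `mean_within`, `mean_between`.
#' @export
group_cohesion <- function(ss, d, groups) {
  d <- as.matrix(d)
  all_members <- unlist(groups)
  missing <- setdiff(all_members, ss$taxa)
  if (length(missing)) stop_hs("group member(s) not among taxa: ",
                               paste(missing, collapse = ", "))
  sides <- lapply(ss$splits, function(s) ss$taxa[s])
  both_sides <- c(sides, lapply(sides, function(s) setdiff(ss$taxa, s)))
  is_union_of_groups <- function(side) {
    inside <- vapply(groups, function(g) all(g %in% side), logical(1))
    outside <- vapply(groups, function(g) !any(g %in% side), logical(1))
    all(inside | outside)
  }
  rows <- lapply(names(groups), function(gn) {
    g <- groups[[gn]]
    iso <- any(vapply(both_sides, function(s) setequal(s, g), logical(1)))
    sup <- any(vapply(both_sides, function(s)
      all(g %in% s) && length(s) < length(ss$taxa) && is_union_of_groups(s),
      logical(1)))
    wd <- if (length(g) > 1) mean(d[g, g][upper.tri(d[g, g])]) else NA_real_
    others <- setdiff(all_members, g)
    bd <- if (length(others)) mean(d[g, others, drop = FALSE]) else NA_real_
    data.frame(group = gn, isolated = iso, isolated_super = sup,
               mean_within = wd, mean_between = bd, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
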