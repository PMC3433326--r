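#' Group-anchored two-dimensional ordination
#'
#' A deterministic two-stage mapping designed for hybrid/parent
#' configurations, where the relationship is not hierarchical: (1) the
#' centroids of the predefined reference groups are embedded by classical
#' scaling of their Euclidean centroid-to-centroid distances, anchoring the
#' groups at maximal mutual separation in the plane; (2) every sample
#' (reference members and focal samples alike) is then placed at the point
#' minimising the sum of squared deviations between its planar distances to
#' the fixed anchors and its original-space distances to the group
#' centroids. The solver is a deterministic multi-start (anchor positions,
#' anchor midpoints and a coarse grid) refined by BFGS. Hybrids between two
#' reference groups land between their anchors. `mode = "mds"` instead
#' returns plain classical scaling of the full sample distance matrix.
#'
#' @param m a [marker_matrix()] (0/1 rows; Euclidean distances are computed
#'   on them).
#' @param reference_groups named list of sample-id vectors (>= 2 groups).
#' @param focal_samples ids of additional samples to place (default: all
#'   remaining rows of `m`).
#' @param mode `"anchored"` (default) or `"mds"`.
#' @return object of class `"ordination_result"`: list with `coords` (n x 2
#'   matrix), `anchors` (group centroid positions), `groups`,
#'   `mapping_error` (over all placed samples).
#' @export
ordinate <- function(m, reference_groups, focal_samples = NULL,
                     mode = c("anchored", "mds")) {
  mode <- match.arg(mode)
  x <- unclass(m)
  if (length(reference_groups) < 2L) stop_hs("need at least 2 reference groups")
  ref_ids <- unlist(reference_groups)
  missing <- setdiff(ref_ids, rownames(x))
  if (length(missing)) stop_hs("unknown reference sample(s): ",
                               paste(missing, collapse = ", "))
  focal_samples <- focal_samples %||% setdiff(rownames(x), ref_ids)
  place_ids <- c(ref_ids, focal_samples)
  xs <- x[place_ids, , drop = FALSE]

  if (mode == "mds") {
    co <- cmdscale(dist(xs), k = 2)
    if (ncol(co) < 2) co <- cbind(co, 0)
    colnames(co) <- c("dim1", "dim2")
    d_orig <- as.matrix(dist(xs))
    return(structure(list(coords = co, anchors = NULL,
                          groups = reference_groups,
                          mapping_error = mapping_error(d_orig, co)),
                     class = "ordination_result"))
  }

  cent <- do.call(rbind, lapply(reference_groups, function(ids)
    colMeans(x[ids, , drop = FALSE])))
  dc <- as.matrix(dist(cent))
  if (all(dc < 1e-12)) warning("all reference centroids coincide")
  anchors <- cmdscale(dist(cent), k = min(2L, nrow(cent) - 1L))
  if (ncol(anchors) < 2) anchors <- cbind(anchors, 0)
  rownames(anchors) <- names(reference_groups)
  colnames(anchors) <- c("dim1", "dim2")

  # distances of every placed sample to the original-space centroids
  targ <- t(vapply(seq_len(nrow(xs)), function(i)
    sqrt(colSums((t(cent) - xs[i, ])^2)), numeric(nrow(cent))))

  starts <- rbind(anchors,
                  t(combn(nrow(anchors), 2, function(p) colMeans(anchors[p, ]))),
                  as.matrix(expand.grid(
                    dim1 = seq(min(anchors[, 1]), max(anchors[, 1]), length.out = 3),
                    dim2 = seq(min(anchors[, 2]) - 1, max(anchors[, 2]) + 1,
                               length.out = 3))))
  obj <- function(y, t_i) sum((sqrt(colSums((t(anchors) - y)^2)) - t_i)^2)
  co <- t(vapply(seq_len(nrow(xs)), function(i) {
    best <- NULL; bestv <- Inf
    for (s in seq_len(nrow(starts))) {
      fit <- optim(starts[s, ], obj, t_i = targ[i, ], method = "BFGS",
                   control = list(reltol = 1e-12, maxit = 500))
      if (fit$value < bestv - 1e-12) { bestv <- fit$value; best <- fit$par }
    }
    best
  }, numeric(2)))
  dimnames(co) <- list(rownames(xs), c("dim1", "dim2"))
  d_orig <- as.matrix(dist(xs))
  structure(list(coords = co, anchors = anchors, groups = reference_groups,
                 mapping_error = mapping_error(d_orig, co)),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat("ordination_result:", nrow(x$coords), "samples,",
      length(x$groups), "reference groups; mapping error",
      format(x$mapping_error, digits = 4), "\n")
  invisible(x)
}

#' Mapping error of a two-dimensional presentation
#'
#' The summed absolute difference between planar and original inter-object
#' distances, relative to the summed original distances:
#' `sum(|d2D - d| ) / sum(d)` over all pairs. Zero for perfectly embeddable
#' configurations; invariant under rotation, reflection and translation of
#' the coordinates.
#'
#' @param d_orig symmetric original-space distance matrix.
#' @param coords n x 2 coordinate matrix (rows in the same order / with the
#'   same names as `d_orig`).
#' @return nonnegative scalar.
#' @export
mapping_error <- function(d_orig, coords) {
  d_orig <- as.matrix(d_orig)
  if (!is.null(rownames(coords)) && !is.null(rownames(d_orig)))
    d_orig <- d_orig[rownames(coords), rownames(coords)]
  if (nrow(d_orig) != nrow(coords)) stop_hs("index sets do not match")
  d2 <- as.matrix(dist(coords))
  ut <- upper.tri(d_orig)
  tot <- sum(d_orig[ut])
  if (tot == 0) stop_hs("total original distance is zero")
  sum(abs(d2[ut] - d_orig[ut])) / tot
}

#' Projection of a point onto the axis between two anchors
#'
#' Returns the scalar projection parameter `t` such that `t = 0` at anchor
#' `a`, `t = 1` at anchor `b`; hybrids between the two groups are expected
#' at intermediate `t`.
#'
#' @param ord an `"ordination_result"`.
#' @param a,b reference group names.
#' @param sample sample id.
#' @return numeric scalar.
#' @export
projection_parameter <- function(ord, a, b, sample) {
  pa <- ord$anchors[a, ]; pb <- ord$anchors[b, ]
  p <- ord$coords[sample, ]
  sum((p - pa) * (pb - pa)) / sum((pb - pa)^2)
}
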