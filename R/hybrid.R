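#' Gamete-ploidy model of the candidate parents
#'
#' For each parental taxon/cytotype: the ploidies of the male gametes it
#' puts out (pollen is produced by meiosis almost exclusively, even in
#' apomicts), the ploidies of its female gametes (which may include
#' unreduced, apomeiotically formed eggs), and the haplotype group it
#' transmits maternally.
#'
#' @param profiles list of [taxon_profile()] objects, or a data frame with
#'   columns `taxon`, `cytotype`, `female` / `male` (comma-separated ploidy
#'   lists) and `haplogroup`.
#' @param hap_groups named character vector mapping haplotype codes to group
#'   labels (used to resolve each profile's transmitted group).
#' @return object of class `"gamete_model"`: data frame with list-columns
#'   `female` and `male`.
#' @export
gamete_model <- function(profiles, hap_groups = NULL) {
  if (is.data.frame(profiles)) {
    df <- profiles
    df$female <- lapply(strsplit(as.character(df$female), ","), as.integer)
    df$male <- lapply(strsplit(as.character(df$male), ","), as.integer)
  } else {
    df <- do.call(rbind, lapply(profiles, function(p) {
      grp <- if (!is.null(hap_groups)) unique(hap_groups[names(p$haplotypes)])
             else unique(unname(p$haplotypes))
      grp <- grp[!is.na(grp)]
      if (length(grp) != 1L)
        stop_hs("profile ", p$taxon, " (", p$cytotype,
                "x) must transmit exactly one haplotype group")
      data.frame(taxon = p$taxon, cytotype = p$cytotype, haplogroup = grp,
                 stringsAsFactors = FALSE)
    }))
    df$female <- lapply(profiles, `[[`, "female_gametes")
    df$male <- lapply(profiles, `[[`, "male_gametes")
  }
  if (!nrow(df)) stop_hs("empty gamete model")
  bad <- vapply(seq_len(nrow(df)), function(i)
    !length(df$female[[i]]) || !length(df$male[[i]]) ||
      any(c(df$female[[i]], df$male[[i]]) < 1L), logical(1))
  if (any(bad)) stop_hs("gamete ploidy sets must be nonempty positive integers")
  class(df) <- c("gamete_model", "data.frame")
  df
}

#' Infer DNA ploidy from flow-cytometry ratios
#'
#' Per species, the sample/standard fluorescence ratio is regressed through
#' the origin against the counted ploidy of the reference individuals
#' (`ratio = beta * ploidy`); each sample is then attributed the integer
#' ploidy minimising `|ratio - beta * k|`. Samples whose best fit leaves a
#' relative residual above `tolerance` are flagged as possible aneuploids.
#' Records failing the CV filter are excluded with a reason; species without
#' any reference individual cannot be attributed.
#'
#' @param records an [fcm_records()] data frame.
#' @param references data frame with `sample_id` and `ploidy` (chromosome-
#'   counted individuals present in `records`).
#' @param cv_max CV acceptance threshold in percent (records at or above it
#'   are excluded).
#' @param tolerance relative residual above which a sample is flagged
#'   `possible_aneuploid`.
#' @param k_max largest integer ploidy considered.
#' @return data frame with one row per record: `status` (`"ok"`,
#'   `"excluded_cv"`, `"cannot_attribute"`), `ploidy`, `residual`,
#'   `possible_aneuploid`, plus the per-species `beta` as an attribute.
#' @export
infer_ploidy_from_fcm <- function(records, references, cv_max = 5,
                                  tolerance = 0.03, k_max = 12L) {
  stopifnot(inherits(records, "fcm_records"))
  refs <- merge(records[, c("sample_id", "ratio", "species")], references,
                by = "sample_id")
  betas <- vapply(split(refs, refs$species), function(r)
    unname(coef(lm(ratio ~ 0 + ploidy, data = r))[1]), numeric(1))
  out <- records
  out$status <- "ok"
  out$ploidy <- NA_integer_
  out$residual <- NA_real_
  out$possible_aneuploid <- FALSE
  for (i in seq_len(nrow(out))) {
    if (out$cv_percent[i] >= cv_max) {
      out$status[i] <- "excluded_cv"
      next
    }
    b <- betas[out$species[i]]
    if (is.na(b)) {
      out$status[i] <- "cannot_attribute"
      next
    }
    k <- seq_len(k_max)
    resid <- abs(out$ratio[i] - b * k)
    best <- which.min(resid)
    out$ploidy[i] <- best
    out$residual[i] <- resid[best] / (b * best)
    out$possible_aneuploid[i] <- out$residual[i] > tolerance
  }
  attr(out, "betas") <- betas
  class(out) <- c("ploidy_attribution", "data.frame")
  out
}

#' Enumerate crosses compatible with an offspring ploidy and haplogroup
#'
#' All (mother, father, egg ploidy, pollen ploidy) combinations in the
#' gamete model whose gamete-ploidy sum equals the target and whose mother
#' transmits the target haplotype group (plastids are maternally inherited,
#' so the offspring's haplotype group names its mother). Crosses within one
#' taxon are excluded unless `allow_intrataxon = TRUE`. Each hypothesis
#' carries the expected maternal genome fraction `egg / (egg + pollen)`.
#'
#' @param model a [gamete_model()].
#' @param target_ploidy offspring ploidy (>= 2).
#' @param target_haplogroup haplotype group of the offspring, or `NA` to
#'   skip the maternal clause (haplotype evidence unavailable).
#' @param allow_intrataxon allow mother and father of the same taxon.
#' @return data frame of class `"cross_hypotheses"` (possibly 0 rows).
#' @export
enumerate_crosses <- function(model, target_ploidy, target_haplogroup,
                              allow_intrataxon = FALSE) {
  if (target_ploidy < 2) stop_hs("target ploidy must be >= 2")
  rows <- list()
  for (mi in seq_len(nrow(model))) {
    if (!is.na(target_haplogroup) && model$haplogroup[mi] != target_haplogroup) next
    for (fi in seq_len(nrow(model))) {
      if (!allow_intrataxon && model$taxon[fi] == model$taxon[mi]) next
      for (egg in model$female[[mi]]) for (pollen in model$male[[fi]]) {
        if (egg + pollen != target_ploidy) next
        rows[[length(rows) + 1L]] <- data.frame(
          mother = model$taxon[mi], mother_cytotype = model$cytotype[mi],
          father = model$taxon[fi], father_cytotype = model$cytotype[fi],
          egg = egg, pollen = pollen, offspring_ploidy = egg + pollen,
          haplogroup = model$haplogroup[mi],
          maternal_fraction = egg / (egg + pollen),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mother = character(0), mother_cytotype = integer(0),
               father = character(0), father_cytotype = integer(0),
               egg = integer(0), pollen = integer(0),
               offspring_ploidy = integer(0), haplogroup = character(0),
               maternal_fraction = numeric(0), stringsAsFactors = FALSE)
  class(out) <- c("cross_hypotheses", "data.frame")
  out
}

#' Parentage scores of a hybrid lineage
#'
#' For each candidate group: the number of fragments shared with the
#' lineage, the shared percentage with the lineage's fragment count as
#' denominator (the published table convention), the retention fraction —
#' the share of the candidate's own fragments found in the lineage, the
#' dosage-bearing quantity used by the composition clause of
#' [explain_lineage()] — and, if a private-fragment table is supplied, the
#' candidate-specific bands the lineage carries (`"k/n"`). Candidates are
#' ranked by shared percentage.
#'
#' @param lineage a `"fragment_set"` (see [fragment_sets()]) for the
#'   lineage.
#' @param candidates list of `"fragment_set"` objects for the candidate
#'   parental groups.
#' @param private optional `private` element of [private_fragments()]
#'   computed over the candidates.
#' @return data frame of class `"parentage_scores"`, ranked.
#' @export
parentage_scores <- function(lineage, candidates, private = NULL) {
  if (!length(candidates)) stop_hs("empty candidate list")
  rows <- lapply(candidates, function(cand) {
    sh <- shared_fragments(lineage, cand)
    ret <- length(intersect(lineage$fragments, cand$fragments)) / cand$count
    priv_txt <- NA_character_
    if (!is.null(private) && cand$label %in% names(private)) {
      pv <- private[[cand$label]]
      priv_txt <- sprintf("%d/%d", length(intersect(lineage$fragments, pv)),
                          length(pv))
    }
    data.frame(candidate = cand$label, candidate_total = cand$count,
               shared = sh$count, shared_pct = sh$percent,
               retention = ret, private_carried = priv_txt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$shared_pct, out$candidate), ]
  rownames(out) <- NULL
  class(out) <- c("parentage_scores", "data.frame")
  out
}

#' Classify hybrid bands as additive, lost or de novo
#'
#' Per locus: present in the parental union and in the hybrid — additive;
#' in the union but absent from the hybrid — lost; absent from both parents
#' but present in the hybrid — de novo. The loss rate is relative to the
#' union size, the de novo rate to the number of loci outside the union;
#' the counts partition the union and non-union loci exactly.
#'
#' @param hybrid,mother,father 0/1 vectors over the same named loci.
#' @return list with `additive`, `lost`, `denovo` counts, `union_size`,
#'   `lost_rate`, `denovo_rate`, `additive_rate`.
#' @export
classify_additivity <- function(hybrid, mother, father) {
  if (length(hybrid) != length(mother) || length(hybrid) != length(father))
    stop_hs("locus sets do not match")
  if (!is.null(names(hybrid)) && !is.null(names(mother)) &&
      (!identical(names(hybrid), names(mother)) ||
       !identical(names(hybrid), names(father))))
    stop_hs("locus sets do not match")
  u <- mother == 1L | father == 1L
  additive <- sum(u & hybrid == 1L)
  lost <- sum(u & hybrid == 0L)
  denovo <- sum(!u & hybrid == 1L)
  list(additive = additive, lost = lost, denovo = denovo,
       union_size = sum(u),
       lost_rate = if (sum(u)) lost / sum(u) else NA_real_,
       denovo_rate = if (sum(!u)) denovo / sum(!u) else NA_real_,
       additive_rate = if (sum(u)) additive / sum(u) else NA_real_)
}

#' Single- versus multiple-event verdict for a hybrid lineage
#'
#' A lineage is explainable by a single hybridisation event if some cross
#' hypothesis satisfies both clauses: (i) haplotype compatibility — true by
#' construction for hypotheses from [enumerate_crosses()] with the
#' lineage's haplogroup; and (ii) composition consistency — the lineage's
#' genetic composition must not contradict the hypothesis' expected
#' maternal genome fraction. Composition leaning is measured on retention
#' fractions (share of each parent's fragments found in the lineage), which
#' are insensitive to parental fragment-count asymmetry: with a maternal
#' fraction above `0.5 + dead_band` the father's retention must not exceed
#' the mother's by more than `tolerance`, below `0.5 - dead_band` the
#' reverse; inside the dead band either leaning is acceptable. Only a
#' contradiction larger than the tolerance fails the clause — a tied
#' composition does not contradict a proposed cross.
#'
#' @param lineage list with at least `label`; used for reporting.
#' @param hypotheses a `"cross_hypotheses"` data frame (typically from
#'   [enumerate_crosses()] at the lineage's ploidy and haplogroup).
#' @param scores a `"parentage_scores"` data frame for the lineage whose
#'   candidate labels contain the taxon name and, for multi-cytotype taxa,
#'   the cytotype qualifier (as produced by [fragment_sets()]).
#' @param tolerance maximum acceptable wrong-direction retention difference.
#' @param dead_band half-width of the neutral zone around a maternal
#'   fraction of 0.5.
#' @return list of class `"lineage_verdict"`: `lineage`, `verdict`
#'   (`"single-event"` or `"not-single-event"`), `reasons` (per-hypothesis),
#'   `hypotheses`.
#' @export
explain_lineage <- function(lineage, hypotheses, scores, tolerance = 0.10,
                            dead_band = 0.05) {
  label <- if (is.list(lineage)) lineage$label else as.character(lineage)
  find_ret <- function(taxon, cytotype) {
    hit <- scores$candidate == sprintf("%s (%dx)", taxon, cytotype)
    if (!any(hit)) hit <- scores$candidate == taxon
    if (!any(hit)) stop_hs("no parentage score for candidate ", taxon)
    scores$retention[which(hit)[1]]
  }
  if (!nrow(hypotheses)) {
    return(structure(list(lineage = label, verdict = "not-single-event",
                          reasons = "no haplotype-compatible cross",
                          hypotheses = hypotheses),
                     class = "lineage_verdict"))
  }
  reasons <- character(nrow(hypotheses))
  ok <- logical(nrow(hypotheses))
  for (i in seq_len(nrow(hypotheses))) {
    h <- hypotheses[i, ]
    ret_m <- find_ret(h$mother, h$mother_cytotype)
    ret_f <- find_ret(h$father, h$father_cytotype)
    f <- h$maternal_fraction
    if (f > 0.5 + dead_band && ret_f - ret_m > tolerance) {
      reasons[i] <- sprintf(
        "composition contradicts %.2f maternal fraction: father retention %.3f > mother %.3f",
        f, ret_f, ret_m)
    } else if (f < 0.5 - dead_band && ret_m - ret_f > tolerance) {
      reasons[i] <- sprintf(
        "composition contradicts %.2f maternal fraction: mother retention %.3f > father %.3f",
        f, ret_m, ret_f)
    } else {
      ok[i] <- TRUE
      reasons[i] <- "compatible"
    }
  }
  structure(list(lineage = label,
                 verdict = if (any(ok)) "single-event" else "not-single-event",
                 reasons = reasons, hypotheses = hypotheses),
            class = "lineage_verdict")
}

#' @export
print.lineage_verdict <- function(x, ...) {
  cat("lineage", x$lineage, "->", x$verdict, "\n")
  if (is.data.frame(x$hypotheses) && nrow(x$hypotheses)) {
    for (i in seq_len(nrow(x$hypotheses))) {
      h <- x$hypotheses[i, ]
      cat(sprintf("  %s (%dx) egg %dx  x  %s (%dx) pollen %dx : %s\n",
                  h$mother, h$mother_cytotype, h$egg, h$father,
                  h$father_cytotype, h$pollen, x$reasons[i]))
    }
  } else {
    cat(" ", x$reasons, "\n")
  }
  invisible(x)
}

#' Define hybrid lineages from combined evidence
#'
#' Lineages are the maximal sets of samples homogeneous in (cluster,
#' cytotype, haplotype). Samples missing any of the three annotations are
#' listed as unassignable rather than raising an error. Lineages are
#' labelled `a`, `b`, `c`, ... by decreasing size.
#'
#' @param samples sample ids to assign.
#' @param clusters named cluster assignment (e.g. from [assign_clones()] at
#'   a lineage-scale threshold, or from split-graph groups).
#' @param cytotypes named integer ploidies (from metadata or
#'   [infer_ploidy_from_fcm()]).
#' @param haplotypes named haplotype codes.
#' @param meta optional [sample_meta()] used to report populations.
#' @return list with `lineages` (data frame: label, cytotype, haplotype,
#'   cluster, n, members, populations) and `unassignable`.
#' @export
define_lineages <- function(samples, clusters, cytotypes, haplotypes,
                            meta = NULL) {
  cl <- clusters[samples]; cy <- cytotypes[samples]; hp <- haplotypes[samples]
  bad <- is.na(cl) | is.na(cy) | is.na(hp)
  unassignable <- samples[bad]
  ok <- samples[!bad]
  if (!length(ok))
    return(list(lineages = NULL, unassignable = unassignable))
  key <- paste(cl[ok], cy[ok], hp[ok], sep = "|")
  grp <- split(ok, key)
  o <- order(-lengths(grp), vapply(grp, function(x) sort(x)[1], character(1)))
  grp <- grp[o]
  rows <- lapply(seq_along(grp), function(k) {
    ids <- sort(grp[[k]])
    data.frame(label = letters[k],
               cytotype = unname(cy[ids[1]]),
               haplotype = unname(hp[ids[1]]),
               cluster = as.character(unname(cl[ids[1]])),
               n = length(ids),
               members = paste(ids, collapse = ","),
               populations = if (is.null(meta)) NA_character_ else
                 paste(sort(unique(meta$population[match(ids, meta$sample_id)])),
                       collapse = ","),
               stringsAsFactors = FALSE)
  })
  list(lineages = do.call(rbind, rows), unassignable = unassignable)
}
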