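#' Pipeline configuration
#'
#' Collects all inputs, stage toggles and thresholds of the end-to-end
#' analysis. Inputs may be given as file paths (the delimited-text / FASTA
#' formats of the readers), as in-memory objects, or omitted entirely, in
#' which case the packaged simulated scenario provides them.
#'
#' @param markers,meta,alignment,fcm,fcm_refs,model inputs (paths or
#'   objects); all `NULL` means simulate.
#' @param hap_groups named character vector (or two-column TSV path) mapping
#'   haplotype codes to the haplotype-group labels used by the gamete
#'   model's `haplogroup` field; defaults to the simulated scenario's
#'   mapping.
#' @param sim a [sim_config()] used when simulating.
#' @param hybrid_taxon taxon whose samples are treated as the putative
#'   hybrids.
#' @param clone_threshold band-difference threshold for clone assignment.
#' @param cluster_threshold band-difference threshold for lineage-scale
#'   clustering.
#' @param connection_limit haplotype-network connection limit (steps or
#'   `"auto"`).
#' @param weight_floor minimum retained split weight.
#' @param cv_max,fcm_tolerance flow-cytometry CV filter and aneuploidy
#'   tolerance.
#' @param composition_tolerance,dead_band composition-clause parameters of
#'   [explain_lineage()].
#' @param stages character vector of enabled stages among `"fragstats"`,
#'   `"clones"`, `"haplonet"`, `"splits"`, `"ordinate"`, `"hybrids"`.
#' @param seed seed for every source of randomness in the run.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(markers = NULL, meta = NULL, alignment = NULL,
                            fcm = NULL, fcm_refs = NULL, model = NULL,
                            hap_groups = NULL,
                            sim = NULL, hybrid_taxon = "P. alpicola",
                            clone_threshold = 5L, cluster_threshold = 20L,
                            connection_limit = "auto", weight_floor = 1e-6,
                            cv_max = 5, fcm_tolerance = 0.03,
                            composition_tolerance = 0.10, dead_band = 0.05,
                            stages = c("fragstats", "clones", "haplonet",
                                       "splits", "ordinate", "hybrids"),
                            seed = 1L, out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; input
#' fields are interpreted as file paths.
#'
#' @param path YAML file.
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

stage_log <- function(stage, t0) {
  message(sprintf("[%s] done in %.2fs", stage,
                  as.numeric(proc.time()[3] - t0)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) - fragment statistics - clone assignment
#' - haplotype network - Neighbor-Net splits - ordination - hybrid-origin
#' inference, and assembles a combined report: fragment and diversity
#' tables, shared-fragment tables, parentage rankings and cross verdicts.
#' With a fixed seed and config the report is identical between runs.
#' Progress is logged to stderr with per-stage timers.
#'
#' @param config a [pipeline_config()] (or path to a YAML config).
#' @return the report as a list (invisibly written to
#'   `out_dir/report.json` plus per-stage TSV/NEXUS/GraphML files when
#'   `out_dir` is set).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  report <- list(seed = config$seed, stages = config$stages)
  t0 <- proc.time()[3]

  # ---- inputs ----
  if (is.null(config$markers)) {
    sim <- config$sim %||% sim_config(seed = config$seed)
    ds <- simulate_dataset(sim)
    markers <- ds$markers; meta <- ds$meta; alignment <- ds$alignment
    fcm <- ds$fcm; fcm_refs <- ds$fcm_refs; model <- ds$model
    hap_map <- ds$hap_groups
    report$input <- "simulated"
  } else {
    load_in <- function(x, reader) if (is.character(x)) reader(x) else x
    markers <- load_in(config$markers, read_marker_matrix)
    meta <- load_in(config$meta, read_metadata)
    alignment <- load_in(config$alignment, read_alignment)
    fcm <- load_in(config$fcm, read_fcm)
    fcm_refs <- load_in(config$fcm_refs,
                        function(p) read.table(p, header = TRUE, sep = "\t",
                                               stringsAsFactors = FALSE))
    model <- config$model
    hap_map <- config$hap_groups
    if (is.character(hap_map) && length(hap_map) == 1L && file.exists(hap_map)) {
      hm <- read.table(hap_map, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
      hap_map <- setNames(hm[[2]], hm[[1]])
    }
    report$input <- "loaded"
  }
  stage_log("input", t0)

  out <- function(name) file.path(config$out_dir, name)
  writing <- !is.null(config$out_dir)
  if (writing) dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  hyb_ids <- active_samples(meta)
  hyb_ids <- hyb_ids[meta$taxon[match(hyb_ids, meta$sample_id)] == config$hybrid_taxon]
  parent_meta_ids <- setdiff(active_samples(meta), hyb_ids)

  # ---- fragment statistics ----
  if ("fragstats" %in% config$stages) {
    t0 <- proc.time()[3]
    totals <- fragment_totals(markers, meta, by = "taxon")
    reps <- replicate_error_rate(markers, meta)
    report$fragstats <- list(total = totals$total,
                             polymorphic = totals$polymorphic,
                             percent_polymorphic = totals$percent_polymorphic,
                             per_group = as.list(totals$per_group),
                             mean_repeatability = reps$mean_repeatability,
                             n_replicate_pairs = reps$n_pairs)
    stage_log("fragstats", t0)
  }

  # ---- clone assignment ----
  if ("clones" %in% config$stages) {
    t0 <- proc.time()[3]
    pops <- unique(meta$population[match(hyb_ids, meta$sample_id)])
    cd <- clonal_diversity(markers, meta, config$clone_threshold,
                           populations = pops)
    sh <- shared_clones(markers, meta, config$clone_threshold, samples = hyb_ids)
    report$clones <- list(threshold = config$clone_threshold,
                          diversity = cd$table, shared = sh)
    if (writing)
      write.table(cd$table, out("clones.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    stage_log("clones", t0)
  }

  # ---- haplotype network ----
  hap_group_of <- NULL
  if ("haplonet" %in% config$stages && !is.null(alignment)) {
    t0 <- proc.time()[3]
    coded <- code_alignment(alignment)
    net <- build_network(coded, limit = config$connection_limit)
    # the maternal clause needs the gamete model's group labels; the
    # network's structural components are the fallback naming
    hap_group_of <- if (!is.null(hap_map)) hap_map else haplotype_groups(net)
    htab <- haplotype_table(meta, net)
    report$haplonet <- list(n_characters = coded$n_characters,
                            n_indel = coded$n_indel, limit = net$limit,
                            n_groups = length(unique(net$components)),
                            table = htab)
    if (writing) {
      write_network_graphml(net, out("network.graphml"))
      write.table(htab, out("haplotypes.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    stage_log("haplonet", t0)
  }

  # ---- splits ----
  if ("splits" %in% config$stages) {
    t0 <- proc.time()[3]
    keep <- active_samples(meta)
    jd <- jaccard_distance(markers[keep, , drop = FALSE])
    ss <- neighbor_net(jd, weight_floor = config$weight_floor)
    taxa_groups <- split(keep, meta$taxon[match(keep, meta$sample_id)])
    coh <- group_cohesion(ss, jd, taxa_groups)
    report$splits <- list(n_splits = length(ss$splits), cohesion = coh)
    if (writing) write_splits_nexus(ss, out("splits.nex"))
    stage_log("splits", t0)
  }

  # ---- ordination ----
  if ("ordinate" %in% config$stages) {
    t0 <- proc.time()[3]
    refs <- split(parent_meta_ids,
                  meta$taxon[match(parent_meta_ids, meta$sample_id)])
    ord <- ordinate(markers, refs, focal_samples = hyb_ids)
    report$ordination <- list(mapping_error = ord$mapping_error,
                              anchors = as.data.frame(ord$anchors))
    if (writing)
      write.table(data.frame(sample_id = rownames(ord$coords), ord$coords),
                  out("coords.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    stage_log("ordinate", t0)
  }

  # ---- hybrid-origin inference ----
  if ("hybrids" %in% config$stages && length(hyb_ids)) {
    t0 <- proc.time()[3]
    pl <- NULL
    if (!is.null(fcm) && !is.null(fcm_refs))
      pl <- infer_ploidy_from_fcm(fcm, fcm_refs, cv_max = config$cv_max,
                                  tolerance = config$fcm_tolerance)
    cytotypes <- setNames(meta$cytotype, meta$sample_id)
    if (!is.null(pl)) {
      est <- setNames(pl$ploidy, pl$sample_id)
      fill <- is.na(cytotypes[names(est)])
      cytotypes[names(est)[fill]] <- est[fill]
    }
    clus_all <- assign_clones(pairwise_differences(markers, hyb_ids),
                              config$cluster_threshold)
    clusters <- setNames(rep(seq_along(clus_all), lengths(clus_all)),
                         unlist(clus_all))
    haplotypes <- setNames(meta$haplotype, meta$sample_id)
    dl <- define_lineages(hyb_ids, clusters, cytotypes, haplotypes, meta)

    grp_sets <- fragment_sets(markers, meta, by = "taxon")
    cand_sets <- grp_sets[names(grp_sets) != config$hybrid_taxon &
                            !startsWith(names(grp_sets), config$hybrid_taxon)]
    priv <- private_fragments(cand_sets)$private

    verdicts <- list(); rankings <- list()
    if (!is.null(dl$lineages)) {
      for (k in seq_len(nrow(dl$lineages))) {
        li <- dl$lineages[k, ]
        ids <- strsplit(li$members, ",")[[1]]
        lset <- fragment_sets(markers, meta, by = setNames(list(ids), li$label))[[1]]
        sc <- parentage_scores(lset, cand_sets, private = priv)
        hg <- if (!is.null(hap_group_of)) unname(hap_group_of[li$haplotype])
              else NA_character_
        hyp <- if (!is.null(model))
          enumerate_crosses(model, li$cytotype, hg) else NULL
        v <- if (!is.null(hyp))
          explain_lineage(list(label = li$label), hyp, sc,
                          tolerance = config$composition_tolerance,
                          dead_band = config$dead_band) else NULL
        rankings[[li$label]] <- sc
        verdicts[[li$label]] <- if (is.null(v)) NULL else
          list(verdict = v$verdict, reasons = v$reasons,
               haplotype_clause = if (is.na(hg)) "unknown" else "applied",
               n_hypotheses = nrow(hyp))
      }
    }
    report$hybrids <- list(ploidy = if (is.null(pl)) NULL else
                             as.data.frame(pl),
                           lineages = dl$lineages,
                           unassignable = dl$unassignable,
                           parentage = rankings, verdicts = verdicts)
    if (writing && !is.null(dl$lineages))
      write.table(dl$lineages, out("lineages.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    stage_log("hybrids", t0)
  }

  if (writing)
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  invisible(report)
}
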