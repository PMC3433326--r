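#' Taxon profile for the synthetic-data generator
#'
#' Describes one parental taxon/cytotype: its per-locus band frequencies, its
#' plastid haplotype pool with haplotype-group labels, the ploidies of the
#' gametes it puts out (female gametes may include unreduced, apomeiotically
#' formed eggs, encoded simply as additional ploidies), and the slope of its
#' flow-cytometry ratio-vs-ploidy calibration.
#'
#' @param taxon taxon name.
#' @param cytotype integer ploidy multiplier (x).
#' @param freqs numeric vector of per-locus band frequencies in `[0, 1]`,
#'   named by locus label.
#' @param haplotypes named character vector: names are haplotype codes of the
#'   taxon's pool, values are haplotype-group labels.
#' @param female_gametes,male_gametes integer vectors of gamete ploidies.
#' @param fcm_beta fluorescence ratio per ploidy unit for the taxon's
#'   species.
#' @return an object of class `"taxon_profile"`.
#' @export
taxon_profile <- function(taxon, cytotype, freqs, haplotypes,
                          female_gametes, male_gametes, fcm_beta = 0.5) {
  if (any(freqs < 0 | freqs > 1)) stop_hs("band frequencies must be in [0, 1]")
  if (is.null(names(freqs))) names(freqs) <- paste0("L", seq_along(freqs))
  if (!length(haplotypes) || is.null(names(haplotypes)))
    stop_hs("haplotype pool must be a named character vector (haplotype -> group)")
  female_gametes <- sort(unique(as.integer(female_gametes)))
  male_gametes <- sort(unique(as.integer(male_gametes)))
  if (!length(female_gametes) || !length(male_gametes))
    stop_hs("gamete ploidy sets must be nonempty")
  if (any(c(female_gametes, male_gametes) < 1L))
    stop_hs("gamete ploidies must be positive integers")
  structure(list(taxon = taxon, cytotype = as.integer(cytotype), freqs = freqs,
                 haplotypes = haplotypes, female_gametes = female_gametes,
                 male_gametes = male_gametes, fcm_beta = fcm_beta),
            class = "taxon_profile")
}

#' Simulation configuration
#'
#' Defaults encode the statistical structure the analysis assumes: 241
#' scorable fragments, a per-band scoring error of 1.24% (mean replicate
#' repeatability 98.76%), and for hybrids 17% loss of parental-union bands
#' plus 2.4% de novo band gain.
#'
#' @param n_loci number of scored fragments.
#' @param epsilon per-band scoring error rate (probability a band flips
#'   between independent scorings of the same genotype).
#' @param loss probability a parental-union band is absent from a hybrid.
#' @param denovo probability a band absent from both parents appears in a
#'   hybrid.
#' @param fcm_noise relative (multiplicative) noise of fluorescence ratios.
#' @param between_steps minimum mutational separation between haplotype
#'   groups in simulated alignments.
#' @param backcross_rounds rounds of recurrent-parent backcrossing used to
#'   build the introgressed lineage of the packaged scenario.
#' @param pop_size default samples per simulated population.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_loci = 241L, epsilon = 0.0124, loss = 0.17,
                       denovo = 0.024, fcm_noise = 0.01, between_steps = 8L,
                       backcross_rounds = 3L, pop_size = 10L, seed = 1L) {
  rates <- c(epsilon = epsilon, loss = loss, denovo = denovo)
  if (any(rates < 0 | rates > 1)) stop_hs("rates must be in [0, 1]")
  structure(list(n_loci = as.integer(n_loci), epsilon = epsilon, loss = loss,
                 denovo = denovo, fcm_noise = fcm_noise,
                 between_steps = as.integer(between_steps),
                 backcross_rounds = as.integer(backcross_rounds),
                 pop_size = as.integer(pop_size), seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a panel of individuals of one parental taxon
#'
#' Each sample carries each band independently with the profile's per-locus
#' frequency (Bernoulli draws); its haplotype is drawn uniformly from the
#' profile's pool.
#'
#' @param profile a [taxon_profile()].
#' @param n number of individuals (>= 1).
#' @param population population code for the metadata.
#' @param prefix sample-id prefix.
#' @param seed optional RNG seed; `NULL` uses the current RNG state.
#' @return list with elements `markers` ([marker_matrix()]) and `meta`
#'   ([sample_meta()]).
#' @export
simulate_parental_panel <- function(profile, n, population = "Pop1",
                                    prefix = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (n < 1L) stop_hs("n must be >= 1")
  L <- length(profile$freqs)
  m <- matrix(rbinom(n * L, 1L, rep(profile$freqs, each = n)), nrow = n)
  prefix <- prefix %||% gsub("[^A-Za-z0-9]", "", profile$taxon)
  ids <- sprintf("%s_%s_%02d", prefix, population, seq_len(n))
  dimnames(m) <- list(ids, names(profile$freqs))
  haps <- sample(names(profile$haplotypes), n, replace = TRUE)
  meta <- sample_meta(data.frame(
    sample_id = ids, taxon = profile$taxon, population = population,
    cytotype = profile$cytotype, locality = population, haplotype = haps,
    stringsAsFactors = FALSE))
  list(markers = marker_matrix(m), meta = meta)
}

#' Simulate clonal copies of a founder genotype
#'
#' Clones differ from the founder only by independent per-band scoring flips
#' at rate `epsilon` (the replicate error model).
#'
#' @param founder 0/1 vector (a marker-matrix row).
#' @param n number of clonal copies.
#' @param epsilon per-band flip rate in `[0, 1]`.
#' @param ids optional sample ids (length `n`).
#' @param seed optional RNG seed.
#' @return a [marker_matrix()] of `n` rows.
#' @export
simulate_clones <- function(founder, n, epsilon, ids = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (epsilon < 0 || epsilon > 1) stop_hs("epsilon must be in [0, 1]")
  n <- as.integer(n)
  if (n < 1L) stop_hs("n must be >= 1")
  L <- length(founder)
  flips <- matrix(rbinom(n * L, 1L, epsilon), nrow = n)
  m <- sweep(flips, 2, as.integer(founder), FUN = function(f, x) abs(x - f))
  if (is.null(ids)) ids <- sprintf("clone_%02d", seq_len(n))
  dimnames(m) <- list(ids, names(founder) %||% paste0("L", seq_len(L)))
  marker_matrix(m)
}

#' Combine two band patterns as a hybridisation event
#'
#' The additive model of dominant markers in allopolyploids: the offspring
#' starts from the union of the parental band sets, each union band is then
#' lost with probability `loss`, and each band absent from both parents
#' appears de novo with probability `denovo`.
#'
#' @param a,b 0/1 band vectors over the same loci.
#' @param loss,denovo rates in `[0, 1]`.
#' @return 0/1 integer vector.
#' @export
hybridize_bands <- function(a, b, loss = 0.17, denovo = 0.024) {
  if (length(a) != length(b)) stop_hs("band vectors differ in length")
  u <- as.integer(a | b)
  keep <- rbinom(length(u), 1L, 1 - loss)
  gain <- rbinom(length(u), 1L, denovo)
  out <- as.integer(ifelse(u == 1L, keep, gain))
  names(out) <- names(a)
  out
}

#' Simulate an F1 hybrid individual
#'
#' Bands follow [hybridize_bands()]; the haplotype is the mother's (maternal
#' plastid inheritance); the cytotype is the sum of the fusing gamete
#' ploidies. The requested gamete ploidies must belong to the parents'
#' gamete sets, otherwise the cross is impossible.
#'
#' @param mother,father lists with elements `profile` (a [taxon_profile()]),
#'   `bands` (0/1 vector) and, for the mother, `haplotype`.
#' @param egg_ploidy,pollen_ploidy gamete ploidies of the cross.
#' @param loss,denovo band loss / de novo gain rates.
#' @param seed optional RNG seed.
#' @return list with `bands`, `cytotype`, `haplotype`, `egg_ploidy`,
#'   `pollen_ploidy`.
#' @export
simulate_hybrid <- function(mother, father, egg_ploidy, pollen_ploidy,
                            loss = 0.17, denovo = 0.024, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!egg_ploidy %in% mother$profile$female_gametes)
    stop_hs("impossible cross: ", mother$profile$taxon, " does not form ",
            egg_ploidy, "x eggs")
  if (!pollen_ploidy %in% father$profile$male_gametes)
    stop_hs("impossible cross: ", father$profile$taxon, " does not form ",
            pollen_ploidy, "x pollen")
  bands <- hybridize_bands(mother$bands, father$bands, loss, denovo)
  list(bands = bands, cytotype = as.integer(egg_ploidy + pollen_ploidy),
       haplotype = mother$haplotype,
       egg_ploidy = as.integer(egg_ploidy),
       pollen_ploidy = as.integer(pollen_ploidy))
}

#' Simulate a haplotype alignment with a known group structure
#'
#' Generates aligned sequences for the requested haplotypes by mutating a
#' random root sequence along a star-per-group topology: every group gets
#' `ceiling(between_steps / 2)` private substitutions shared by its members
#' (so groups are at least `between_steps` apart), and every non-ancestral
#' haplotype gets one further private substitution (so within-group nearest
#' neighbours are 1 step apart). Indels are single-column gaps shared by all
#' members of one group; poly-A stretches of per-sequence ragged length are
#' written into the excluded regions.
#'
#' @param groups named list: group label -> character vector of haplotype
#'   codes.
#' @param between_steps minimum mutational distance between groups.
#' @param length_bp total alignment length.
#' @param n_indels number of codable single-column indels.
#' @param n_polya number of poly-A regions (each becomes an excluded region).
#' @param seed optional RNG seed.
#' @return list with `alignment` (a [haplo_alignment()] whose sequence ids
#'   are the haplotype codes) and `groups` (named character vector haplotype
#'   -> group).
#' @export
simulate_haplotypes <- function(groups, between_steps = 8L, length_bp = 550L,
                                n_indels = 3L, n_polya = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  haps <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(haps)) stop_hs("haplotype codes must be unique across groups")
  grp_of <- rep(names(groups), lengths(groups))
  names(grp_of) <- haps

  root <- sample(c("A", "C", "G", "T"), length_bp, replace = TRUE)
  polya_len <- 9L
  polya_starts <- round(seq(0.25, 0.75, length.out = n_polya) * length_bp)
  excluded <- cbind(start = polya_starts, end = polya_starts + polya_len - 1L)
  polya_cols <- unlist(lapply(seq_len(n_polya),
                              function(i) excluded[i, 1]:excluded[i, 2]))
  root[polya_cols] <- "A"

  free <- setdiff(seq_len(length_bp), polya_cols)
  k_grp <- ceiling(between_steps / 2)
  need <- length(groups) * k_grp + length(haps) + n_indels
  mut_cols <- sample(free, need)
  ptr <- 0L
  take <- function(k) { cols <- mut_cols[ptr + seq_len(k)]; ptr <<- ptr + k; cols }

  other <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)
  seqs <- matrix(rep(root, length(haps)), nrow = length(haps), byrow = TRUE)
  rownames(seqs) <- haps
  for (g in names(groups)) {
    cols <- take(k_grp)
    members <- groups[[g]]
    for (cc in cols) seqs[members, cc] <- other(root[cc])
    # star topology: first haplotype is the group ancestor
    for (h in members[-1]) {
      cc <- take(1L)
      seqs[h, cc] <- other(root[cc])
    }
  }
  # group-shared single-column indels
  indel_groups <- rep(names(groups), length.out = n_indels)
  for (i in seq_len(n_indels)) {
    cc <- take(1L)
    seqs[groups[[indel_groups[i]]], cc] <- "-"
  }
  # ragged poly-A tails: shorten the stretch by 0-3 positions per sequence
  for (i in seq_len(n_polya)) {
    for (r in seq_len(nrow(seqs))) {
      trim <- sample(0:3, 1)
      if (trim > 0) seqs[r, (excluded[i, 2] - trim + 1L):excluded[i, 2]] <- "-"
    }
  }
  list(alignment = haplo_alignment(seqs, excluded_regions = excluded),
       groups = grp_of)
}

#' Simulate flow-cytometry ratio records
#'
#' Ratios follow `beta_species * ploidy * (1 + N(0, noise))`; CVs are drawn
#' uniformly below the acceptance threshold unless a sample is listed in
#' `high_cv` (those receive CVs just above 5%).
#'
#' @param ploidies data frame with `sample_id`, `species`, `ploidy` (true
#'   ploidy, possibly fractional for planted aneuploids).
#' @param betas named numeric vector of per-species slopes.
#' @param noise relative ratio noise (standard deviation).
#' @param high_cv sample ids to receive CVs above the filter.
#' @param seed optional RNG seed.
#' @return an [fcm_records()] data frame.
#' @export
simulate_fcm <- function(ploidies, betas, noise = 0.01, high_cv = character(0),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  beta <- betas[ploidies$species]
  if (any(is.na(beta))) stop_hs("no beta for species: ",
                                paste(unique(ploidies$species[is.na(beta)]), collapse = ", "))
  ratio <- beta * ploidies$ploidy * (1 + rnorm(nrow(ploidies), 0, noise))
  cv <- runif(nrow(ploidies), 1.5, 4.8)
  cv[ploidies$sample_id %in% high_cv] <- runif(sum(ploidies$sample_id %in% high_cv), 5.05, 5.2)
  fcm_records(data.frame(sample_id = ploidies$sample_id, ratio = ratio,
                         cv_percent = round(cv, 2), species = ploidies$species,
                         stringsAsFactors = FALSE))
}

# ---- packaged scenario -----------------------------------------------------

# Band-frequency profiles of the packaged scenario. Locus blocks (fractions
# of the locus count) give the parents realistic overlap: a shared core, an
# argentea-specific and a pusilla-specific block, small fully private blocks,
# and an outgroup block; a tail of loci is carried by nobody, so de novo
# gains have somewhere to land.
scenario_profiles <- function(n_loci = 241L) {
  L <- as.integer(n_loci)
  cut <- function(f) max(1L, round(f * L / 241))
  sizes <- c(core = cut(40), arg = cut(85), arg6_priv = cut(6), arg2_priv = cut(1),
             pus = cut(95), pus_priv = cut(6), aur = cut(8))
  idx <- split(seq_len(min(L, sum(sizes))), rep(seq_along(sizes), sizes)[seq_len(min(L, sum(sizes)))])
  names(idx) <- names(sizes)[seq_along(idx)]
  zero <- setNames(numeric(L), paste0("L", seq_len(L)))

  f_pus <- zero; f_pus[idx$core] <- 0.95; f_pus[idx$pus] <- 0.95; f_pus[idx$pus_priv] <- 0.97
  f_a6 <- zero; f_a6[idx$core] <- 0.95; f_a6[idx$arg] <- 0.95; f_a6[idx$arg6_priv] <- 0.97
  f_a2 <- zero; f_a2[idx$core[seq_len(length(idx$core) %/% 2)]] <- 0.95
  f_a2[idx$arg[seq_len(length(idx$arg) %/% 2)]] <- 0.95; f_a2[idx$arg2_priv] <- 0.97
  f_aur <- zero; f_aur[idx$core[seq_len(length(idx$core) %/% 2)]] <- 0.7
  f_aur[idx$aur] <- 0.95

  list(
    pusilla = taxon_profile("P. pusilla", 4L, f_pus, c(W = "verna"),
                            female_gametes = c(2L, 3L, 5L, 6L, 7L),
                            male_gametes = c(2L, 3L), fcm_beta = 0.62),
    argentea2x = taxon_profile("P. argentea", 2L, f_a2, c(I = "argentea"),
                               female_gametes = 1L, male_gametes = 1L,
                               fcm_beta = 0.55),
    argentea6x = taxon_profile("P. argentea", 6L, f_a6,
                               c(E = "argentea", F = "argentea", G = "argentea"),
                               female_gametes = 6L, male_gametes = 3L,
                               fcm_beta = 0.55),
    aurea = taxon_profile("P. aurea", 2L, f_aur, c(T = "verna"),
                          female_gametes = 1L, male_gametes = 1L,
                          fcm_beta = 0.50))
}

#' Simulate a complete multi-marker dataset with known truth
#'
#' The packaged `"alpicola"` scenario emulates the structure of a hybrid
#' complex: two parental cytotypes of one species (2x/6x), a second parental
#' species (4x), an outgroup control taxon, and three clonal hybrid lineages
#' of contrasting origin: lineage `a`, a pentaploid F1 (reduced 2x egg of the
#' 4x species fertilised by 3x pollen of the hexaploid); lineage `b`, a
#' hexaploid of complex origin carrying the hexaploid parent's haplotype
#' (planted in two populations as one clone, no single model cross can
#' produce it); and lineage `c`, a pentaploid recurrently backcrossed toward
#' the 4x species. Replicate scorings, a haplotype alignment with three
#' groups, and flow-cytometry records (including a planted aneuploid and a
#' high-CV failure) are emitted together with truth tables for every stage.
#'
#' @param config a [sim_config()].
#' @param scenario scenario name; only `"alpicola"` is defined.
#' @return list with `markers`, `meta`, `alignment`, `hap_groups`, `fcm`,
#'   `fcm_refs`, `model` (a [gamete_model()]), `profiles`, `truth` (lists of
#'   per-sample clone, lineage and ploidy truth plus lineage definitions) and
#'   `config`.
#' @export
simulate_dataset <- function(config = sim_config(), scenario = "alpicola") {
  if (!identical(scenario, "alpicola")) stop_hs("unknown scenario: ", scenario)
  set.seed(config$seed)
  prof <- scenario_profiles(config$n_loci)
  eps <- config$epsilon

  panels <- list(
    simulate_parental_panel(prof$pusilla, config$pop_size, "P_PUS", "pus"),
    simulate_parental_panel(prof$argentea2x, max(4L, config$pop_size - 2L), "P_ARG2", "arg2"),
    simulate_parental_panel(prof$argentea6x, config$pop_size, "P_ARG6", "arg6"),
    simulate_parental_panel(prof$aurea, max(4L, config$pop_size - 4L), "P_AUR", "aur"))
  markers <- do.call(rbind, lapply(panels, function(p) unclass(p$markers)))
  meta <- do.call(rbind, lapply(panels, function(p) as.data.frame(p$meta)))

  pick <- function(pat) markers[grep(pat, rownames(markers))[1], ]
  mother_pus <- list(profile = prof$pusilla, bands = pick("^pus"), haplotype = "W")
  father_a6 <- list(profile = prof$argentea6x, bands = pick("^arg6"))

  # lineage a: F1, 4x-species 2x egg x hexaploid 3x pollen -> 5x, haplotype W
  f1 <- simulate_hybrid(mother_pus, father_a6, 2L, 3L,
                        loss = config$loss, denovo = config$denovo)

  # lineage b: complex origin; bands additive over the same parents but the
  # maternal haplotype is the hexaploid's (G) and the cytotype hexaploid --
  # no single cross in the gamete model can produce this combination
  b_bands <- hybridize_bands(pick("^arg6"), pick("^pus"),
                             loss = config$loss, denovo = config$denovo)

  # lineage c: recurrent backcrossing of the F1 toward the 4x species
  c_bands <- f1$bands
  for (i in seq_len(config$backcross_rounds)) {
    recur <- markers[grep("^pus", rownames(markers))[1L + i], ]
    c_bands <- hybridize_bands(c_bands, recur,
                               loss = config$loss, denovo = config$denovo)
  }

  n_a <- config$pop_size
  n_b1 <- max(4L, config$pop_size - 3L); n_b2 <- max(4L, config$pop_size - 3L)
  n_c <- max(4L, config$pop_size - 2L)
  lin <- rbind(
    data.frame(lineage = "a", population = "P_LINA",
               id = sprintf("alpA_P_LINA_%02d", seq_len(n_a))),
    data.frame(lineage = "b", population = "P_LINB1",
               id = sprintf("alpB_P_LINB1_%02d", seq_len(n_b1))),
    data.frame(lineage = "b", population = "P_LINB2",
               id = sprintf("alpB_P_LINB2_%02d", seq_len(n_b2))),
    data.frame(lineage = "c", population = "P_LINC",
               id = sprintf("alpC_P_LINC_%02d", seq_len(n_c))))
  founders <- list(a = f1$bands, b = b_bands, c = c_bands)
  hap_of <- c(a = "W", b = "G", c = "W")
  cyt_of <- c(a = 5L, b = 6L, c = 5L)
  hyb <- do.call(rbind, lapply(unique(lin$lineage), function(lg) {
    ids <- lin$id[lin$lineage == lg]
    unclass(simulate_clones(founders[[lg]], length(ids), eps, ids = ids))
  }))
  markers <- rbind(markers, hyb)
  meta <- rbind(meta, data.frame(
    sample_id = lin$id, taxon = "P. alpicola", population = lin$population,
    cytotype = cyt_of[lin$lineage], locality = lin$population,
    haplotype = hap_of[lin$lineage], replicate_of = NA_character_,
    excluded = FALSE, excluded_reason = NA_character_,
    stringsAsFactors = FALSE))

  # replicate scorings: ~5% of samples re-scored with the same error model
  rep_src <- rownames(markers)[round(seq(1, nrow(markers), length.out = 4))]
  rep_rows <- do.call(rbind, lapply(rep_src, function(s)
    unclass(simulate_clones(markers[s, ], 1L, eps, ids = paste0(s, "_rep")))))
  markers <- rbind(markers, rep_rows)
  meta <- rbind(meta, data.frame(
    sample_id = paste0(rep_src, "_rep"),
    taxon = meta$taxon[match(rep_src, meta$sample_id)],
    population = meta$population[match(rep_src, meta$sample_id)],
    cytotype = meta$cytotype[match(rep_src, meta$sample_id)],
    locality = meta$locality[match(rep_src, meta$sample_id)],
    haplotype = meta$haplotype[match(rep_src, meta$sample_id)],
    replicate_of = rep_src, excluded = FALSE,
    excluded_reason = NA_character_, stringsAsFactors = FALSE))
  meta <- sample_meta(meta)
  markers <- marker_matrix(markers)

  # haplotype alignment: the two parental groups plus a third, unsampled one
  hapsim <- simulate_haplotypes(
    list(argentea = c("E", "F", "G", "I"), verna = c("W", "T", "U"), relic = "Q"),
    between_steps = config$between_steps)

  # flow cytometry: true ploidies, one planted aneuploid, one high-CV failure
  species <- meta$taxon[is.na(meta$replicate_of)]
  ids <- meta$sample_id[is.na(meta$replicate_of)]
  true_pl <- as.numeric(meta$cytotype[is.na(meta$replicate_of)])
  aneu_id <- lin$id[lin$lineage == "b"][1]
  true_pl[ids == aneu_id] <- 6.3
  highcv_id <- lin$id[lin$lineage == "b"][2]
  betas <- c("P. pusilla" = prof$pusilla$fcm_beta,
             "P. argentea" = prof$argentea6x$fcm_beta,
             "P. aurea" = prof$aurea$fcm_beta,
             "P. alpicola" = 0.585)
  fcm <- simulate_fcm(data.frame(sample_id = ids, species = species,
                                 ploidy = true_pl, stringsAsFactors = FALSE),
                      betas, noise = config$fcm_noise, high_cv = highcv_id)
  # chromosome-counted reference individuals; none for the outgroup taxon
  fcm_refs <- data.frame(
    sample_id = c(grep("^pus", ids, value = TRUE)[1],
                  grep("^arg2", ids, value = TRUE)[1],
                  grep("^arg6", ids, value = TRUE)[1],
                  lin$id[lin$lineage == "a"][1],
                  lin$id[lin$lineage == "b"][3]),
    ploidy = c(4L, 2L, 6L, 5L, 6L), stringsAsFactors = FALSE)

  model <- gamete_model(list(prof$pusilla, prof$argentea2x, prof$argentea6x,
                             prof$aurea),
                        hap_groups = hapsim$groups)

  truth <- list(
    clones = data.frame(sample_id = lin$id, clone = paste0("clone_", lin$lineage),
                        stringsAsFactors = FALSE),
    lineages = data.frame(sample_id = lin$id, lineage = lin$lineage,
                          stringsAsFactors = FALSE),
    lineage_info = data.frame(
      lineage = c("a", "b", "c"),
      origin = c("f1", "complex", "backcross"),
      cytotype = cyt_of, haplotype = hap_of,
      mother = c("P. pusilla", NA, "P. pusilla"),
      father = c("P. argentea", NA, "P. argentea"),
      mother_cytotype = c(4L, NA, 4L), father_cytotype = c(6L, NA, 6L),
      egg = c(2L, NA, NA), pollen = c(3L, NA, NA),
      stringsAsFactors = FALSE, row.names = NULL),
    ploidies = data.frame(sample_id = ids, ploidy = true_pl,
                          stringsAsFactors = FALSE),
    aneuploids = aneu_id, high_cv = highcv_id,
    founders = founders)

  list(markers = markers, meta = meta, alignment = hapsim$alignment,
       hap_groups = hapsim$groups, fcm = fcm, fcm_refs = fcm_refs,
       model = model, profiles = prof, truth = truth, config = config)
}
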