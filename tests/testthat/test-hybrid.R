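# the parental gamete-ploidy model used throughout: 1x/1x for the diploid,
# 3x/6x for the hexaploid (apomeiotic eggs), 2x,3x / 2x,3x,5x,6x,7x for the
# 4x-7x species with facultative unreduced eggs
study_model <- function() {
  gamete_model(data.frame(
    taxon = c("P. argentea", "P. argentea", "P. pusilla"),
    cytotype = c(2L, 6L, 4L),
    haplogroup = c("argentea", "argentea", "verna"),
    female = c("1", "6", "2,3,5,6,7"),
    male = c("1", "3", "2,3"),
    stringsAsFactors = FALSE))
}

test_that("ploidy attribution regresses ratios through the origin", {
  beta <- 0.55
  rec <- fcm_records(data.frame(
    sample_id = c("ref2", "ref6", "q5", "badcv", "aneu", "orphan"),
    ratio = c(2 * beta, 6 * beta, 5 * beta, 4 * beta, 6.3 * beta, 1.0),
    cv_percent = c(2.1, 2.5, 3.0, 5.13, 2.2, 2.0),
    species = c(rep("P. argentea", 5), "P. frigida")))
  refs <- data.frame(sample_id = c("ref2", "ref6"), ploidy = c(2L, 6L))
  out <- infer_ploidy_from_fcm(rec, refs, cv_max = 5, tolerance = 0.03)

  expect_equal(out$ploidy[out$sample_id == "q5"], 5L)       # exact proportionality
  expect_equal(out$status[out$sample_id == "badcv"], "excluded_cv")
  expect_equal(out$status[out$sample_id == "orphan"], "cannot_attribute")
  aneu <- out[out$sample_id == "aneu", ]
  expect_equal(aneu$ploidy, 6L)
  expect_true(aneu$possible_aneuploid)                       # 5% > 3% tolerance
  expect_false(out$possible_aneuploid[out$sample_id == "q5"])
})

test_that("ploidy recovery is exact at 1 percent ratio noise", {
  set.seed(51)
  pl <- data.frame(sample_id = sprintf("s%02d", 1:60), species = "X",
                   ploidy = rep(2:7, each = 10))
  fcm <- simulate_fcm(pl, c(X = 0.6), noise = 0.01)
  refs <- data.frame(sample_id = c("s01", "s51"), ploidy = c(2L, 7L))
  out <- infer_ploidy_from_fcm(fcm, refs)
  expect_equal(out$ploidy, pl$ploidy)
})

test_that("cross enumeration honours gamete sets and maternal haplotype", {
  model <- study_model()

  # pentaploid with the 4x species' haplotype group: a unique cross
  h5 <- enumerate_crosses(model, 5, "verna")
  expect_equal(nrow(h5), 1L)
  expect_equal(h5$mother, "P. pusilla")
  expect_equal(h5$father, "P. argentea")
  expect_equal(h5$father_cytotype, 6L)
  expect_equal(c(h5$egg, h5$pollen), c(2L, 3L))
  expect_equal(h5$maternal_fraction, 0.4)

  # hexaploid with the argentea-type haplotype: no single cross exists
  expect_equal(nrow(enumerate_crosses(model, 6, "argentea")), 0L)

  # enabling intrataxon crosses adds e.g. 2x egg + 3x pollen within the 4x species
  h5s <- enumerate_crosses(model, 5, "verna", allow_intrataxon = TRUE)
  expect_gt(nrow(h5s), nrow(h5))

  # closure: every hypothesis re-validates against the model
  for (target in 2:9) for (hg in c("verna", "argentea")) {
    hy <- enumerate_crosses(model, target, hg)
    if (!nrow(hy)) next
    for (i in seq_len(nrow(hy))) {
      mi <- which(model$taxon == hy$mother[i] & model$cytotype == hy$mother_cytotype[i])
      fi <- which(model$taxon == hy$father[i] & model$cytotype == hy$father_cytotype[i])
      expect_true(hy$egg[i] %in% model$female[[mi]])
      expect_true(hy$pollen[i] %in% model$male[[fi]])
      expect_equal(hy$egg[i] + hy$pollen[i], target)
      expect_equal(model$haplogroup[mi], hg)
    }
  }
  expect_error(enumerate_crosses(model, 1, "verna"), ">= 2")

  # NA haplogroup skips the maternal clause entirely
  h_na <- enumerate_crosses(model, 5, NA)
  expect_true(all(c("P. pusilla") %in% h_na$mother))
  expect_gte(nrow(h_na), nrow(h5))
})

test_that("parentage scores reproduce published-style shared percentages", {
  # a 115-fragment lineage sharing 107 with a 205-fragment candidate (93.04%)
  # and 104 with a 177-fragment candidate (90.43%)
  lin <- fset("lineage a", paste0("L", 1:115))
  pus <- fset("P. pusilla", paste0("L", c(1:107, 1000:1097)))
  arg6 <- fset("P. argentea (6x)", paste0("L", c(1:104, 2000:2072)))
  out <- parentage_scores(lin, list(pus, arg6))
  expect_equal(out$shared_pct, c(93.04, 90.43))
  expect_equal(out$candidate[1], "P. pusilla")
  expect_equal(out$retention, c(107 / 205, 104 / 177))

  # private-band containment reported as "k/n"
  priv <- list("P. pusilla" = paste0("L", c(1:2, 1000:1003)))
  out2 <- parentage_scores(lin, list(pus), private = priv)
  expect_equal(out2$private_carried, "2/6")

  expect_error(parentage_scores(lin, list()), "empty candidate")
})

test_that("additivity classification partitions union and non-union loci", {
  mom <- c(1L, 1L, 0L, 0L, 0L); dad <- c(0L, 1L, 1L, 0L, 0L)
  # exact union -> nothing lost, nothing de novo
  r <- classify_additivity(as.integer(mom | dad), mom, dad)
  expect_equal(r[c("additive", "lost", "denovo")], list(additive = 3L, lost = 0L, denovo = 0L))

  # all-zero hybrid -> everything lost
  r2 <- classify_additivity(rep(0L, 5), mom, dad)
  expect_equal(r2$lost, r2$union_size)

  expect_error(classify_additivity(c(1L, 0L), mom, dad), "locus sets")

  # conservation on random instances
  set.seed(52)
  for (i in 1:10) {
    h <- rbinom(50, 1, 0.5); a <- rbinom(50, 1, 0.5); b <- rbinom(50, 1, 0.5)
    r3 <- classify_additivity(h, a, b)
    expect_equal(r3$additive + r3$lost, r3$union_size)
    expect_equal(r3$denovo + sum(!(a | b) & h == 0L), 50L - r3$union_size)
  }

  # simulated rates converge on the generating loss / de novo parameters
  set.seed(53)
  L <- 10000
  a <- rbinom(L, 1, 0.6); b <- rbinom(L, 1, 0.6)
  h <- hybridize_bands(a, b, loss = 0.17, denovo = 0.024)
  r4 <- classify_additivity(h, a, b)
  expect_lt(abs(r4$lost_rate - 0.17), 3 * sqrt(0.17 * 0.83 / r4$union_size))
  expect_lt(abs(r4$denovo_rate - 0.024),
            3 * sqrt(0.024 * 0.976 / (L - r4$union_size)))
})

test_that("single-event verdicts weigh haplotype and composition clauses", {
  model <- study_model()
  h5 <- enumerate_crosses(model, 5, "verna")

  balanced <- data.frame(
    candidate = c("P. pusilla", "P. argentea (6x)", "P. argentea (2x)"),
    retention = c(0.82, 0.84, 0.80))
  class(balanced) <- c("parentage_scores", "data.frame")
  v1 <- explain_lineage(list(label = "a"), h5, balanced)
  expect_equal(v1$verdict, "single-event")

  # strongly mother-leaning composition contradicts a 0.4 maternal fraction
  skewed <- balanced; skewed$retention <- c(0.90, 0.60, 0.60)
  v2 <- explain_lineage(list(label = "c"), h5, skewed)
  expect_equal(v2$verdict, "not-single-event")
  expect_match(v2$reasons, "mother retention")

  # no haplotype-compatible cross
  v3 <- explain_lineage(list(label = "b"),
                        enumerate_crosses(model, 6, "argentea"), balanced)
  expect_equal(v3$verdict, "not-single-event")
  expect_match(v3$reasons, "no haplotype-compatible")

  # inside the dead band either leaning passes
  h6 <- enumerate_crosses(model, 6, "verna")
  expect_true(any(abs(h6$maternal_fraction - 0.5) < 0.05))
  v4 <- explain_lineage(list(label = "x"), h6, skewed)
  expect_equal(v4$verdict, "single-event")
})

test_that("lineages are maximal homogeneous annotation classes", {
  samples <- paste0("s", 1:7)
  clusters <- setNames(c(1, 1, 1, 2, 2, 3, NA), samples)
  cytos <- setNames(c(5, 5, 5, 6, 6, 5, 5), samples)
  haps <- setNames(c("W", "W", "W", "G", "G", "W", "W"), samples)
  dl <- define_lineages(samples, clusters, cytos, haps)
  expect_equal(nrow(dl$lineages), 3L)
  expect_equal(dl$lineages$label, c("a", "b", "c"))   # by decreasing size
  expect_equal(dl$lineages$n, c(3L, 2L, 1L))
  expect_equal(dl$unassignable, "s7")

  # all samples identical in annotations -> one lineage
  one <- define_lineages(samples[1:3], setNames(rep(1, 3), samples[1:3]),
                         cytos[1:3], haps[1:3])
  expect_equal(nrow(one$lineages), 1L)
})

test_that("the planted scenario yields the planted lineages and verdicts", {
  ds <- simulate_dataset(sim_config(seed = 61))
  rpt <- run_pipeline(pipeline_config(sim = sim_config(seed = 61), seed = 61,
                                      stages = c("haplonet", "hybrids")))
  lg <- rpt$hybrids$lineages
  expect_equal(nrow(lg), 3L)
  # member sets match the planted lineages exactly
  got <- lapply(strsplit(lg$members, ","), sort)
  want <- lapply(split(ds$truth$lineages$sample_id, ds$truth$lineages$lineage), sort)
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(want, paste, "", collapse = ","))

  # verdict by planted origin
  origin_of <- setNames(ds$truth$lineage_info$origin, ds$truth$lineage_info$lineage)
  for (k in seq_len(nrow(lg))) {
    planted <- names(want)[vapply(want, function(w)
      identical(w, got[[k]]), logical(1))]
    v <- rpt$hybrids$verdicts[[lg$label[k]]]
    if (origin_of[planted] == "f1") expect_equal(v$verdict, "single-event")
    else expect_equal(v$verdict, "not-single-event")
  }

  # a clone spanning two populations is flagged
  sh <- shared_clones(ds$markers, ds$meta, threshold = 20,
                      samples = ds$truth$clones$sample_id)
  expect_true(!is.null(sh) && any(grepl("P_LINB1", sh$populations) &
                                    grepl("P_LINB2", sh$populations)))
})
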