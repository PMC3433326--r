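test_that("parental panels follow the band-frequency profiles", {
  prof1 <- taxon_profile("T", 2L, setNames(rep(1, 20), paste0("L", 1:20)),
                         c(H = "g"), 1L, 1L)
  pan <- simulate_parental_panel(prof1, 5, seed = 1)
  expect_true(all(pan$markers == 1L))

  # Bernoulli(0.5) presence fraction within 3 sigma of 0.5
  prof2 <- taxon_profile("T", 2L, setNames(rep(0.5, 200), paste0("L", 1:200)),
                         c(H = "g"), 1L, 1L)
  pan2 <- simulate_parental_panel(prof2, 50, seed = 2)
  n <- length(pan2$markers)
  expect_lt(abs(mean(pan2$markers) - 0.5), 3 * sqrt(0.25 / n))

  # determinism under seed
  a <- simulate_parental_panel(prof2, 10, seed = 42)
  b <- simulate_parental_panel(prof2, 10, seed = 42)
  expect_identical(a$markers, b$markers)
  expect_identical(a$meta$haplotype, b$meta$haplotype)
  expect_error(simulate_parental_panel(prof1, 0), ">= 1")
})

test_that("clone simulation reproduces the scoring-error model", {
  founder <- setNames(rep(c(1L, 0L), length.out = 241), paste0("L", 1:241))
  expect_true(all(simulate_clones(founder, 4, 0, seed = 1) ==
                    matrix(founder, 4, 241, byrow = TRUE)))
  # epsilon = 1 flips every band
  z <- setNames(rep(0L, 50), paste0("L", 1:50))
  expect_true(all(simulate_clones(z, 3, 1, seed = 1) == 1L))

  # expected pairwise difference 2 e (1 - e) L between two noisy copies
  eps <- 0.0124; L <- 241
  set.seed(3)
  diffs <- replicate(400, {
    cl <- simulate_clones(founder, 2, eps)
    sum(cl[1, ] != cl[2, ])
  })
  expected <- 2 * eps * (1 - eps) * L   # ~5.9
  se <- sqrt(expected / 400)            # Poisson-scale error of the mean
  expect_lt(abs(mean(diffs) - expected), 3 * se)
})

test_that("hybrid bands are additive with loss and de novo gain", {
  L <- 30
  mom_prof <- taxon_profile("M", 4L, setNames(rep(0.9, L), paste0("L", 1:L)),
                            c(W = "g1"), female_gametes = c(2L, 3L),
                            male_gametes = 2L)
  dad_prof <- taxon_profile("D", 6L, setNames(rep(0.9, L), paste0("L", 1:L)),
                            c(E = "g2"), female_gametes = 6L, male_gametes = 3L)
  mom <- list(profile = mom_prof,
              bands = setNames(c(rep(1L, 10), rep(0L, 20)), paste0("L", 1:L)),
              haplotype = "W")
  dad <- list(profile = dad_prof,
              bands = setNames(c(rep(0L, 20), rep(1L, 10)), paste0("L", 1:L)))

  h <- simulate_hybrid(mom, dad, 2, 3, loss = 0, denovo = 0, seed = 1)
  expect_equal(unname(h$bands), as.integer(mom$bands | dad$bands))
  expect_equal(h$cytotype, 5L)           # egg + pollen
  expect_equal(h$haplotype, "W")         # maternal inheritance

  # loss = 1: only de novo bands can remain
  h2 <- simulate_hybrid(mom, dad, 2, 3, loss = 1, denovo = 0.5, seed = 2)
  expect_true(all(h2$bands[mom$bands == 1 | dad$bands == 1] == 0L))

  expect_error(simulate_hybrid(mom, dad, 4, 3), "impossible cross")
  expect_error(simulate_hybrid(mom, dad, 2, 6), "impossible cross")

  # retention of union bands ~ 1 - loss (binomial, 3 sigma)
  set.seed(4)
  u <- rep(1L, 10000)
  kept <- hybridize_bands(u, u, loss = 0.17, denovo = 0.024)
  p <- mean(kept)
  expect_lt(abs(p - 0.83), 3 * sqrt(0.83 * 0.17 / 10000))
})

test_that("simulated haplotype groups have the planted step structure", {
  hs <- simulate_haplotypes(list(g1 = c("A", "B", "C"), g2 = c("D", "E"), g3 = "F"),
                            between_steps = 4, seed = 8)
  d <- step_distance_matrix(code_alignment(hs$alignment))
  grp <- hs$groups[rownames(d)]
  for (i in seq_len(nrow(d))) for (j in seq_len(ncol(d))) {
    if (i == j) next
    if (grp[i] == grp[j]) expect_lte(d[i, j], 2) else expect_gte(d[i, j], 4)
  }
  # star topology: non-ancestral haplotypes sit 1 step from the ancestor
  expect_equal(unname(d["A", "B"]), 1)
  expect_equal(unname(d["A", "C"]), 1)
})

test_that("fcm simulation supports slope recovery within 2 percent", {
  pl <- data.frame(sample_id = paste0("s", 1:60),
                   species = rep(c("X", "Y"), each = 30),
                   ploidy = rep(2:7, 10))
  betas <- c(X = 0.55, Y = 0.62)
  fcm <- simulate_fcm(pl, betas, noise = 0.01, seed = 5)
  for (sp in c("X", "Y")) {
    sub <- merge(fcm[fcm$species == sp, ], pl)
    b <- unname(coef(lm(ratio ~ 0 + ploidy, data = sub))[1])
    expect_lt(abs(b - betas[sp]) / betas[sp], 0.02)
  }
})

test_that("the packaged scenario is deterministic and truth-consistent", {
  cfg <- sim_config(seed = 21)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(unclass(ds1$markers), unclass(ds2$markers))
  expect_identical(ds1$truth, ds2$truth)
  expect_identical(ds1$fcm$ratio, ds2$fcm$ratio)

  # non-parent-specific bands enter hybrids only at the de novo rate:
  # outgroup-only loci in the F1 founder
  prof <- ds1$profiles
  aur_only <- names(which(prof$aurea$freqs > 0 & prof$pusilla$freqs == 0 &
                            prof$argentea6x$freqs == 0))
  f1 <- ds1$truth$founders$a
  rate <- mean(f1[aur_only])
  expect_lt(rate, 0.024 + 3 * sqrt(0.024 * 0.976 / length(aur_only)))

  # planted clones stay under the clone threshold with high probability:
  # max within-lineage pairwise difference is far below the lineage scale
  pd <- pairwise_differences(ds1$markers, ds1$truth$clones$sample_id)
  same <- outer(ds1$truth$clones$clone, ds1$truth$clones$clone, "==")
  diag(same) <- FALSE
  expect_lt(max(pd[same]), 20)
  expect_gt(min(pd[!same & upper.tri(pd)]), 20)
})
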