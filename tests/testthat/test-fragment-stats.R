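test_that("fragment totals match a brute-force per-column scan", {
  m <- random_markers(20, 30, seed = 3)
  meta <- meta_for(m)
  ft <- fragment_totals(m, meta)
  present <- apply(m, 2, function(col) any(col == 1))
  poly <- apply(m, 2, function(col) any(col == 1) && any(col == 0))
  expect_equal(ft$total, sum(present))
  expect_equal(ft$polymorphic, sum(poly))
  expect_equal(ft$percent_polymorphic,
               round(100 * sum(poly) / sum(present), 2))

  # worked example: 233 polymorphic of 241 scored -> 96.68%
  big <- matrix(0L, 2, 241, dimnames = list(c("a", "b"), paste0("L", 1:241)))
  big[, 1:8] <- 1L          # fixed present in all samples
  big[1, 9:241] <- 1L       # polymorphic
  ft2 <- fragment_totals(marker_matrix(big), meta_for(big))
  expect_equal(ft2$polymorphic, 233L)
  expect_equal(ft2$percent_polymorphic, 96.68)

  # all loci fixed present -> 0% polymorphic
  allon <- tiny_matrix(rep(1, 6))
  expect_equal(fragment_totals(allon, meta_for(allon))$percent_polymorphic, 0)

  meta_ex <- meta_for(m)
  meta_ex$excluded <- TRUE
  meta_ex$excluded_reason <- "x"
  expect_error(fragment_totals(m, meta_ex), "excluded")
})

test_that("shared fragments use the first group's count as denominator", {
  # published-table arithmetic: 58 of 115 -> 50.43%, 149 of 164 -> 90.85%
  lin_a <- fset("lineage a", paste0("L", 1:115))
  arg2 <- fset("arg 2x", paste0("L", c(1:58, 300:319)))
  sh <- shared_fragments(lin_a, arg2)
  expect_equal(sh$count, 58L)
  expect_equal(sh$percent, 50.43)

  coll <- fset("collina", paste0("L", 1:164))
  arg6 <- fset("arg 6x", paste0("L", c(16:164, 400:427)))
  sh2 <- shared_fragments(coll, arg6)
  expect_equal(sh2$count, 149L)
  expect_equal(sh2$percent, 90.85)

  # identity and the set-intersection oracle on random sets
  expect_equal(shared_fragments(lin_a, lin_a), list(count = 115L, percent = 100))
  set.seed(7)
  for (i in 1:10) {
    fa <- fset("a", sample(paste0("L", 1:60), 30))
    fb <- fset("b", sample(paste0("L", 1:60), 25))
    sh <- shared_fragments(fa, fb)
    expect_equal(sh$count, length(intersect(fa$fragments, fb$fragments)))
    expect_equal(sh$percent, round(100 * sh$count / 30, 2))
  }
  expect_error(shared_fragments(fset("e", character(0)), lin_a), "empty")
})

test_that("private fragments are group-exclusive and disjoint", {
  g1 <- fset("g1", "L1"); g1$members <- "s1"
  g2 <- fset("g2", "L2"); g2$members <- "s2"
  pf <- private_fragments(list(g1, g2))
  expect_equal(pf$private, list(g1 = "L1", g2 = "L2"))

  # a band present in 2 of 5 groups is private to none
  gs <- lapply(1:5, function(k) {
    g <- fset(paste0("g", k), if (k <= 2) c("Lx", paste0("L", k)) else paste0("L", k))
    g$members <- paste0("s", k)
    g
  })
  pf2 <- private_fragments(gs)
  expect_false("Lx" %in% unlist(pf2$private))
  # disjointness and total bound
  expect_equal(anyDuplicated(unlist(pf2$private)), 0L)
  expect_lte(length(unlist(pf2$private)), length(unique(unlist(lapply(gs, `[[`, "fragments")))))

  # overlapping membership rejected unless allowed
  g2b <- g2; g2b$members <- "s1"
  expect_error(private_fragments(list(g1, g2b)), "overlap")
  expect_silent(private_fragments(list(g1, g2b), allow_overlap = TRUE))

  # an additive hybrid (loss = 0) carries all parental private bands
  mom <- setNames(c(1L, 1L, 0L, 0L, 0L), paste0("L", 1:5))
  dad <- setNames(c(0L, 0L, 1L, 1L, 0L), paste0("L", 1:5))
  set.seed(1)
  hyb <- hybridize_bands(mom, dad, loss = 0, denovo = 0)
  names(hyb) <- names(mom)
  hset <- fset("hyb", names(hyb)[hyb == 1])
  gm <- fset("mom", names(mom)[mom == 1]); gm$members <- "m"
  gd <- fset("dad", names(dad)[dad == 1]); gd$members <- "d"
  pf3 <- private_fragments(list(gm, gd), hybrids = list(hset))
  expect_true(all(pf3$hybrid_content$carried == pf3$hybrid_content$private_total))
})

test_that("replicate repeatability follows the closed form", {
  m <- tiny_matrix(rep(c(1, 0), 241)[1:482], loci = paste0("L", 1:241))
  meta <- sample_meta(data.frame(sample_id = c("s1", "s2"), taxon = "t",
                                 population = "p",
                                 replicate_of = c(NA, "s1")))
  # identical pair -> 100%
  m2 <- marker_matrix(rbind(s1 = m[1, ], s2 = m[1, ]))
  expect_equal(replicate_error_rate(m2, meta)$mean_repeatability, 100)

  # pair differing at 3 of 241 -> 98.76%
  row2 <- m[1, ]; row2[1:3] <- 1L - row2[1:3]
  m3 <- marker_matrix(rbind(s1 = m[1, ], s2 = row2))
  rr <- replicate_error_rate(m3, meta)
  expect_equal(rr$pairs$differences, 3L)
  expect_equal(rr$mean_repeatability, 98.76)

  # no replicates -> explicit empty result, not an error
  rr0 <- replicate_error_rate(m3, meta_for(m3))
  expect_equal(rr0$n_pairs, 0L)
  expect_true(is.na(rr0$mean_repeatability))

  # epsilon-simulated replicates: mean repeatability ~ 100 (1 - 2 e (1 - e))
  eps <- 0.0124; L <- 241; n <- 150
  founder <- setNames(rep(c(1L, 0L), length.out = L), paste0("L", 1:L))
  set.seed(12)
  orig <- simulate_clones(founder, n, eps, ids = sprintf("o%03d", 1:n))
  reps <- simulate_clones(founder, n, eps, ids = sprintf("r%03d", 1:n))
  mm <- marker_matrix(rbind(unclass(orig), unclass(reps)))
  md <- sample_meta(data.frame(
    sample_id = rownames(mm), taxon = "t", population = "p",
    replicate_of = c(rep(NA, n), rownames(orig))))
  got <- replicate_error_rate(mm, md)$mean_repeatability
  expected <- 100 * (1 - 2 * eps * (1 - eps))
  se <- 100 * sqrt(2 * eps * (1 - eps) / L / n)
  expect_lt(abs(got - expected), 3 * se)
})
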