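make_aln <- function(seqs, excl = NULL) haplo_alignment(seqs, excl)

test_that("alignment coding excludes regions and codes indels", {
  # no gaps, no exclusions: unchanged
  plain <- make_aln(c(h1 = "ACGTACGT", h2 = "ACGTACGA"))
  cd <- code_alignment(plain)
  expect_equal(cd$n_characters, 8L)
  expect_equal(cd$n_indel, 0L)

  # one excluded region, one shared gap run of length 2 -> one indel character
  seqs <- c(h1 = "ACGTAAAACGGT",
            h2 = "ACGTAAAAC--T",
            h3 = "ACCTAAAACGGT")
  cd2 <- code_alignment(make_aln(seqs, rbind(c(5, 8))))
  # 12 cols - 4 excluded - 2 gap-run cols = 6 nucleotide + 1 indel character
  expect_equal(cd2$n_nucleotide, 6L)
  expect_equal(cd2$n_indel, 1L)
  expect_equal(cd2$n_characters, 7L)
  d <- step_distance_matrix(cd2)
  expect_equal(unname(d["h1", "h2"]), 1L)  # the indel only
  expect_equal(unname(d["h1", "h3"]), 1L)  # the substitution only
  expect_equal(unname(d["h2", "h3"]), 2L)

  # overlapping distinct gap runs demand manual coding
  bad <- make_aln(c(h1 = "AC--TT", h2 = "ACC--T", h3 = "ACCGTT"))
  expect_error(code_alignment(bad), "manual")

  # synthetic oracle: columns - excluded - gap columns + runs
  hs <- simulate_haplotypes(list(g1 = c("A", "B"), g2 = c("C", "D")),
                            between_steps = 4, n_indels = 2, seed = 3)
  cdx <- code_alignment(hs$alignment)
  ex_cols <- sum(hs$alignment$excluded_regions[, 2] -
                   hs$alignment$excluded_regions[, 1] + 1)
  expect_equal(cdx$n_characters,
               ncol(hs$alignment$seqs) - ex_cols - 2L + 2L)
  expect_equal(cdx$n_indel, 2L)
})

test_that("step distances count substitutions and indel characters alike", {
  expect_equal(step_distance(c("A", "C", "0"), c("A", "C", "0")), 0)
  expect_equal(step_distance(c("A", "C", "0"), c("A", "T", "1")), 2)
  expect_equal(step_distance(c("N", "C"), c("A", "C")), 0)  # N is missing
  expect_error(step_distance(c("A"), c("A", "C")), "character count")

  set.seed(2)
  for (i in 1:10) {
    x <- sample(c("A", "C", "G", "T"), 40, TRUE)
    y <- sample(c("A", "C", "G", "T"), 40, TRUE)
    expect_equal(step_distance(x, y), sum(x != y))
  }
})

test_that("network components respect the connection limit", {
  # two close pairs 6 steps apart, limit 5 -> two components
  d <- matrix(c(0, 1, 6, 7,
                1, 0, 6, 7,
                6, 6, 0, 1,
                7, 7, 1, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  net <- build_network(d, limit = 5)
  expect_equal(length(unique(net$components)), 2L)
  expect_equal(unname(net$components[c("A", "B")]), c(1L, 1L))

  # a single k-step connection inserts k - 1 intermediates
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  net2 <- build_network(d2, limit = 3)
  expect_equal(sum(!igraph::V(net2$graph)$observed), 2L)
  expect_equal(unname(igraph::distances(net2$graph)["X", "Y"]), 3)
  # inferred intermediates have degree >= 2
  degs <- igraph::degree(net2$graph)[!igraph::V(net2$graph)$observed]
  expect_true(all(degs >= 2))

  expect_error(build_network(d2, limit = 0), "positive")
})

test_that("components equal brute-force thresholding for small sets", {
  set.seed(14)
  for (i in 1:10) {
    n <- 6
    base <- matrix(sample(c("A", "C", "G", "T"), 30, TRUE), nrow = 1)
    seqs <- do.call(rbind, lapply(1:n, function(k) {
      s <- base[1, ]
      mut <- sample(30, sample(0:6, 1))
      for (cc in mut) s[cc] <- sample(setdiff(c("A", "C", "G", "T"), s[cc]), 1)
      s
    }))
    rownames(seqs) <- paste0("h", 1:n)
    cd <- code_alignment(haplo_alignment(seqs))
    d <- step_distance_matrix(cd)
    for (lim in c(1, 2, 4)) {
      net <- build_network(d, limit = lim)
      # oracle: transitive closure over pairs with distance <= limit
      adj <- d <= lim
      reach <- adj
      for (k in 1:n) reach <- reach | (reach %*% adj > 0)
      oracle <- unique(apply(reach, 1, function(r) paste(sort(rownames(d)[r]), collapse = ",")))
      got <- vapply(split(names(net$components), net$components),
                    function(x) paste(sort(x), collapse = ","), "")
      expect_setequal(unname(got), oracle)
    }
    # merging is monotone in the limit
    k1 <- length(unique(build_network(d, limit = 1)$components))
    k2 <- length(unique(build_network(d, limit = 6)$components))
    expect_gte(k1, k2)
  }
})

test_that("observed pairs are connected by paths no longer than their distance", {
  hs <- simulate_haplotypes(list(g1 = c("A", "B", "C"), g2 = c("D", "E")),
                            between_steps = 4, seed = 17)
  cd <- code_alignment(hs$alignment)
  net <- build_network(cd, limit = 10)   # everything connected
  gd <- igraph::distances(net$graph)
  for (i in rownames(net$step_matrix)) for (j in rownames(net$step_matrix)) {
    expect_lte(gd[i, j], net$step_matrix[i, j] + 1e-9)
  }
})

test_that("the auto connection limit joins 1-step and refuses 13-step links", {
  lim <- hybriscope:::parsimony_connection_limit(443)
  expect_gte(lim, 1L)
  expect_lt(lim, 13L)
})

test_that("haplotype tables report carriers, taxa and populations", {
  meta <- sample_meta(data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    taxon = c("P. pusilla", "P. alpicola", "P. alpicola", "P. argentea"),
    population = c("p1", "p2", "p2", "p3"),
    haplotype = c("W", "W", NA, "E")))
  tab <- haplotype_table(meta)
  expect_equal(nrow(tab), 2L)            # no empty haplotype rows
  w <- tab[tab$haplotype == "W", ]
  expect_equal(w$n_carriers, 2L)
  expect_equal(w$taxa, "P. alpicola,P. pusilla")
  expect_equal(w$populations, "p1,p2")

  hs <- simulate_haplotypes(list(g1 = c("W", "E")), between_steps = 4, seed = 1)
  net <- build_network(code_alignment(hs$alignment), limit = 3)
  tab2 <- haplotype_table(meta, net)
  expect_true(all(!is.na(tab2$group)))
})
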