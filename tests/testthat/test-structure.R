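test_that("theta hits the fixed-difference and identical-group extremes", {
  g1 <- make_group("P1", "J_ST", list(locA = c(`100` = 10)))
  g2 <- make_group("P2", "J_ST", list(locA = c(`102` = 10)))
  expect_equal(fst_theta(make_groups(g1, g2))$theta, 1)

  g3 <- make_group("P1", "J_ST", list(locA = c(`100` = 6, `102` = 6)))
  g4 <- make_group("P2", "J_ST", list(locA = c(`100` = 6, `102` = 6)))
  expect_lte(fst_theta(make_groups(g3, g4))$theta, 0)

  # all-monomorphic is undefined
  g5 <- make_group("P1", "J_ST", list(locA = c(`100` = 8)))
  g6 <- make_group("P2", "J_ST", list(locA = c(`100` = 8)))
  expect_error(fst_theta(make_groups(g5, g6)), "monomorphic")
})

test_that("theta equals the ANOVA-on-indicators oracle on a known table", {
  # groups n = (4,4), counts A/B = (3,1) vs (1,3)
  counts <- list(c(A = 3, B = 1), c(A = 1, B = 3))
  g1 <- make_group("P1", "J_ST", list(locA = counts[[1]]))
  g2 <- make_group("P2", "J_ST", list(locA = counts[[2]]))
  expect_equal(fst_theta(make_groups(g1, g2))$theta,
               theta_anova_oracle(counts), tolerance = 1e-12)
})

test_that("theta is invariant to allele relabeling and multi-locus is a component ratio", {
  g1 <- make_group("P1", "J_ST", list(locA = c(`100` = 7, `102` = 3),
                                      locB = c(`150` = 2, `152` = 8)))
  g2 <- make_group("P2", "J_ST", list(locA = c(`100` = 2, `102` = 8),
                                      locB = c(`150` = 6, `152` = 4)))
  r <- fst_theta(make_groups(g1, g2))
  relab <- function(g) {
    g$counts <- lapply(g$counts, function(cnt) {
      names(cnt) <- rev(names(cnt)); cnt })
    g
  }
  r2 <- fst_theta(make_groups(relab(g1), relab(g2)))
  expect_equal(r$theta, r2$theta, tolerance = 1e-12)
  # ratio of sums, not mean of ratios; and bounded by per-locus thetas
  expect_equal(r$theta,
               sum(r$per_locus$sigma_a) /
                 sum(r$per_locus$sigma_a + r$per_locus$sigma_w))
  expect_gte(r$theta, min(r$per_locus$theta))
  expect_lte(r$theta, max(r$per_locus$theta))
})

test_that("permutation test is seed-stable and maximal statistics get the minimal p", {
  df <- data.frame(individual = paste0("i", 1:20),
                   population = rep(c("P1", "P2"), each = 10),
                   chromosome = "J", arrangement = "J_ST",
                   locA = rep(c(100L, 102L), each = 10),
                   locB = NA_integer_, stringsAsFactors = FALSE)
  ht <- toy_ht(df)
  set.seed(1); p1 <- fst_permutation_test(ht, B = 199)$p_value
  set.seed(1); p2 <- fst_permutation_test(ht, B = 199)$p_value
  expect_identical(p1, p2)
  expect_equal(p1, 1 / 200) # fixed difference: no permutation can reach theta
  expect_error(fst_permutation_test(ht, B = 0), "B must be >= 1")
})

test_that("pairwise matrix is symmetric, zero-diagonal and self-consistent", {
  set.seed(13)
  gs <- lapply(1:3, function(i)
    make_group(paste0("P", i), "J_ST",
               list(locA = stats::setNames(rpois(3, 8) + 1,
                                           c(100, 102, 104)))))
  gro <- do.call(make_groups, gs)
  pw <- pairwise_fst(gro)
  expect_equal(pw$matrix, t(pw$matrix))
  expect_equal(unname(diag(pw$matrix)), rep(0, 3))
  expect_equal(pw$matrix[2, 1],
               fst_theta(make_groups(gs[[1]], gs[[2]]))$theta,
               tolerance = 1e-12)
  # three identical groups are undifferentiated
  gident <- make_groups(
    make_group("P1", "J_ST", list(locA = c(`100` = 5, `102` = 5))),
    make_group("P2", "J_ST", list(locA = c(`100` = 5, `102` = 5))),
    make_group("P3", "J_ST", list(locA = c(`100` = 5, `102` = 5))))
  expect_true(all(pairwise_fst(gident)$matrix <= 0))
})

test_that("between/within partition recovers simulated structure and enumerates the signed-rank p", {
  cfg <- sim_config(F_arr = 0.1, F_pop = 0.005, group_size = 30, seed = 77)
  ht <- simulate_dataset(cfg)$haplotypes
  pa <- partition_fst(ht, "A")
  expect_gt(pa$between$theta, mean(vapply(pa$within, `[[`, numeric(1),
                                          "theta")))
  # all 8 A-chromosome loci individually higher between than within gives
  # the exact one-sided signed-rank enumeration 1/2^8
  if (all(pa$per_locus$theta_between > pa$per_locus$theta_within_mean))
    expect_equal(pa$wilcoxon_p, 1 / 2^8, tolerance = 1e-12)
  expect_lt(pa$wilcoxon_p, 0.05)

  # population subsetting drops groups
  pa7 <- partition_fst(ht, "A", exclude_populations = c("DRO", "SUN"))
  within_pops <- vapply(pa7$within, function(w) nrow(w$per_locus) > 0,
                        logical(1))
  expect_true(all(within_pops))
})

test_that("PCoA reproduces closed-form two- and three-point embeddings", {
  m2 <- matrix(c(0, 0.1, 0.1, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  p2 <- pcoa_fst(m2)
  expect_equal(length(p2$percent), 1)
  expect_equal(p2$percent, 100)
  expect_equal(sort(abs(p2$coordinates[, 1])), rep(sqrt(0.1) / 2, 2),
               tolerance = 1e-9, ignore_attr = TRUE)

  # three equidistant groups: two equal eigenvalues, 50/50
  m3 <- matrix(0.2, 3, 3); diag(m3) <- 0
  dimnames(m3) <- list(letters[1:3], letters[1:3])
  p3 <- pcoa_fst(m3)
  expect_equal(p3$percent, c(50, 50), tolerance = 1e-9)

  # classical-scaling definition: recovered coordinates reproduce sqrt(F)
  d <- as.matrix(dist(cbind(c(0, 1, 3, 2), c(0, 2, 1, 4))))^2
  p4 <- pcoa_fst(d)
  rec <- as.matrix(dist(p4$coordinates))
  expect_equal(rec, sqrt(d), tolerance = 1e-9, ignore_attr = TRUE)
  # and agrees with stats::cmdscale on the same matrix
  cs <- stats::cmdscale(sqrt(d), k = 2, eig = TRUE)
  expect_equal(sort(p4$eigenvalues[1:2]), sort(cs$eig[1:2]),
               tolerance = 1e-9)
  expect_error(pcoa_fst(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})
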