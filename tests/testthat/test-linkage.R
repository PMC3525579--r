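test_that("D'm hits the coupling and independence anchors", {
  # complete coupling at p = q = 0.5
  x <- matrix(c(20, 0, 0, 20), 2, 2)
  expect_equal(dm_statistic(x), 1)
  # independence table
  p <- c(0.5, 0.3, 0.2); q <- c(0.6, 0.4)
  ind <- outer(p, q) * 1000
  expect_equal(dm_statistic(ind), 0, tolerance = 1e-12)
  # single category errors
  expect_error(dm_statistic(matrix(c(5, 5), 2, 1)), "fewer than 2")
  # 2x2 case equals |D'| of the biallelic definition
  x2 <- matrix(c(18, 2, 5, 15), 2, 2)
  P <- x2 / sum(x2)
  D <- P[1, 1] - sum(P[1, ]) * sum(P[, 1])
  dmax <- min(sum(P[1, ]) * (1 - sum(P[, 1])),
              (1 - sum(P[1, ])) * sum(P[, 1]))
  expect_equal(dm_statistic(x2), abs(D / dmax), tolerance = 1e-12)
})

test_that("D'm matches the brute-force oracle and is bounded and label-invariant", {
  # the spec's 3-allele x 2-arrangement table
  x <- matrix(c(20, 5, 0, 0, 15, 10), 3, 2)
  expect_equal(dm_statistic(x), dm_oracle(x), tolerance = 1e-12)
  set.seed(17)
  for (i in 1:25) {
    x <- matrix(rpois(15, 4), 5, 3)
    x <- x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
    if (nrow(x) < 2 || ncol(x) < 2) next
    v <- dm_statistic(x)
    expect_equal(v, dm_oracle(x), tolerance = 1e-12)
    expect_gte(v, 0); expect_lte(v, 1)
    # invariance to allele (row) permutation
    expect_equal(dm_statistic(x[sample(nrow(x)), , drop = FALSE]), v,
                 tolerance = 1e-12)
  }
})

test_that("Monte-Carlo exact test tracks Fisher and is seed-stable", {
  x <- matrix(c(20, 0, 0, 20), 2, 2)
  set.seed(2)
  expect_equal(mc_exact_test(x, B = 999), 1 / 1000)
  set.seed(9); pA <- mc_exact_test(x, B = 99)
  set.seed(9); pB <- mc_exact_test(x, B = 99)
  expect_identical(pA, pB)
  # degenerate margins
  expect_equal(mc_exact_test(matrix(c(10, 0, 0, 0), 2, 2), B = 99), 1)
  # agreement with the exact two-sided Fisher p on moderate 2x2 tables
  set.seed(31)
  for (tab in list(matrix(c(12, 4, 6, 14), 2, 2),
                   matrix(c(8, 8, 9, 7), 2, 2))) {
    pf <- stats::fisher.test(tab)$p.value
    pmc <- mc_exact_test(tab, B = 20000)
    expect_equal(pmc, pf, tolerance = 0.012)
  }
})

test_that("interallelic D-prime and Yates chi-square match hand computation", {
  x <- matrix(c(30, 0, 0, 30), 2, 2,
              dimnames = list(c("245", "251"), c("J_ST", "J_1")))
  res <- allele_inversion_dprime(x)
  r11 <- res[res$allele == "245" & res$arrangement == "J_ST", ]
  expect_equal(r11$Dprime, 1)
  expect_equal(r11$chisq_yates, 60 * (900 - 30)^2 / 30^4, tolerance = 1e-9)
  expect_true(r11$passes_min_obs)
  # joint count below min_obs is flagged regardless of p
  x2 <- matrix(c(2, 28, 28, 2), 2, 2,
               dimnames = list(c("a", "b"), c("X", "Y")))
  res2 <- allele_inversion_dprime(x2, min_obs = 3)
  low <- res2[res2$joint_count == 2, ]
  expect_true(all(!low$passes_min_obs))
  expect_true(all(low$p < 0.05))
  # independence cell: D' = 0, chi-square ~ 0
  ind <- outer(c(30, 30), c(20, 40)) / 60
  storage.mode(ind) <- "double"
  dimnames(ind) <- list(c("a", "b"), c("X", "Y"))
  res3 <- allele_inversion_dprime(ind)
  expect_equal(res3$Dprime, rep(0, 4), tolerance = 1e-12)
  expect_true(all(res3$chisq_yates < 1))
})

test_that("FDR adjustment follows Benjamini-Yekutieli with B-H as superset", {
  p <- c(0.001, 0.01, 0.02, 0.4, 0.9)
  by <- fdr_adjust(p, "BY", alpha = 0.05)
  expect_equal(by$p_adjusted, stats::p.adjust(p, "BY"))
  expect_equal(by$reject, stats::p.adjust(p, "BY") <= 0.05)
  expect_equal(sum(by$reject), 1) # only the smallest p survives B-Y here
  expect_false(any(fdr_adjust(rep(1, 6))$reject))
  expect_equal(nrow(fdr_adjust(numeric(0))), 0)
  set.seed(4)
  for (i in 1:10) {
    pr <- runif(12)^2
    expect_true(all(fdr_adjust(pr, "BY")$reject <=
                      fdr_adjust(pr, "BH")$reject))
  }
})

test_that("Ohta components satisfy the decomposition identity and the hand example", {
  # two biallelic subpopulations with opposite coupling at p = q = 0.5
  t1 <- matrix(c(0.5, 0, 0, 0.5) * 40, 2, 2,
               dimnames = list(c("a", "b"), c("x", "y")))
  t2 <- matrix(c(0, 0.5, 0.5, 0) * 40, 2, 2,
               dimnames = list(c("a", "b"), c("x", "y")))
  oc <- ohta_components(list(t1, t2))
  expect_equal(oc$Dp2_ST, 0, tolerance = 1e-12)
  expect_equal(oc$Dp2_IS, 0.25, tolerance = 1e-12)
  expect_equal(oc$D2_IS, 0.25, tolerance = 1e-12)
  expect_equal(oc$D2_ST, 0, tolerance = 1e-12)
  expect_equal(oc$D2_IT, 0.25, tolerance = 1e-12)
  # duplicated subpopulation: no among-population LD variance
  oc2 <- ohta_components(list(t1, t1))
  expect_equal(oc2$Dp2_IS, 0, tolerance = 1e-12)
  expect_equal(oc2$D2_IT, oc2$Dp2_ST, tolerance = 1e-12)
  # identity on random tables
  set.seed(23)
  for (i in 1:20) {
    tabs <- lapply(1:4, function(k) matrix(rpois(12, 5) + 1, 3, 4))
    oc3 <- ohta_components(tabs)
    expect_equal(oc3$D2_IT, oc3$Dp2_IS + oc3$Dp2_ST, tolerance = 1e-12)
    expect_true(all(unlist(oc3) >= 0))
  }
  expect_error(ohta_components(list(t1)), ">= 2 subpopulations")
})

test_that("opposite-sign coupling across populations gives the drift signature", {
  # drift: per-population LD with alternating sign -> Dp2_IS >> Dp2_ST;
  # identical coupling everywhere -> Dp2_ST > 0 with Dp2_IS ~ 0
  t_pos <- matrix(c(18, 2, 2, 18), 2, 2)
  t_neg <- matrix(c(2, 18, 18, 2), 2, 2)
  drift <- ohta_components(list(t_pos, t_neg, t_pos, t_neg))
  system <- ohta_components(list(t_pos, t_pos, t_pos, t_pos))
  expect_gt(drift$Dp2_IS, drift$Dp2_ST * 10)
  expect_gt(system$Dp2_ST, 0.01)
  expect_lt(system$Dp2_IS, 1e-12)
})

test_that("inter-locus scan recovers injected LD and skips monomorphic loci", {
  cfg <- sim_config(F_arr = 0, F_pop = 0, group_size = 150,
                    pop_meta = data.frame(population = c("P1", "P2"),
                                          latitude = c(40, 50),
                                          longitude = c(0, 5)),
                    ld_pair = list(locus_a = "dsub59", locus_b = "dsub69",
                                   arrangement = "J_1", dprime = 0.8),
                    seed = 33)
  ht <- simulate_dataset(cfg)$haplotypes
  set.seed(1)
  res <- pairwise_locus_ld(ht, "J", "J_1", pooled = TRUE, B = 499)
  hit <- res[res$locus_a %in% c("dsub59", "dsub69") &
               res$locus_b %in% c("dsub59", "dsub69"), ]
  expect_equal(nrow(hit), 1)
  expect_lt(hit$p, 0.05)
  expect_equal(min(res$p), hit$p)
})
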