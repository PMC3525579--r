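test_that("cline frequencies are a latitude softmax", {
  cfg <- sim_config(seed = 1)
  # closed form: two arrangements, a = (0,0), b = (0, -0.2), lat = 50
  cfg2 <- sim_config(
    pop_meta = data.frame(population = "X", latitude = 50, longitude = 0),
    clines = data.frame(chromosome = "J", arrangement = c("J_ST", "J_1"),
                        a = c(0, 0), b = c(0, -0.2),
                        stringsAsFactors = FALSE),
    seed = 1)
  f <- cline_arrangement_freqs(cfg2, "X")$J
  expect_equal(unname(f["J_1"]), 1 / (1 + exp(10)), tolerance = 1e-12)
  expect_equal(sum(f), 1, tolerance = 1e-12)

  # flat coefficients give uniform frequencies
  cfg3 <- sim_config(
    pop_meta = data.frame(population = "X", latitude = 50, longitude = 0),
    clines = data.frame(chromosome = "U",
                        arrangement = c("U_ST", "U_1+2", "U_1+2+8"),
                        a = 0, b = 0, stringsAsFactors = FALSE),
    seed = 1)
  expect_equal(unname(cline_arrangement_freqs(cfg3, "X")$U), rep(1/3, 3))

  # positive standard slope is monotone in latitude
  lats <- seq(36, 60, by = 4)
  fr <- vapply(lats, function(l) {
    cfgl <- sim_config(
      pop_meta = data.frame(population = "X", latitude = l, longitude = 0),
      clines = data.frame(chromosome = "J", arrangement = c("J_ST", "J_1"),
                          a = c(0, 3.4), b = c(0, -0.08),
                          stringsAsFactors = FALSE),
      seed = 1)
    cline_arrangement_freqs(cfgl, "X")$J[["J_ST"]]
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("Dirichlet divergence draw has Balding-Nichols moments", {
  base <- c(`100` = 0.5, `102` = 0.5)
  expect_identical(draw_group_freqs(base, 0), base)
  expect_error(draw_group_freqs(base, 1), "\\[0, 1\\)")
  set.seed(42)
  draws <- replicate(20000, draw_group_freqs(base, 0.5)[1])
  # Var(p) = F p (1-p) = 0.125
  expect_equal(var(draws), 0.125, tolerance = 0.01)
  expect_equal(mean(draws), 0.5, tolerance = 0.01)
})

test_that("clinal allele injection is exactly invertible on the arcsin scale", {
  lats <- c(P1 = 37, P2 = 42, P3 = 50, P4 = 60)
  f0 <- c(`100` = 0.4, `102` = 0.4, `104` = 0.2)
  fbp <- lapply(lats, function(l) f0)
  spec <- list(allele = "102", c0 = 0.2, c1 = 0.012) # no clipping over range
  adj <- inject_clinal_allele(fbp, spec, lats)
  y <- asin(sqrt(vapply(adj, `[[`, numeric(1), "102")))
  fit <- stats::lm(y ~ lats)
  expect_equal(unname(coef(fit)[2]), 0.012, tolerance = 1e-10)
  expect_equal(summary(fit)$r.squared, 1, tolerance = 1e-10)
  # non-target alleles keep mutual proportions and vectors stay normalized
  for (p in names(adj)) {
    expect_equal(sum(adj[[p]]), 1, tolerance = 1e-12)
    expect_equal(adj[[p]][["100"]] / adj[[p]][["104"]], 2, tolerance = 1e-12)
  }
  # constant c1 = 0 gives sin^2(c0) everywhere
  adj0 <- inject_clinal_allele(fbp, list(allele = "102", c0 = 0.7, c1 = 0),
                               lats)
  expect_equal(unique(round(vapply(adj0, `[[`, numeric(1), "102"), 12)),
               round(sin(0.7)^2, 12))
  expect_error(inject_clinal_allele(list(P1 = c(`100` = 1)),
                                    spec, lats), "single-allele")
})

test_that("simulation is seed-reproducible", {
  cfg <- sim_config(seed = 99)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(as.data.frame(s1$haplotypes), as.data.frame(s2$haplotypes))
  expect_identical(s1$truth$arrangement_freqs, s2$truth$arrangement_freqs)
})

test_that("neutral generator yields near-zero differentiation and F_arr is recovered at inside loci", {
  # F_arr = F_pop = 0: between-arrangement theta within +/-0.01 of 0
  cfg0 <- sim_config(F_arr = 0, F_pop = 0, group_size = 250, seed = 5)
  ht0 <- simulate_dataset(cfg0)$haplotypes
  p0 <- partition_fst(ht0, "J")
  expect_lt(abs(p0$between$theta), 0.01)

  # F_arr = 0.25: theta among the arrangements themselves (one large group
  # per arrangement, so each group is one independent pool draw) recovers
  # F_arr at inside loci and ~ 0 at outside loci. Chromosome A contributes
  # six inside-locus pool draws per arrangement.
  inside_A <- c("dsub11", "dsub37", "dsub76", "dsub05", "dsub21", "dsub39")
  one_pop <- data.frame(population = "P1", latitude = 45, longitude = 0)
  thin <- thout <- numeric(6)
  for (r in 1:6) {
    cfg <- sim_config(pop_meta = one_pop, F_arr = 0.25, F_pop = 0,
                      group_size = 200, seed = 100 + r)
    ht <- simulate_dataset(cfg)$haplotypes
    df <- as.data.frame(ht)
    gro <- group_counts(haplotype_table(df[df$chromosome == "A", ],
                                        attr(ht, "locus_map"),
                                        attr(ht, "pop_meta"),
                                        attr(ht, "arrangements")))
    thin[r] <- fst_theta(gro, loci = inside_A)$theta
    thout[r] <- fst_theta(gro, loci = c("dsub70", "dsub19"))$theta
  }
  expect_equal(mean(thin), 0.25, tolerance = 0.2)
  expect_lt(abs(mean(thout)), 0.02)
})

test_that("within-arrangement drift parameter is recovered across its range", {
  # mean pairwise within-arrangement theta ~ F_pop (20% relative over reps)
  for (f in c(0.05, 0.2)) {
    th <- numeric(6)
    for (r in 1:6) {
      cfg <- sim_config(F_arr = 0, F_pop = f, group_size = 60,
                        seed = 1000 * f * 100 + r)
      ht <- simulate_dataset(cfg)$haplotypes
      pa <- partition_fst(ht, "U")
      th[r] <- mean(vapply(pa$within, `[[`, numeric(1), "theta"))
    }
    expect_equal(mean(th), f, tolerance = 0.2)
  }
})

test_that("injected two-locus LD is recovered as interallelic D-prime", {
  cfg <- sim_config(F_arr = 0, F_pop = 0, group_size = 300,
                    pop_meta = data.frame(population = "P1", latitude = 45,
                                          longitude = 0),
                    ld_pair = list(locus_a = "dsub59", locus_b = "dsub69",
                                   arrangement = "J_1", dprime = 0.8),
                    seed = 21)
  ht <- simulate_dataset(cfg)$haplotypes
  df <- as.data.frame(ht)
  sub <- df[df$arrangement == "J_1", ]
  d <- toy_design()
  subht <- haplotype_table(sub, attr(ht, "locus_map"), attr(ht, "pop_meta"),
                           attr(ht, "arrangements"))
  tab <- gametic_table(subht, "dsub59", "dsub69")
  res <- allele_inversion_dprime(tab, min_obs = 1)
  # the coupled pair is the modal-allele x modal-allele cell
  star <- res[which.max(res$joint_count), ]
  expect_gt(star$Dprime, 0.7)
  expect_lt(star$Dprime, 0.9)
})
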