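# Small in-code fixtures shared across tests.

# a minimal two-population, two-arrangement, two-locus design
toy_design <- function() {
  list(
    pop_meta = data.frame(
      population = c("P1", "P2", "P3", "P4"),
      latitude = c(37, 42, 50, 60),
      longitude = c(-4, 2, 5, 11),
      stringsAsFactors = FALSE),
    arrangements = data.frame(
      chromosome = c("J", "J"),
      arrangement = c("J_ST", "J_1"),
      stringsAsFactors = FALSE),
    locus_map = data.frame(
      locus = c("locA", "locB"),
      chromosome = c("J", "J"),
      cyto_order = 1:2,
      inside_of = c("J_1", ""),
      region = NA_character_,
      stringsAsFactors = FALSE)
  )
}

# haplotype table with explicit allele columns
toy_ht <- function(rows) {
  d <- toy_design()
  haplotype_table(rows, d$locus_map, d$pop_meta, d$arrangements)
}

# build a group object directly from named count vectors
make_group <- function(population, arrangement, counts,
                       chromosome = "J") {
  counts <- lapply(counts, function(x)
    stats::setNames(as.integer(x), names(x)))
  g <- list(population = population, chromosome = chromosome,
            arrangement = arrangement,
            n = max(vapply(counts, sum, integer(1))),
            counts = counts,
            n_locus = vapply(counts, sum, integer(1)))
  class(g) <- "hap_group"
  g
}

make_groups <- function(...) structure(list(...), class = "group_counts")

# independent brute-force theta oracle: ANOVA on 0/1 allele indicators
theta_anova_oracle <- function(counts_list) {
  # counts_list: list of named count vectors, one per group
  alleles <- sort(unique(unlist(lapply(counts_list, names))))
  g <- rep(seq_along(counts_list),
           vapply(counts_list, sum, numeric(1)))
  haps <- unlist(lapply(counts_list, function(cnt)
    rep(names(cnt), cnt)))
  nk <- vapply(counts_list, sum, numeric(1))
  n <- sum(nk); r <- length(nk)
  nc <- (n - sum(nk^2) / n) / (r - 1)
  sa <- 0; sw <- 0
  for (a in alleles) {
    y <- as.numeric(haps == a)
    fit <- stats::aov(y ~ factor(g))
    ms <- summary(fit)[[1]][["Mean Sq"]]
    sa <- sa + (ms[1] - ms[2]) / nc
    sw <- sw + ms[2]
  }
  sa / (sa + sw)
}

# naive cell-by-cell D'm oracle (scalar loops, kept deliberately different
# from the vectorized implementation)
dm_oracle <- function(x) {
  n <- sum(x)
  total <- 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    p <- sum(x[i, ]) / n
    q <- sum(x[, j]) / n
    D <- x[i, j] / n - p * q
    dmax <- if (D < 0) min(p * q, (1 - p) * (1 - q))
            else min(p * (1 - q), (1 - p) * q)
    dp <- if (dmax == 0) 0 else D / dmax
    total <- total + p * q * abs(dp)
  }
  total
}
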