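#' Gene diversity (expected heterozygosity) from allele counts
#'
#' Nei's unbiased estimator for a haploid sample of size n:
#' He = n/(n-1) * (1 - sum p_i^2). With `unbiased = FALSE` the plain
#' gene diversity 1 - sum p_i^2 is returned, for frequency tables that come
#' without sample sizes.
#'
#' @param counts named vector of allele counts (n = sum >= 2)
#' @param unbiased apply the n/(n-1) small-sample correction (default TRUE)
#' @return He in [0, 1]
#' @export
gene_diversity <- function(counts, unbiased = TRUE) {
  n <- sum(counts)
  if (n < 2) stop("gene diversity undefined for n < 2")
  p <- counts / n
  he <- 1 - sum(p^2)
  if (unbiased) he <- he * n / (n - 1)
  min(he, 1)
}

#' Gene diversity of arrangement frequencies
#'
#' Applies the same estimator to chromosomal-arrangement frequencies treated
#' as alleles of a pseudo-locus.
#'
#' @param freqs arrangement frequency vector (sums to 1)
#' @param n number of chromosomes scored; NULL for the biased estimator
#' @return He
#' @export
arrangement_diversity <- function(freqs, n = NULL) {
  if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1")
  he <- 1 - sum(freqs^2)
  if (!is.null(n)) {
    if (n < 2) stop("n must be >= 2")
    he <- he * n / (n - 1)
  }
  min(he, 1)
}

#' Per-group and per-locus diversity table
#'
#' One row per group x locus plus a summary row per group (locus = "all",
#' the mean of per-locus He, the group-level variability statistic reported
#' in arrangement-by-population tables). The arcsin-sqrt transformed He is
#' included as `He_asin` (radians), the variance-stabilized scale used for
#' regressions on latitude.
#'
#' @param groups a [group_counts()] object
#' @param unbiased passed to [gene_diversity()]
#' @return data frame (population, chromosome, arrangement, locus, n, He,
#'   He_asin)
#' @export
diversity_table <- function(groups, unbiased = TRUE) {
  if (!length(groups)) stop("no groups")
  rows <- list()
  for (g in groups) {
    he <- vapply(names(g$counts), function(l) {
      if (g$n_locus[[l]] >= 2) gene_diversity(g$counts[[l]], unbiased)
      else NA_real_
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      population = g$population, chromosome = g$chromosome,
      arrangement = g$arrangement,
      locus = c(names(g$counts), "all"),
      n = c(unname(g$n_locus), g$n),
      He = c(unname(he), mean(he, na.rm = TRUE)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$He_asin <- asin(sqrt(pmin(pmax(out$He, 0), 1)))
  out
}
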