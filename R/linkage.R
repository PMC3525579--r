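# Linkage disequilibrium between multiallelic markers and inversions
# (treated as a pseudo-locus whose alleles are the arrangements), and
# between marker pairs within an arrangement.

#' Joint gametic counts for a locus against arrangements or a second locus
#'
#' Builds the alleles x categories count table used by [dm_statistic()],
#' [mc_exact_test()] and [allele_inversion_dprime()]. Phase is observed (each
#' row of the haplotype table is one phased chromosome), so joint counts are
#' direct tabulations.
#'
#' @param ht a [haplotype_table()] (subset to the haplotypes of interest)
#' @param locus locus name (table rows)
#' @param against "arrangement" or a second locus name (table columns)
#' @return integer matrix of joint counts
#' @export
gametic_table <- function(ht, locus, against = "arrangement") {
  df <- as.data.frame(ht)
  a <- df[[locus]]
  b <- if (identical(against, "arrangement")) df$arrangement else df[[against]]
  ok <- !is.na(a) & !is.na(b)
  tab <- table(a[ok], b[ok])
  m <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  m
}

#' Multiallelic D'm statistic
#'
#' Hedrick's multiallelic extension of Lewontin's normalized disequilibrium:
#' for each cell, D_ij = x_ij - p_i q_j, normalized by its sign-dependent
#' bound D_max, and averaged with weights p_i q_j:
#' D'm = sum_ij p_i q_j |D'_ij|, bounded in [0, 1]. Zero-margin rows/columns
#' are dropped; both axes must retain >= 2 categories.
#'
#' @param x joint count (or proportion) matrix, alleles x categories
#' @return D'm
#' @export
dm_statistic <- function(x) {
  x <- x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("D'm undefined: fewer than 2 categories with nonzero margin")
  P <- x / sum(x)
  p <- rowSums(P)
  q <- colSums(P)
  pq <- outer(p, q)
  D <- P - pq
  dmax_neg <- pmin(pq, outer(1 - p, 1 - q))
  dmax_pos <- pmin(outer(p, 1 - q), outer(1 - p, q))
  dmax <- ifelse(D < 0, dmax_neg, dmax_pos)
  Dp <- ifelse(dmax == 0, 0, D / dmax)
  sum(pq * abs(Dp))
}

#' Monte-Carlo Fisher exact test of a contingency table
#'
#' Category labels are permuted against allele labels B times; the statistic
#' is the conditional (hypergeometric) log-probability of the table given its
#' margins, and p = (1 + #\{logP_perm <= logP_obs\}) / (B + 1). Degenerate
#' margins (a single nonzero row or column) give p = 1.
#'
#' @param x joint count matrix
#' @param B permutations (default 10000)
#' @return p-value
#' @export
mc_exact_test <- function(x, B = 10000) {
  if (B < 1) stop("B must be >= 1")
  x <- x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 2) return(1)
  n <- sum(x)
  if (n < 2) stop("need n >= 2")
  # expand to paired label vectors
  ij <- which(x > 0, arr.ind = TRUE)
  a <- rep(ij[, 1], x[ij])
  b <- rep(ij[, 2], x[ij])
  K <- nrow(x); C <- ncol(x)
  stat <- function(av, bv)
    -sum(lgamma(tabulate((bv - 1L) * K + av, K * C) + 1))
  obs <- stat(a, b)
  hits <- 0L
  for (i in seq_len(B))
    if (stat(a, sample(b)) <= obs + 1e-9) hits <- hits + 1L
  (1 + hits) / (B + 1)
}

#' Per-allele interallelic D' against arrangements, with Yates chi-square
#'
#' Each (allele i, arrangement j) cell is collapsed to a 2x2 table (i vs
#' not-i, j vs not-j); D'_ij is the normalized disequilibrium of that 2x2 and
#' significance is a Yates-corrected chi-square with 1 df. Associations
#' supported by fewer than `min_obs` joint observations are flagged
#' non-significant regardless of p, guarding against spurious rare-cell hits.
#'
#' @param x joint count matrix, alleles x arrangements
#' @param min_obs minimum joint count for a trustworthy association
#'   (default 3)
#' @return data frame (allele, arrangement, D, Dprime, chisq_yates, p,
#'   joint_count, passes_min_obs)
#' @export
allele_inversion_dprime <- function(x, min_obs = 3) {
  x <- x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need >= 2 categories on each axis")
  n <- sum(x)
  P <- x / n
  p <- rowSums(P); q <- colSums(P)
  out <- list()
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    a <- x[i, j]
    b <- sum(x[i, ]) - a
    cc <- sum(x[, j]) - a
    d <- n - a - b - cc
    D <- P[i, j] - p[i] * q[j]
    dmax <- if (D < 0) min(p[i] * q[j], (1 - p[i]) * (1 - q[j]))
            else min(p[i] * (1 - q[j]), (1 - p[i]) * q[j])
    dp <- if (dmax == 0) 0 else D / dmax
    denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
    chi <- if (denom == 0) 0 else
      n * max(abs(a * d - b * cc) - n / 2, 0)^2 / denom
    out[[length(out) + 1L]] <- data.frame(
      allele = rownames(x)[i], arrangement = colnames(x)[j],
      D = D, Dprime = dp, chisq_yates = chi,
      p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
      joint_count = a, passes_min_obs = a >= min_obs,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' False-discovery-rate adjustment and decisions
#'
#' Benjamini-Yekutieli by default (the conservative correction recommended
#' for population-genetic scans); Benjamini-Hochberg optionally. B-H
#' rejections always contain the B-Y rejections.
#'
#' @param p p-values in [0, 1]
#' @param method "BY" or "BH"
#' @param alpha nominal FDR level (default 0.05)
#' @return data frame (p, p_adjusted, reject); empty input gives an empty
#'   frame
#' @export
fdr_adjust <- function(p, method = c("BY", "BH"), alpha = 0.05) {
  method <- match.arg(method)
  if (!length(p))
    return(data.frame(p = numeric(0), p_adjusted = numeric(0),
                      reject = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = method)
  data.frame(p = p, p_adjusted = adj, reject = !is.na(adj) & adj <= alpha)
}

#' Ohta's variance decomposition of two-locus LD over subpopulations
#'
#' With unweighted subpopulation means (pbar_i, qbar_j, xbar_ij) over the
#' gametic tables x_k of the k subpopulations:
#' D2_IS  = sum_ij E_k (x_ijk - p_ik q_jk)^2   (within-subpopulation LD)
#' D2_ST  = sum_ij E_k (p_ik q_jk - pbar_i qbar_j)^2
#' D'2_IS = sum_ij E_k (x_ijk - xbar_ij)^2     (variance of LD among pops)
#' D'2_ST = sum_ij (xbar_ij - pbar_i qbar_j)^2 (LD of the pooled averages)
#' D2_IT  = sum_ij E_k (x_ijk - pbar_i qbar_j)^2
#' and D2_IT = D'2_IS + D'2_ST exactly. Drift produces D'2_IS >> D'2_ST
#' (different LD in each population); systematic epistatic selection the
#' reverse. A sample-size-weighted mode is available but the unweighted
#' averages are the LinkDos-style default.
#'
#' @param tables list (>= 2) of joint count matrices with identical dimnames,
#'   one per subpopulation
#' @param weights NULL for unweighted means, or "n" to weight subpopulations
#'   by their gamete counts
#' @return list of the five components
#' @export
ohta_components <- function(tables, weights = NULL) {
  if (length(tables) < 2) stop("need >= 2 subpopulations")
  dims <- lapply(tables, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("gametic tables must share dimensions")
  w <- if (identical(weights, "n")) vapply(tables, sum, numeric(1))
       else rep(1, length(tables))
  w <- w / sum(w)
  X <- lapply(tables, function(t) t / sum(t))          # x_ijk
  PQ <- lapply(X, function(x) outer(rowSums(x), colSums(x)))  # p_ik q_jk
  xbar <- Reduce(`+`, Map(`*`, X, w))
  pbar <- Reduce(`+`, Map(function(x, wk) wk * rowSums(x), X, w))
  qbar <- Reduce(`+`, Map(function(x, wk) wk * colSums(x), X, w))
  pqbar <- outer(pbar, qbar)
  Ek <- function(f) sum(Reduce(`+`, Map(function(k, wk) wk * f(k), seq_along(X), w)))
  list(
    D2_IS  = Ek(function(k) (X[[k]] - PQ[[k]])^2),
    D2_ST  = Ek(function(k) (PQ[[k]] - pqbar)^2),
    Dp2_IS = Ek(function(k) (X[[k]] - xbar)^2),
    Dp2_ST = sum((xbar - pqbar)^2),
    D2_IT  = Ek(function(k) (X[[k]] - pqbar)^2)
  )
}

#' Ohta components for a locus pair from a haplotype table
#'
#' @param ht a [haplotype_table()]
#' @param chromosome chromosome label
#' @param locus_a,locus_b locus pair
#' @param arrangement optional: restrict to chromosomes carrying this
#'   arrangement
#' @param weights passed to [ohta_components()]
#' @return list of components
#' @export
ohta_locus_pair <- function(ht, chromosome, locus_a, locus_b,
                            arrangement = NULL, weights = NULL) {
  df <- as.data.frame(ht)
  df <- df[df$chromosome == chromosome, , drop = FALSE]
  if (!is.null(arrangement))
    df <- df[df$arrangement == arrangement, , drop = FALSE]
  ok <- !is.na(df[[locus_a]]) & !is.na(df[[locus_b]])
  df <- df[ok, , drop = FALSE]
  pops <- unique(df$population)
  if (length(pops) < 2) stop("need >= 2 subpopulations with joint counts")
  la <- sort(unique(df[[locus_a]]))
  lb <- sort(unique(df[[locus_b]]))
  tables <- lapply(pops, function(p) {
    sub <- df[df$population == p, ]
    tab <- table(factor(sub[[locus_a]], levels = la),
                 factor(sub[[locus_b]], levels = lb))
    matrix(as.integer(tab), nrow = length(la),
           dimnames = list(as.character(la), as.character(lb)))
  })
  ohta_components(tables, weights = weights)
}

#' Marker-inversion D'm scan (Table-2-shaped analysis)
#'
#' For every chromosome, locus and population: D'm between the locus and the
#' frequent arrangements (those surviving the group-size filter), with a
#' Monte-Carlo Fisher exact p and an FDR decision across the whole scan.
#'
#' @param ht a [haplotype_table()]
#' @param B permutations per test
#' @param min_group_size arrangements are retained in a population only where
#'   their group passes this size filter
#' @param fdr_method,alpha passed to [fdr_adjust()]
#' @return data frame (chromosome, locus, population, Dm, p, p_adjusted,
#'   significant)
#' @export
dm_scan <- function(ht, B = 1000, min_group_size = 7,
                    fdr_method = "BY", alpha = 0.05) {
  lm <- attr(ht, "locus_map")
  df <- as.data.frame(ht)
  gro <- suppressWarnings(group_counts(ht, min_group_size))
  keep_key <- vapply(gro, function(g)
    paste(g$population, g$chromosome, g$arrangement, sep = "\r"),
    character(1))
  rows <- list()
  for (chrom in unique(df$chromosome)) {
    for (pop in unique(df$population)) {
      sub <- df[df$chromosome == chrom & df$population == pop &
                  paste(df$population, df$chromosome, df$arrangement,
                        sep = "\r") %in% keep_key, , drop = FALSE]
      if (!nrow(sub) || length(unique(sub$arrangement)) < 2) next
      for (l in intersect(lm$locus[lm$chromosome == chrom], names(df))) {
        a <- sub[[l]]; ok <- !is.na(a)
        if (length(unique(a[ok])) < 2) next
        tab <- table(a[ok], sub$arrangement[ok])
        x <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
        rows[[length(rows) + 1L]] <- data.frame(
          chromosome = chrom, locus = l, population = pop,
          Dm = dm_statistic(x), p = mc_exact_test(x, B = B),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no testable locus/population combinations")
  out <- do.call(rbind, rows)
  adj <- fdr_adjust(out$p, method = fdr_method, alpha = alpha)
  out$p_adjusted <- adj$p_adjusted
  out$significant <- adj$reject
  out
}

#' Inter-locus exact tests within an arrangement
#'
#' Monte-Carlo Fisher exact tests for every locus pair among haplotypes
#' carrying one arrangement, either per population or pooled across
#' populations (with an optional exclusion set, e.g. the Scandinavian
#' populations whose drift dominates within-arrangement differentiation).
#' Monomorphic loci are skipped with a message. An FDR column covers the
#' whole table.
#'
#' @param ht a [haplotype_table()]
#' @param chromosome chromosome label
#' @param arrangement arrangement label
#' @param pooled pool populations into one test per pair (default FALSE)
#' @param exclude_populations populations dropped in pooled mode
#' @param B permutations per test
#' @param fdr_method,alpha passed to [fdr_adjust()]
#' @return data frame (locus_a, locus_b, population, p, p_adjusted,
#'   significant)
#' @export
pairwise_locus_ld <- function(ht, chromosome, arrangement, pooled = FALSE,
                              exclude_populations = NULL, B = 1000,
                              fdr_method = "BY", alpha = 0.05) {
  lm <- attr(ht, "locus_map")
  df <- as.data.frame(ht)
  df <- df[df$chromosome == chromosome & df$arrangement == arrangement &
             !(df$population %in% exclude_populations), , drop = FALSE]
  loci <- intersect(lm$locus[lm$chromosome == chromosome], names(df))
  pops <- if (pooled) "pooled" else unique(df$population)
  rows <- list()
  for (pop in pops) {
    sub <- if (pooled) df else df[df$population == pop, , drop = FALSE]
    for (i in seq_along(loci)) for (j in seq_len(i - 1L)) {
      a <- sub[[loci[i]]]; b <- sub[[loci[j]]]
      ok <- !is.na(a) & !is.na(b)
      if (length(unique(a[ok])) < 2 || length(unique(b[ok])) < 2) {
        message("skipping monomorphic pair ", loci[j], "-", loci[i],
                " in ", pop)
        next
      }
      tab <- table(a[ok], b[ok])
      x <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
      rows[[length(rows) + 1L]] <- data.frame(
        locus_a = loci[j], locus_b = loci[i], population = pop,
        p = mc_exact_test(x, B = B), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(locus_a = character(0), locus_b = character(0),
                      population = character(0), p = numeric(0),
                      p_adjusted = numeric(0), significant = logical(0)))
  out <- do.call(rbind, rows)
  adj <- fdr_adjust(out$p, method = fdr_method, alpha = alpha)
  out$p_adjusted <- adj$p_adjusted
  out$significant <- adj$reject
  out
}
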