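# Haploid F_ST (theta) from variance components on allele indicators.
#
# Per locus and allele u: with groups k = 1..r of sizes n_k and allele
# frequencies p_ku,
#   SSA_u = sum_k n_k (p_ku - pbar_u)^2              (df r - 1)
#   SSW_u = sum_k n_k p_ku (1 - p_ku)                (df n - r)
#   n_c   = (n - sum n_k^2 / n) / (r - 1)
#   sigma2_a,u = (MSA - MSW) / n_c ; sigma2_w,u = MSW
# theta_locus = sum_u sigma2_a,u / sum_u (sigma2_a,u + sigma2_w,u), and the
# multi-locus estimate is the ratio of components summed over loci
# (Weir-Cockerham convention), not a mean of ratios. This is mathematically
# the haplotypic AMOVA F_ST with allele-identity distance.

# counts: groups x alleles matrix -> list(sigma_a, sigma_w) summed over alleles
.theta_components <- function(cm) {
  cm <- cm[rowSums(cm) > 0, , drop = FALSE]
  nk <- rowSums(cm)
  n <- sum(nk)
  r <- nrow(cm)
  if (r < 2 || n - r < 1) return(list(sigma_a = NA_real_, sigma_w = NA_real_))
  p <- cm / nk
  pbar <- colSums(cm) / n
  SSA <- colSums(nk * sweep(p, 2, pbar)^2)
  SSW <- colSums(nk * p * (1 - p))
  MSA <- SSA / (r - 1)
  MSW <- SSW / (n - r)
  nc <- (n - sum(nk^2) / n) / (r - 1)
  list(sigma_a = sum((MSA - MSW) / nc), sigma_w = sum(MSW))
}

# assemble a groups x alleles count matrix for one locus
.locus_count_matrix <- function(groups, locus) {
  cnts <- lapply(groups, function(g) g$counts[[locus]])
  alleles <- unique(unlist(lapply(cnts, names)))
  num <- suppressWarnings(as.integer(alleles))
  alleles <- if (anyNA(num)) sort(alleles) else alleles[order(num)]
  cm <- matrix(0L, nrow = length(groups), ncol = length(alleles),
               dimnames = list(NULL, alleles))
  for (i in seq_along(cnts)) {
    if (is.null(cnts[[i]])) next
    cm[i, names(cnts[[i]])] <- cnts[[i]]
  }
  cm
}

#' Haploid multi-locus F_ST (theta) across groups
#'
#' Locus-by-locus variance-component theta over the supplied groups, plus the
#' multi-locus ratio-of-sums estimate. Monomorphic loci contribute zero
#' components; if every locus is monomorphic across all groups the estimate
#' is undefined and an error is signalled.
#'
#' @param groups a [group_counts()] object or plain list of groups
#' @param loci optional subset of loci
#' @param scope label stored in the result (e.g. "between-arrangements")
#' @return object of class `fst_result`: `scope`, `per_locus` data frame
#'   (locus, sigma_a, sigma_w, theta), `theta` (multi-locus), and NULL
#'   `p_value`/`n_permutations` until a permutation test fills them
#' @export
fst_theta <- function(groups, loci = NULL, scope = "global") {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (is.null(loci))
    loci <- unique(unlist(lapply(groups, function(g) names(g$counts))))
  per <- lapply(loci, function(l) {
    cm <- .locus_count_matrix(groups, l)
    vc <- .theta_components(cm)
    data.frame(locus = l, sigma_a = vc$sigma_a, sigma_w = vc$sigma_w,
               theta = vc$sigma_a / (vc$sigma_a + vc$sigma_w),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  sa <- sum(per$sigma_a, na.rm = TRUE)
  sw <- sum(per$sigma_w, na.rm = TRUE)
  if (all(is.na(per$sigma_a)) || (sa == 0 && sw == 0))
    stop("theta undefined: all groups monomorphic at all loci")
  structure(list(scope = scope, per_locus = per, theta = sa / (sa + sw),
                 p_value = NULL, n_permutations = NULL),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("fst_result [%s]: multi-locus theta = %.5f", x$scope, x$theta))
  if (!is.null(x$p_value))
    cat(sprintf(" (p = %.4g, %d permutations)", x$p_value, x$n_permutations))
  cat("\n")
  invisible(x)
}

# haplotype-level allele matrix and integer group factor for fast permutation
.perm_setup <- function(ht, loci = NULL) {
  lm <- attr(ht, "locus_map")
  df <- as.data.frame(ht)
  chrom <- unique(df$chromosome)
  if (length(chrom) != 1)
    stop("permutation test expects haplotypes from a single chromosome")
  chrom_loci <- intersect(lm$locus[lm$chromosome == chrom], names(df))
  if (!is.null(loci)) chrom_loci <- intersect(chrom_loci, loci)
  g <- as.integer(interaction(df$population, df$arrangement, drop = TRUE))
  codes <- lapply(chrom_loci, function(l) {
    a <- df[[l]]
    lev <- sort(unique(a[!is.na(a)]))
    list(code = match(a, lev), K = length(lev))
  })
  names(codes) <- chrom_loci
  list(g = g, r = max(g), codes = codes)
}

.theta_from_codes <- function(setup, g) {
  sa <- 0; sw <- 0
  r <- setup$r
  for (cd in setup$codes) {
    ok <- !is.na(cd$code)
    cm <- matrix(tabulate((g[ok] - 1L) * cd$K + cd$code[ok], r * cd$K),
                 nrow = r, ncol = cd$K, byrow = TRUE)
    vc <- .theta_components(cm)
    if (!is.na(vc$sigma_a)) { sa <- sa + vc$sigma_a; sw <- sw + vc$sigma_w }
  }
  sa / (sa + sw)
}

#' Permutation test of multi-locus theta
#'
#' Haplotypes are permuted among the compared groups (group sizes preserved)
#' and the multi-locus theta recomputed each time;
#' p = (1 + #\{theta_perm >= theta_obs\}) / (B + 1).
#'
#' @param ht a [haplotype_table()] restricted to the haplotypes being
#'   compared (one chromosome); groups are its population x arrangement units
#' @param loci optional locus subset
#' @param B number of permutations (default 10000)
#' @return an `fst_result` with `p_value` and `n_permutations` filled in
#' @export
fst_permutation_test <- function(ht, loci = NULL, B = 10000) {
  if (B < 1) stop("B must be >= 1")
  setup <- .perm_setup(ht, loci)
  if (setup$r < 2) stop("need at least 2 groups")
  obs <- .theta_from_codes(setup, setup$g)
  hits <- 0L
  for (b in seq_len(B)) {
    tb <- .theta_from_codes(setup, sample(setup$g))
    if (!is.na(tb) && tb >= obs) hits <- hits + 1L
  }
  gro <- group_counts(ht, min_group_size = 1)
  res <- fst_theta(gro, loci = loci, scope = "permutation-tested")
  res$p_value <- (1 + hits) / (B + 1)
  res$n_permutations <- B
  res
}

#' Pairwise theta matrix over groups
#'
#' Multi-locus theta for every pair of groups; slightly negative estimates
#' are retained. With `linearized = TRUE`, Slatkin's theta/(1 - theta)
#' transform is applied (Inf, with a warning, where theta = 1), the scale
#' used for isolation-by-distance regressions.
#'
#' @param groups a [group_counts()] object
#' @param loci optional locus subset
#' @param linearized apply theta/(1 - theta)
#' @return object of class `pairwise_fst`: `labels`, `matrix` (symmetric,
#'   zero diagonal), `linearized`
#' @export
pairwise_fst <- function(groups, loci = NULL, linearized = FALSE) {
  if (length(groups) < 2) stop("need at least 2 groups")
  labs <- vapply(groups, function(g)
    paste(g$population, g$arrangement, sep = "/"), character(1))
  m <- matrix(0, length(groups), length(groups), dimnames = list(labs, labs))
  for (i in seq_along(groups)) for (j in seq_len(i - 1L)) {
    th <- tryCatch(fst_theta(list(groups[[i]], groups[[j]]), loci)$theta,
                   error = function(e) NA_real_)
    m[i, j] <- m[j, i] <- th
  }
  if (linearized) {
    if (any(m == 1, na.rm = TRUE)) warning("theta = 1: linearized value is Inf")
    off <- row(m) != col(m)
    m[off] <- m[off] / (1 - m[off])
  }
  structure(list(labels = labs, matrix = m, linearized = linearized),
            class = "pairwise_fst")
}

#' Between- vs within-arrangement partition of differentiation
#'
#' "Between" pools all population x arrangement groups of one chromosome into
#' a single theta analysis; "within:<arr>" estimates theta among the
#' populations carrying that arrangement. Per-locus theta vectors are
#' compared by an exact paired one-sided Wilcoxon signed-rank test (pairing
#' per locus: between-theta against the mean within-theta), the statistic the
#' motivating study reports for its higher-between-than-within contrast.
#'
#' @param ht a [haplotype_table()]
#' @param chromosome chromosome label
#' @param min_group_size passed to [group_counts()]
#' @param exclude_populations population ids dropped before grouping (e.g.
#'   the Scandinavian pair)
#' @param loci optional locus subset (e.g. inside loci only)
#' @return list with `between` (fst_result), `within` (named list of
#'   fst_result, arrangements observed in >= 2 populations), `wilcoxon_p`
#'   and `per_locus` (locus, theta_between, theta_within_mean)
#' @export
partition_fst <- function(ht, chromosome, min_group_size = 7,
                          exclude_populations = NULL, loci = NULL) {
  df <- as.data.frame(ht)
  keep <- df$chromosome == chromosome &
    !(df$population %in% exclude_populations)
  sub <- df[keep, , drop = FALSE]
  if (!nrow(sub)) stop("no haplotypes for chromosome ", chromosome)
  sub <- haplotype_table(sub, attr(ht, "locus_map"), attr(ht, "pop_meta"),
                         attr(ht, "arrangements"))
  gro <- group_counts(sub, min_group_size = min_group_size)
  if (length(unique(vapply(gro, `[[`, character(1), "arrangement"))) < 2)
    stop("need >= 2 arrangements for a between/within partition")
  between <- fst_theta(gro, loci = loci, scope = "between-arrangements")
  arrs <- unique(vapply(gro, `[[`, character(1), "arrangement"))
  within <- list()
  for (arr in arrs) {
    ga <- gro[vapply(gro, function(g) g$arrangement == arr, logical(1))]
    if (length(ga) < 2) {
      warning("arrangement ", arr, " carried by < 2 populations; omitted")
      next
    }
    within[[arr]] <- fst_theta(ga, loci = loci,
                               scope = paste0("within:", arr))
  }
  if (!length(within)) stop("no arrangement observed in >= 2 populations")

  wl <- sapply(within, function(w)
    w$per_locus$theta[match(between$per_locus$locus, w$per_locus$locus)])
  if (is.null(dim(wl))) wl <- matrix(wl, ncol = length(within))
  within_mean <- rowMeans(wl, na.rm = TRUE)
  per_locus <- data.frame(locus = between$per_locus$locus,
                          theta_between = between$per_locus$theta,
                          theta_within_mean = within_mean,
                          stringsAsFactors = FALSE)
  ok <- stats::complete.cases(per_locus[, 2:3])
  wp <- if (sum(ok) >= 2) {
    stats::wilcox.test(per_locus$theta_between[ok],
                       per_locus$theta_within_mean[ok], paired = TRUE,
                       alternative = "greater",
                       exact = sum(ok) <= 25)$p.value
  } else NA_real_
  list(between = between, within = within, wilcoxon_p = wp,
       per_locus = per_locus)
}

#' Principal coordinates of a pairwise theta matrix
#'
#' Classical (Gower) scaling with theta treated as a squared dissimilarity:
#' negative entries are clamped to zero, -theta/2 is double-centred, and
#' coordinates are eigenvector * sqrt(lambda) for positive eigenvalues.
#' Percent variation is over the positive eigenvalues only.
#'
#' @param m a `pairwise_fst` or a symmetric zero-diagonal matrix
#' @return object of class `pcoa_result`: `coordinates`, `eigenvalues`,
#'   `percent` (sums to 100 over positive eigenvalues)
#' @export
pcoa_fst <- function(m) {
  if (inherits(m, "pairwise_fst")) m <- m$matrix
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("matrix must be symmetric")
  m[m < 0] <- 0
  diag(m) <- 0
  n <- nrow(m)
  C <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * C %*% m %*% C
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-9
  lam <- e$values[pos]
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lam), length(lam))
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("Axis", seq_along(lam))
  structure(list(coordinates = coords, eigenvalues = e$values,
                 percent = 100 * lam / sum(lam)),
            class = "pcoa_result")
}
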