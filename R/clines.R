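# Geography: great-circle distances, Mantel isolation-by-distance
# regressions, and latitudinal regressions of arrangement frequencies,
# allele frequencies (most / second-most common allele) and heterozygosity.

#' Great-circle distance between two populations
#'
#' Haversine distance on a sphere of radius 6371.0 km.
#'
#' @param meta_a,meta_b one-row data frames (or lists) with `latitude` and
#'   `longitude` in decimal degrees
#' @return distance in kilometres
#' @export
geo_distance <- function(meta_a, meta_b) {
  geosphere::distHaversine(c(meta_a$longitude, meta_a$latitude),
                           c(meta_b$longitude, meta_b$latitude),
                           r = 6371000) / 1000
}

#' Pairwise distance matrix for a population metadata table
#'
#' @param meta data frame (population, latitude, longitude)
#' @return symmetric km matrix with population dimnames
#' @export
geo_distance_matrix <- function(meta) {
  n <- nrow(meta)
  m <- matrix(0, n, n, dimnames = list(meta$population, meta$population))
  for (i in seq_len(n)) for (j in seq_len(i - 1L))
    m[i, j] <- m[j, i] <- geo_distance(meta[i, ], meta[j, ])
  m
}

#' Isolation-by-distance Mantel regression
#'
#' OLS of pairwise F_ST on log10 geographic distance (km), with significance
#' from a Mantel permutation: population identities are permuted (rows and
#' columns of the F_ST matrix together) and the one-sided p is
#' (1 + #\{slope_perm >= slope_obs\}) / (B + 1). Pairs at zero distance are
#' excluded with a warning.
#'
#' @param fst_matrix square pairwise F_ST matrix whose dimnames are
#'   population ids (a `pairwise_fst` over single-arrangement groups also
#'   works if its labels match `meta$population`)
#' @param meta population metadata (population, latitude, longitude)
#' @param B Mantel permutations (default 10000)
#' @return object of class `ibd_result`: slope, intercept, r_squared,
#'   p_mantel, n_pairs
#' @export
ibd_regression <- function(fst_matrix, meta, B = 10000) {
  if (inherits(fst_matrix, "pairwise_fst")) fst_matrix <- fst_matrix$matrix
  pops <- rownames(fst_matrix)
  if (length(pops) < 4) stop("need >= 4 populations")
  meta <- meta[match(pops, meta$population), ]
  dm <- geo_distance_matrix(meta)
  lt <- lower.tri(dm)
  zero <- lt & dm == 0
  if (any(zero)) {
    warning("coincident populations: ", sum(zero), " pair(s) excluded")
    lt <- lt & dm > 0
  }
  logd <- log10(dm[lt])
  y <- fst_matrix[lt]
  fit <- stats::lm(y ~ logd)
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  # permute population identities; distances fixed, F_ST matrix relabelled
  n <- length(pops)
  hits <- 0L
  for (b in seq_len(B)) {
    pm <- sample.int(n)
    yp <- fst_matrix[pm, pm][lt]
    sp <- stats::cov(yp, logd) / stats::var(logd)
    if (sp >= slope) hits <- hits + 1L
  }
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, p_mantel = (1 + hits) / (B + 1),
                 n_pairs = sum(lt), n_permutations = B),
            class = "ibd_result")
}

#' Polynomial latitude regression of a per-population response
#'
#' OLS of an (optionally arcsin-sqrt transformed) response on latitude,
#' degree 1 for arrangement-frequency clines and degree 2 for the
#' heterozygosity-latitude profile whose maximum falls at mid-latitudes.
#'
#' @param values named numeric vector, one value per population
#' @param meta population metadata
#' @param degree polynomial degree (1 or 2)
#' @param transform "none" or "arcsin-sqrt" (values must then lie in [0,1])
#' @return object of class `cline_fit`: coefficients (intercept first),
#'   r_squared, p_value (overall F test), degree, transform, n
#' @export
latitude_polynomial_fit <- function(values, meta, degree = 1,
                                    transform = c("none", "arcsin-sqrt")) {
  transform <- match.arg(transform)
  pops <- names(values)
  lat <- meta$latitude[match(pops, meta$population)]
  ok <- !is.na(values) & !is.na(lat)
  if (sum(ok) < degree + 2)
    stop("need at least degree + 2 populations")
  y <- values[ok]
  if (transform == "arcsin-sqrt") y <- asin(sqrt(pmin(pmax(y, 0), 1)))
  fit <- stats::lm(y ~ poly(lat[ok], degree, raw = TRUE))
  s <- summary(fit)
  # constant response: no variance to explain
  r2 <- if (stats::sd(y) == 0) 0 else s$r.squared
  pf <- if (is.null(s$fstatistic) || stats::sd(y) == 0) NA_real_ else
    unname(stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                     lower.tail = FALSE))
  structure(list(coefficients = unname(stats::coef(fit)),
                 r_squared = r2, p_value = pf,
                 degree = degree, transform = transform, n = sum(ok)),
            class = "cline_fit")
}

# frequency of each allele of one locus per population within one arrangement
.freqs_by_population <- function(groups, arrangement, locus) {
  ga <- groups[vapply(groups, function(g)
    g$arrangement == arrangement && !is.null(g$counts[[locus]]) &&
      sum(g$counts[[locus]]) > 0, logical(1))]
  if (!length(ga)) return(NULL)
  alleles <- sort(unique(as.integer(unlist(lapply(ga, function(g)
    names(g$counts[[locus]]))))))
  fm <- t(vapply(ga, function(g) {
    f <- stats::setNames(numeric(length(alleles)), alleles)
    fr <- allele_frequencies(g, locus)
    f[names(fr)] <- fr
    f
  }, numeric(length(alleles))))
  rownames(fm) <- vapply(ga, `[[`, character(1), "population")
  fm
}

#' Latitudinal regression of the most common alleles within an arrangement
#'
#' The most common (MCA) and second-most common (SMCA) allele of a locus are
#' ranked by unweighted mean frequency across populations (ties broken by the
#' smaller fragment size); the chosen allele's arcsin-sqrt frequencies are
#' regressed on latitude. The fit is skipped (NULL) when the arrangement is
#' scored in fewer than 4 populations or the locus is not polymorphic there.
#'
#' @param groups a [group_counts()] object
#' @param meta population metadata
#' @param arrangement arrangement label
#' @param locus locus name
#' @param rank "MCA" or "SMCA"
#' @return a `cline_fit` with `allele` attached, or NULL when skipped
#' @export
allele_cline_regression <- function(groups, meta, arrangement, locus,
                                    rank = c("MCA", "SMCA")) {
  rank <- match.arg(rank)
  fm <- .freqs_by_population(groups, arrangement, locus)
  if (is.null(fm) || nrow(fm) < 4 || ncol(fm) < 2) return(NULL)
  mean_f <- colMeans(fm)
  ord <- order(-mean_f, as.integer(colnames(fm)))
  allele <- colnames(fm)[ord[if (rank == "MCA") 1 else 2]]
  fit <- latitude_polynomial_fit(stats::setNames(fm[, allele],
                                                 rownames(fm)),
                                 meta, degree = 1,
                                 transform = "arcsin-sqrt")
  fit$allele <- allele
  fit$rank <- rank
  fit$arrangement <- arrangement
  fit$locus <- locus
  fit
}

#' Batch MCA/SMCA cline scan with FDR control
#'
#' Runs [allele_cline_regression()] for every locus x arrangement x
#' \{MCA, SMCA\} combination with enough populations and applies
#' [fdr_adjust()] across all tests (Table-3-shaped analysis).
#'
#' @param groups a [group_counts()] object
#' @param meta population metadata
#' @param fdr_method,alpha passed to [fdr_adjust()]
#' @return data frame (chromosome, locus, arrangement, rank, allele, slope,
#'   r_squared, p, p_adjusted, significant)
#' @export
allele_cline_scan <- function(groups, meta, fdr_method = "BY", alpha = 0.05) {
  combos <- unique(do.call(rbind, lapply(groups, function(g)
    data.frame(chromosome = g$chromosome, arrangement = g$arrangement,
               locus = names(g$counts), stringsAsFactors = FALSE))))
  rows <- list()
  for (i in seq_len(nrow(combos))) for (rk in c("MCA", "SMCA")) {
    fit <- allele_cline_regression(groups, meta, combos$arrangement[i],
                                   combos$locus[i], rank = rk)
    if (is.null(fit)) next
    rows[[length(rows) + 1L]] <- data.frame(
      chromosome = combos$chromosome[i], locus = combos$locus[i],
      arrangement = combos$arrangement[i], rank = rk, allele = fit$allele,
      slope = fit$coefficients[2], r_squared = fit$r_squared,
      p = fit$p_value, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no testable locus/arrangement combinations")
  out <- do.call(rbind, rows)
  adj <- fdr_adjust(out$p, method = fdr_method, alpha = alpha)
  out$p_adjusted <- adj$p_adjusted
  out$significant <- adj$reject
  out
}

#' Correlation of locus heterozygosity with inversion frequency
#'
#' Pearson correlation, per (locus, arrangement), between the locus He in the
#' arrangement's groups and the arrangement's frequency across the same
#' populations. A mostly non-significant table indicates locus variability is
#' independent of local inversion frequency.
#'
#' @param he_table output of [diversity_table()]
#' @param arrangement_freqs data frame (population, chromosome, arrangement,
#'   frequency)
#' @param alpha significance level for the summary fraction
#' @return list(table = per-pair data frame (chromosome, locus, arrangement,
#'   r, p, n), fraction_nonsignificant)
#' @export
he_inversion_correlation <- function(he_table, arrangement_freqs,
                                     alpha = 0.05) {
  ht <- he_table[he_table$locus != "all", ]
  combos <- unique(ht[, c("chromosome", "arrangement", "locus")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sel <- ht$chromosome == combos$chromosome[i] &
      ht$arrangement == combos$arrangement[i] & ht$locus == combos$locus[i]
    he <- ht[sel, ]
    fr <- arrangement_freqs[
      arrangement_freqs$chromosome == combos$chromosome[i] &
        arrangement_freqs$arrangement == combos$arrangement[i], ]
    m <- merge(he[, c("population", "He")],
               fr[, c("population", "frequency")], by = "population")
    m <- m[stats::complete.cases(m), ]
    if (nrow(m) < 4) next
    if (stats::sd(m$He) == 0 || stats::sd(m$frequency) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = combos$chromosome[i], locus = combos$locus[i],
        arrangement = combos$arrangement[i], r = NA_real_, p = NA_real_,
        n = nrow(m), stringsAsFactors = FALSE)
      next
    }
    ct <- stats::cor.test(m$He, m$frequency)
    rows[[length(rows) + 1L]] <- data.frame(
      chromosome = combos$chromosome[i], locus = combos$locus[i],
      arrangement = combos$arrangement[i], r = unname(ct$estimate),
      p = ct$p.value, n = nrow(m), stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("fewer than 4 matched populations everywhere")
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$p)
  list(table = tab,
       fraction_nonsignificant = mean(tab$p[ok] > alpha))
}

#' Observed arrangement frequencies per population
#'
#' Tabulated from the haplotype table (all scored chromosomes, no group-size
#' filter), the input for arrangement-cline fits and He-frequency
#' correlations.
#'
#' @param ht a [haplotype_table()]
#' @return data frame (population, chromosome, arrangement, n, frequency)
#' @export
arrangement_frequencies <- function(ht) {
  df <- as.data.frame(ht)
  tab <- as.data.frame(table(df$population, df$chromosome, df$arrangement),
                       stringsAsFactors = FALSE)
  names(tab) <- c("population", "chromosome", "arrangement", "n")
  tab <- tab[tab$n > 0 | TRUE, ]
  tot <- stats::aggregate(n ~ population + chromosome, tab, sum)
  m <- merge(tab, tot, by = c("population", "chromosome"),
             suffixes = c("", "_total"))
  m <- m[m$n_total > 0, ]
  m$frequency <- m$n / m$n_total
  # keep only arrangements that belong to the chromosome
  arrs <- attr(ht, "arrangements")
  keep <- paste(m$chromosome, m$arrangement) %in%
    paste(arrs$chromosome, arrs$arrangement)
  m[keep, c("population", "chromosome", "arrangement", "n", "frequency")]
}
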