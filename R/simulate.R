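#' Build a simulation configuration
#'
#' The generator emulates the statistical structure the analysis assumes:
#' arrangement frequencies following multinomial-logit latitudinal clines,
#' arrangement-specific allele pools at loci inside inversions (the
#' frequency-level consequence of recombination suppression in
#' heterokaryotypes), Dirichlet drift of each population's pool around its
#' arrangement pool, and optional injected clinal alleles and two-locus LD.
#'
#' @param pop_meta data frame (population, latitude, longitude); defaults to
#'   the nine-population clinal design of [study_design()]
#' @param clines data frame (chromosome, arrangement, a, b): multinomial-logit
#'   cline coefficients, arrangement score = a + b * latitude
#' @param locus_map locus map as in [study_design()]
#' @param base_freqs named list locus -> named numeric base allele-frequency
#'   vector (names are fragment sizes in bp); default 8 alleles per locus with
#'   geometric-flavoured frequencies giving He near 0.84, the range typical of
#'   the study's microsatellites
#' @param F_arr between-arrangement divergence in [0,1) at inside loci
#'   (default 0.10)
#' @param F_pop within-arrangement among-population divergence in [0,1)
#'   (default 0.007, the study's within-arrangement differentiation scale)
#' @param group_size haplotypes per population x arrangement group in quota
#'   mode (default 30, the modal group size of the study design)
#' @param sampling "quota" (fixed group sizes) or "karyotype" (arrangement
#'   drawn per haplotype from the cline frequencies)
#' @param n_per_pop total haplotypes per population per chromosome in
#'   karyotype mode
#' @param clinal_allele optional list(locus, arrangement, allele, c0, c1):
#'   force that allele's frequency to sin^2(c0 + c1 * latitude) on the
#'   arcsin-sqrt scale, clipped to [0.01, 0.99]
#' @param ld_pair optional list(locus_a, locus_b, arrangement, dprime): couple
#'   the most common alleles of the two loci at the target interallelic D'
#' @param seed integer seed; the whole dataset is reproducible from it
#' @return a `sim_config` list
#' @export
sim_config <- function(pop_meta = NULL, clines = NULL, locus_map = NULL,
                       base_freqs = NULL, F_arr = 0.10, F_pop = 0.007,
                       group_size = 30, sampling = c("quota", "karyotype"),
                       n_per_pop = 60, clinal_allele = NULL, ld_pair = NULL,
                       seed = 1L) {
  design <- study_design()
  if (is.null(pop_meta)) pop_meta <- design$pop_meta
  if (is.null(locus_map)) locus_map <- design$locus_map
  if (is.null(clines)) clines <- default_cline_coefficients()
  if (is.null(base_freqs)) base_freqs <- default_base_freqs(locus_map)
  sampling <- match.arg(sampling)
  if (F_arr < 0 || F_arr >= 1 || F_pop < 0 || F_pop >= 1)
    stop("F_arr and F_pop must lie in [0, 1)")
  if (group_size < 1) stop("group sizes must be >= 1")
  for (l in names(base_freqs)) {
    f <- base_freqs[[l]]
    if (abs(sum(f) - 1) > 1e-8) stop("base frequencies must sum to 1: ", l)
  }
  bad <- setdiff(names(base_freqs), locus_map$locus)
  if (length(bad)) stop("base_freqs for unknown loci: ", paste(bad, collapse = ", "))
  if (!is.null(clinal_allele)) {
    f <- base_freqs[[clinal_allele$locus]]
    if (is.null(f)) stop("clinal_allele: unknown locus ", clinal_allele$locus)
    if (length(f) < 2) stop("clinal_allele: single-allele locus is degenerate")
    if (!(clinal_allele$allele %in% names(f)))
      stop("clinal_allele: allele not in locus pool")
  }
  if (!is.null(ld_pair)) {
    if (is.null(base_freqs[[ld_pair$locus_a]]) ||
        is.null(base_freqs[[ld_pair$locus_b]]))
      stop("ld_pair references unknown loci")
  }
  structure(list(pop_meta = pop_meta, clines = clines, locus_map = locus_map,
                 arrangements = unique(clines[, c("chromosome", "arrangement")]),
                 base_freqs = base_freqs, F_arr = F_arr, F_pop = F_pop,
                 group_size = group_size, sampling = sampling,
                 n_per_pop = n_per_pop, clinal_allele = clinal_allele,
                 ld_pair = ld_pair, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default multinomial-logit cline coefficients
#'
#' Chosen so that, over the 36-60 degree latitude span, standard arrangements
#' rise with latitude and the inverted arrangements (A_2, J_1, U_1+2,
#' U_1+2+8) fall, with realistic mid-latitude polymorphism, matching the
#' qualitative clines reported for these inversions.
#'
#' @return data frame (chromosome, arrangement, a, b)
#' @export
default_cline_coefficients <- function() {
  data.frame(
    chromosome  = c("A", "A", "A", "J", "J", "U", "U", "U"),
    arrangement = c("A_ST", "A_1", "A_2", "J_ST", "J_1",
                    "U_ST", "U_1+2", "U_1+2+8"),
    a = c(0, -2.4, 4.0, 0, 3.4, 0, 3.2, 4.4),
    b = c(0, 0.03, -0.10, 0, -0.08, 0, -0.07, -0.12),
    stringsAsFactors = FALSE
  )
}

#' Default base allele pools
#'
#' Eight alleles per locus at even bp spacing from a locus-specific offset,
#' with tapered frequencies (biased gene diversity 0.84) comparable to the
#' observed microsatellite heterozygosities.
#'
#' @param locus_map locus map
#' @param n_alleles alleles per locus
#' @return named list locus -> named frequency vector
#' @export
default_base_freqs <- function(locus_map, n_alleles = 8) {
  w <- 0.8 ^ (seq_len(n_alleles) - 1)
  w <- w / sum(w)
  out <- lapply(seq_len(nrow(locus_map)), function(i) {
    sizes <- 100 + 10 * i + 2 * (seq_len(n_alleles) - 1)
    stats::setNames(w, sizes)
  })
  names(out) <- locus_map$locus
  out
}

#' Expected arrangement frequencies of a population under the cline model
#'
#' Softmax of the arrangement scores a_k + b_k * latitude, per chromosome.
#'
#' @param config a [sim_config()]
#' @param population population id
#' @return named list chromosome -> named frequency vector
#' @export
cline_arrangement_freqs <- function(config, population) {
  lat <- config$pop_meta$latitude[config$pop_meta$population == population]
  if (!length(lat)) stop("unknown population: ", population)
  out <- list()
  for (chrom in unique(config$clines$chromosome)) {
    cc <- config$clines[config$clines$chromosome == chrom, ]
    s <- exp(cc$a + cc$b * lat)
    out[[chrom]] <- stats::setNames(s / sum(s), cc$arrangement)
  }
  out
}

#' Draw a diverged allele-frequency vector (Balding-Nichols / Dirichlet)
#'
#' Draws from a Dirichlet with concentration base_i * (1 - F) / F, so that
#' E[p] = base and Var(p_i) = F * base_i * (1 - base_i): the expected
#' differentiation between the draw and the base pool is F.
#'
#' @param base_freqs named base frequency vector
#' @param F divergence parameter in [0, 1); F = 0 returns the base exactly
#' @return named frequency vector
#' @export
draw_group_freqs <- function(base_freqs, F) {
  if (F < 0 || F >= 1) stop("F must lie in [0, 1)")
  if (F == 0) return(base_freqs)
  conc <- base_freqs * (1 - F) / F
  g <- stats::rgamma(length(conc), shape = conc, rate = 1)
  if (sum(g) <= 0) { # pathological tiny concentrations: fall back to one draw
    i <- sample.int(length(conc), 1, prob = base_freqs)
    g <- numeric(length(conc)); g[i] <- 1
  }
  stats::setNames(g / sum(g), names(base_freqs))
}

#' Inject a deterministic latitudinal cline into one allele's frequency
#'
#' Sets the target allele's frequency in each population to
#' sin^2(c0 + c1 * latitude), clipped to [0.01, 0.99], and rescales the other
#' alleles proportionally; a regression of arcsin(sqrt(freq)) on latitude
#' recovers slope c1 exactly when no clipping occurs.
#'
#' @param freqs_by_population named list population -> named frequency vector
#' @param clinal_spec list(allele, c0, c1)
#' @param latitudes named numeric vector of population latitudes
#' @return adjusted named list of frequency vectors
#' @export
inject_clinal_allele <- function(freqs_by_population, clinal_spec, latitudes) {
  for (pop in names(freqs_by_population)) {
    f <- freqs_by_population[[pop]]
    if (length(f) < 2) stop("cannot inject a cline at a single-allele locus")
    a <- as.character(clinal_spec$allele)
    target <- sin(clinal_spec$c0 + clinal_spec$c1 * latitudes[[pop]])^2
    target <- min(max(target, 0.01), 0.99)
    rest <- f[setdiff(names(f), a)]
    rest <- rest / sum(rest) * (1 - target)
    f[a] <- target
    f[names(rest)] <- rest
    freqs_by_population[[pop]] <- f
  }
  freqs_by_population
}

#' Simulate a full haplotype dataset with known truth
#'
#' Per chromosome, each arrangement receives its own allele pool at loci
#' inside inversions (drawn once from the base pool with divergence `F_arr`);
#' outside loci share the base pool across arrangements. Each population then
#' re-draws every (arrangement, locus) pool with divergence `F_pop`
#' (within-arrangement drift). Haplotypes sample alleles independently per
#' locus, except for an optional `ld_pair` coupling, and group sizes follow
#' the configured quota or karyotype-draw design.
#'
#' @param config a [sim_config()]
#' @return list with `haplotypes` (a [haplotype_table()]) and `truth` (a
#'   `sim_truth` list: the config, expected arrangement frequencies per
#'   population, and the realized population-level allele pools)
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  lm <- config$locus_map
  pm <- config$pop_meta
  arrs <- config$arrangements
  lat <- stats::setNames(pm$latitude, pm$population)

  # arrangement-level pools
  arr_pools <- list() # [[chrom]][[arr]][[locus]]
  for (chrom in unique(arrs$chromosome)) {
    arr_pools[[chrom]] <- list()
    for (arr in arrs$arrangement[arrs$chromosome == chrom]) {
      pools <- list()
      for (l in lm$locus[lm$chromosome == chrom]) {
        base <- config$base_freqs[[l]]
        inside_any <- nzchar(lm$inside_of[lm$locus == l])
        pools[[l]] <- if (inside_any) draw_group_freqs(base, config$F_arr)
                      else base
      }
      arr_pools[[chrom]][[arr]] <- pools
    }
  }

  # population-level pools (within-arrangement drift), then cline injection
  pop_pools <- list() # [[chrom]][[arr]][[pop]][[locus]]
  for (chrom in names(arr_pools)) {
    pop_pools[[chrom]] <- list()
    for (arr in names(arr_pools[[chrom]])) {
      pop_pools[[chrom]][[arr]] <- list()
      for (pop in pm$population) {
        pop_pools[[chrom]][[arr]][[pop]] <-
          lapply(arr_pools[[chrom]][[arr]],
                 function(f) draw_group_freqs(f, config$F_pop))
      }
    }
  }
  ca <- config$clinal_allele
  if (!is.null(ca)) {
    chrom <- lm$chromosome[lm$locus == ca$locus]
    fbp <- lapply(pop_pools[[chrom]][[ca$arrangement]],
                  function(pools) pools[[ca$locus]])
    fbp <- inject_clinal_allele(fbp, ca, lat)
    for (pop in names(fbp))
      pop_pools[[chrom]][[ca$arrangement]][[pop]][[ca$locus]] <- fbp[[pop]]
  }

  # expected arrangement frequencies (truth)
  arr_freqs <- lapply(pm$population, function(p)
    cline_arrangement_freqs(config, p))
  names(arr_freqs) <- pm$population

  # sample haplotypes
  all_loci <- lm$locus
  rows <- list()
  idx <- 0L
  for (chrom in names(arr_pools)) {
    chrom_loci <- lm$locus[lm$chromosome == chrom]
    for (pop in pm$population) {
      if (config$sampling == "quota") {
        draw_arrs <- rep(names(arr_pools[[chrom]]),
                         each = config$group_size)
      } else {
        fr <- arr_freqs[[pop]][[chrom]]
        draw_arrs <- sample(names(fr), config$n_per_pop, replace = TRUE,
                            prob = fr)
      }
      for (arr in unique(draw_arrs)) {
        n <- sum(draw_arrs == arr)
        pools <- pop_pools[[chrom]][[arr]][[pop]]
        am <- matrix(NA_integer_, nrow = n, ncol = length(all_loci),
                     dimnames = list(NULL, all_loci))
        lp <- config$ld_pair
        coupled <- !is.null(lp) && lp$arrangement == arr &&
          all(c(lp$locus_a, lp$locus_b) %in% chrom_loci)
        for (l in chrom_loci) {
          if (coupled && l %in% c(lp$locus_a, lp$locus_b)) next
          f <- pools[[l]]
          am[, l] <- as.integer(sample(names(f), n, replace = TRUE, prob = f))
        }
        if (coupled) {
          ab <- .draw_ld_pair(pools[[lp$locus_a]], pools[[lp$locus_b]],
                              lp$dprime, n)
          am[, lp$locus_a] <- ab$a
          am[, lp$locus_b] <- ab$b
        }
        df <- data.frame(individual = sprintf("%s_%s_%s_%03d", pop, chrom,
                                              arr, seq_len(n) ),
                         population = pop, chromosome = chrom,
                         arrangement = arr, stringsAsFactors = FALSE)
        rows[[idx <- idx + 1L]] <- cbind(df, as.data.frame(am))
      }
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  ht <- haplotype_table(df, lm, pm, arrs[, c("chromosome", "arrangement")])
  truth <- structure(list(config = config, arrangement_freqs = arr_freqs,
                          allele_freqs = pop_pools), class = "sim_truth")
  list(haplotypes = ht, truth = truth)
}

# couple the most common alleles of two loci at a target interallelic D'
.draw_ld_pair <- function(fa, fb, dprime, n) {
  a_star <- names(fa)[which.max(fa)]
  b_star <- names(fb)[which.max(fb)]
  p <- fa[[a_star]]; q <- fb[[b_star]]
  dmax <- min(p * (1 - q), (1 - p) * q) # positive-D bound
  D <- dprime * dmax
  pr <- c(p * q + D, p * (1 - q) - D, (1 - p) * q - D, (1 - p) * (1 - q) + D)
  pr <- pmax(pr, 0); pr <- pr / sum(pr)
  z <- sample.int(4, n, replace = TRUE, prob = pr)
  draw_other <- function(f, star, m) {
    rest <- f[setdiff(names(f), star)]
    if (!length(rest)) return(rep(star, m))
    sample(names(rest), m, replace = TRUE, prob = rest)
  }
  a <- character(n); b <- character(n)
  a[z <= 2] <- a_star
  a[z > 2] <- draw_other(fa, a_star, sum(z > 2))
  b[z %in% c(1, 3)] <- b_star
  b[z %in% c(2, 4)] <- draw_other(fb, b_star, sum(z %in% c(2, 4)))
  list(a = as.integer(a), b = as.integer(b))
}

#' Write a simulation truth object to JSON
#'
#' @param truth a `sim_truth` from [simulate_dataset()]
#' @param path output path
#' @export
write_sim_truth <- function(truth, path) {
  x <- list(seed = truth$config$seed,
            F_arr = truth$config$F_arr, F_pop = truth$config$F_pop,
            clines = truth$config$clines,
            arrangement_freqs = truth$arrangement_freqs,
            allele_freqs = truth$allele_freqs)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
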