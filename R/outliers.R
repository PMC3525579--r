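# fdist-style F_ST outlier detection: simulate a neutral island-model null
# of (He, F_ST) pairs under infinite-alleles mutation, bin by
# heterozygosity, and flag observed loci outside the He-conditioned
# quantile envelope.

#' Simulate neutral (He, F_ST) pairs under an island model
#'
#' Each locus is an independent structured-coalescent genealogy of the
#' sampled haploid lineages in a symmetric `n_demes`-island model at scaled
#' migration rate M, with infinite-alleles mutation at a rate drawn
#' log-uniformly from `theta_range` (spanning He from roughly 0.05 to 0.95).
#' He is the unbiased gene diversity of the pooled sample and F_ST the same
#' haploid variance-component theta used on observed data. Monomorphic loci
#' are dropped.
#'
#' @param M scaled migration rate
#' @param sample_sizes haplotypes sampled per deme (default 9 demes x 30,
#'   the study design)
#' @param n_demes islands in the universe (default 100)
#' @param n_loci loci to simulate
#' @param theta_range log-uniform range of the mutation parameter, scaled to
#'   the pooled population (the per-deme rate is theta / n_demes), so the
#'   default range spans pooled He of roughly 0.05 to 0.95
#' @return data frame (He, Fst, theta_mut), one row per polymorphic locus
#' @export
simulate_neutral_fst_he <- function(M, sample_sizes = rep(30L, 9),
                                    n_demes = 100, n_loci = 1000,
                                    theta_range = c(0.05, 20)) {
  out <- matrix(NA_real_, n_loci, 3)
  lo <- log(theta_range[1]); hi <- log(theta_range[2])
  for (i in seq_len(n_loci)) {
    th <- exp(stats::runif(1, lo, hi))
    sim <- sim_island_locus_cpp(as.integer(n_demes),
                                as.integer(sample_sizes), M, th / n_demes)
    al <- sim[, 2]
    if (length(unique(al)) < 2) next
    cm <- matrix(tabulate((sim[, 1] - 1L) * max(al) + al,
                          length(sample_sizes) * max(al)),
                 nrow = length(sample_sizes), byrow = TRUE)
    cm <- cm[, colSums(cm) > 0, drop = FALSE]
    n <- sum(cm)
    p <- colSums(cm) / n
    he <- (1 - sum(p^2)) * n / (n - 1)
    vc <- .theta_components(cm)
    out[i, ] <- c(he, vc$sigma_a / (vc$sigma_a + vc$sigma_w), th)
  }
  out <- out[!is.na(out[, 1]), , drop = FALSE]
  data.frame(He = out[, 1], Fst = out[, 2], theta_mut = out[, 3])
}

#' Calibrate the island-model migration rate to a target F_ST
#'
#' Starting from M0 solving target = 1/(1 + 2 M), bisects on log M until the
#' median simulated per-locus F_ST of a pilot batch lies within +/-5%
#' relative of the target. The median simulated F_ST is monotone decreasing
#' in M, so bracketed bisection converges.
#'
#' @param target_fst target F_ST in (0, 1)
#' @param sample_sizes,n_demes,theta_range as in [simulate_neutral_fst_he()]
#' @param n_pilot pilot loci per bisection step (>= 2000 recommended)
#' @param max_iter iteration cap (error with diagnostics on overrun)
#' @param tol relative tolerance on the median (default 0.05)
#' @return calibrated M, with attribute `median_fst`
#' @export
calibrate_island_model <- function(target_fst, sample_sizes = rep(30L, 9),
                                   n_demes = 100, theta_range = c(0.05, 20),
                                   n_pilot = 2000, max_iter = 40,
                                   tol = 0.05) {
  if (target_fst <= 0 || target_fst >= 1) stop("target_fst must be in (0,1)")
  med <- function(M)
    stats::median(simulate_neutral_fst_he(M, sample_sizes, n_demes,
                                          n_pilot, theta_range)$Fst)
  M0 <- (1 / target_fst - 1) / 2
  lo <- M0 / 16; hi <- M0 * 16
  f_lo <- med(lo); f_hi <- med(hi)
  it <- 0
  while (f_lo < target_fst && it < 5) { lo <- lo / 4; f_lo <- med(lo); it <- it + 1 }
  while (f_hi > target_fst && it < 10) { hi <- hi * 4; f_hi <- med(hi); it <- it + 1 }
  if (f_lo < target_fst || f_hi > target_fst)
    stop(sprintf("cannot bracket target %.4g: median F_ST in [%.4g, %.4g]",
                 target_fst, f_hi, f_lo))
  for (i in seq_len(max_iter)) {
    M <- sqrt(lo * hi)
    f <- med(M)
    if (abs(f - target_fst) <= tol * target_fst)
      return(structure(M, median_fst = f))
    if (f > target_fst) lo <- M else hi <- M
  }
  stop(sprintf(paste0("island-model calibration did not converge in %d ",
                      "iterations: target %.4g, last median %.4g at M = %.4g"),
               max_iter, target_fst, f, M))
}

#' Build an He-conditioned quantile envelope from neutral simulations
#'
#' He in (0, 1) is cut into `n_bins` equal-width bins; per bin the
#' alpha/2 and 1 - alpha/2 quantiles of simulated F_ST form the neutral
#' envelope. Empty bins inherit the nearest populated bin.
#'
#' @param sims output of [simulate_neutral_fst_he()] (>= 1e4 loci for a
#'   production scan; smaller for exploration)
#' @param n_bins number of equal-He bins (default 50)
#' @param alpha two-sided tail probability (default 0.01)
#' @param M,target_fst optional provenance recorded in the envelope
#' @return object of class `outlier_envelope`
#' @export
build_envelope <- function(sims, n_bins = 50, alpha = 0.01, M = NA,
                           target_fst = NA) {
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(sims$He, edges, rightmost.closed = TRUE),
                   1L), n_bins)
  lower <- upper <- rep(NA_real_, n_bins)
  nb <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    f <- sims$Fst[bin == b]
    nb[b] <- length(f)
    if (length(f) >= 2) {
      # type-6 ((n+1)-rule) quantiles: the exceedance probability of a new
      # neutral locus beyond the estimated tail stays at ~alpha/2 even with
      # moderate per-bin counts
      q <- stats::quantile(f, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                           type = 6)
      lower[b] <- q[1]; upper[b] <- q[2]
    }
  }
  # fill empty bins from the nearest populated one
  pop_bins <- which(!is.na(lower))
  if (!length(pop_bins)) stop("no populated He bins")
  for (b in which(is.na(lower))) {
    nb_near <- pop_bins[which.min(abs(pop_bins - b))]
    lower[b] <- lower[nb_near]; upper[b] <- upper[nb_near]
  }
  structure(list(edges = edges, lower = lower, upper = upper,
                 n_per_bin = nb, n_loci = nrow(sims), alpha = alpha,
                 M = M, target_fst = target_fst, sims = sims),
            class = "outlier_envelope")
}

#' Write / read an envelope as a JSON artifact
#'
#' @param envelope an `outlier_envelope`
#' @param path JSON path
#' @export
write_envelope <- function(envelope, path) {
  x <- envelope[c("edges", "lower", "upper", "n_per_bin", "n_loci",
                  "alpha", "M", "target_fst")]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Classify observed loci against a neutral envelope
#'
#' Each observed locus is assigned "positive" (F_ST above its He-bin upper
#' quantile), "balancing" (below the lower quantile) or "neutral", with an
#' empirical per-locus p (fraction of simulated F_ST in the bin at or above
#' the observed value). Loci with He outside the simulated range use the
#' nearest bin and are flagged.
#'
#' @param observed data frame with columns `locus`, `He`, `Fst`
#' @param envelope an `outlier_envelope`
#' @return data frame (locus, He, Fst, p_upper, classification,
#'   he_out_of_range)
#' @export
classify_outliers <- function(observed, envelope) {
  n_bins <- length(envelope$lower)
  sims <- envelope$sims
  he_rng <- range(sims$He)
  bin <- pmin(pmax(findInterval(observed$He, envelope$edges,
                                rightmost.closed = TRUE), 1L), n_bins)
  simbin <- pmin(pmax(findInterval(sims$He, envelope$edges,
                                   rightmost.closed = TRUE), 1L), n_bins)
  out <- observed
  out$p_upper <- NA_real_
  out$classification <- "neutral"
  out$he_out_of_range <- observed$He < he_rng[1] | observed$He > he_rng[2]
  for (i in seq_len(nrow(observed))) {
    b <- bin[i]
    f <- sims$Fst[simbin == b]
    if (!length(f)) { # nearest populated bin
      pop_bins <- sort(unique(simbin))
      b <- pop_bins[which.min(abs(pop_bins - b))]
      f <- sims$Fst[simbin == b]
    }
    out$p_upper[i] <- mean(f >= observed$Fst[i])
    if (observed$Fst[i] > envelope$upper[bin[i]])
      out$classification[i] <- "positive"
    else if (observed$Fst[i] < envelope$lower[bin[i]])
      out$classification[i] <- "balancing"
  }
  out
}

#' Full fdist-style outlier scan of one arrangement's loci
#'
#' Computes per-locus He (pooled) and within-arrangement F_ST across
#' populations, calibrates the island model to the observed multi-locus
#' F_ST, simulates the neutral envelope and classifies each locus. One
#' optional refinement pass removes flagged loci, recalibrates to the
#' remaining loci's multi-locus F_ST and re-classifies.
#'
#' @param groups a [group_counts()] object restricted to one arrangement
#'   (>= 2 populations)
#' @param n_loci simulated loci for the envelope (default 10000; use 1e5 to
#'   match a production scan)
#' @param alpha two-sided tail probability (default 0.01)
#' @param n_demes,theta_range island-model settings
#' @param refine run one outlier-removal recalibration pass
#' @param n_pilot pilot size for calibration
#' @return list(classification, envelope, M, target_fst)
#' @export
outlier_scan <- function(groups, n_loci = 10000, alpha = 0.01,
                         n_demes = 100, theta_range = c(0.05, 20),
                         refine = FALSE, n_pilot = 2000) {
  loci <- unique(unlist(lapply(groups, function(g) names(g$counts))))
  obs <- .observed_he_fst(groups, loci)
  sample_sizes <- vapply(groups, `[[`, numeric(1), "n")
  run <- function(target, loci_used) {
    M <- calibrate_island_model(target, sample_sizes = sample_sizes,
                                n_demes = n_demes,
                                theta_range = theta_range,
                                n_pilot = n_pilot)
    sims <- simulate_neutral_fst_he(M, sample_sizes, n_demes, n_loci,
                                    theta_range)
    env <- build_envelope(sims, alpha = alpha, M = as.numeric(M),
                          target_fst = target)
    list(M = M, envelope = env,
         classification = classify_outliers(obs, env))
  }
  target <- fst_theta(groups, loci)$theta
  target <- min(max(target, 0.001), 0.99)
  res <- run(target, loci)
  if (refine) {
    keep <- res$classification$locus[res$classification$classification ==
                                       "neutral"]
    if (length(keep) >= 2 && length(keep) < length(loci)) {
      target2 <- fst_theta(groups, keep)$theta
      target2 <- min(max(target2, 0.001), 0.99)
      res <- run(target2, keep)
      target <- target2
    }
  }
  list(classification = res$classification, envelope = res$envelope,
       M = as.numeric(res$M), target_fst = target)
}

# per-locus pooled He and across-group theta
.observed_he_fst <- function(groups, loci) {
  rows <- lapply(loci, function(l) {
    cm <- .locus_count_matrix(groups, l)
    n <- sum(cm)
    if (n < 2 || ncol(cm) < 2) return(NULL)
    p <- colSums(cm) / n
    he <- (1 - sum(p^2)) * n / (n - 1)
    vc <- .theta_components(cm)
    data.frame(locus = l, He = he,
               Fst = vc$sigma_a / (vc$sigma_a + vc$sigma_w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("no polymorphic loci to scan")
  out
}
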