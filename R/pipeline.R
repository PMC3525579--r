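# Orchestration: run every analysis stage on a haplotype table and render
# study-shaped report tables.

#' Pipeline configuration
#'
#' @param B permutations for all permutation tests (>= 100)
#' @param min_group_size group-size filter (default 7)
#' @param min_obs minimum joint count for allele-inversion associations
#' @param fdr_method,alpha FDR settings
#' @param exclude_populations populations excluded from within-arrangement
#'   pooled analyses (e.g. the Scandinavian pair)
#' @param run_outliers run the (slow) outlier scan stage
#' @param outlier_loci simulated loci for the outlier envelope
#' @param seed integer seed controlling every stochastic stage
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(B = 1000, min_group_size = 7, min_obs = 3,
                            fdr_method = "BY", alpha = 0.05,
                            exclude_populations = NULL,
                            run_outliers = FALSE, outlier_loci = 2000,
                            seed = 1L) {
  if (B < 100) stop("B must be >= 100")
  structure(list(B = B, min_group_size = min_group_size, min_obs = min_obs,
                 fdr_method = fdr_method, alpha = alpha,
                 exclude_populations = exclude_populations,
                 run_outliers = run_outliers, outlier_loci = outlier_loci,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes diversity, differentiation (between/within-arrangement partition,
#' pairwise matrices, PCoA), linkage (marker-inversion D'm scan, interallelic
#' D', Ohta components for inside-locus pairs), clines (arrangement and
#' allele-frequency latitude regressions, He-latitude quadratic, IBD Mantel
#' regressions) and optionally the outlier scan. Stage failures are caught:
#' the bundle is marked partial and earlier stages preserved. Deterministic
#' given the config seed.
#'
#' @param ht a [haplotype_table()]
#' @param config a [pipeline_config()]
#' @return object of class `pipeline_bundle` with elements `stages` (named
#'   list), `errors`, `partial`, `config`
#' @export
run_pipeline <- function(ht, config = pipeline_config()) {
  set.seed(config$seed)
  meta <- attr(ht, "pop_meta")
  lm <- attr(ht, "locus_map")
  stages <- list()
  errors <- list()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) errors[[name]] <<- conditionMessage(res)
    else stages[[name]] <<- res
    invisible(NULL)
  }
  gro <- suppressWarnings(group_counts(ht, config$min_group_size))
  chroms <- unique(vapply(gro, `[[`, character(1), "chromosome"))

  run_stage("diversity", {
    list(table = diversity_table(gro),
         arrangement_freqs = arrangement_frequencies(ht))
  })

  run_stage("structure", {
    out <- list()
    for (ch in chroms) {
      part <- tryCatch(
        partition_fst(ht, ch, min_group_size = config$min_group_size),
        error = function(e) NULL)
      gch <- gro[vapply(gro, function(g) g$chromosome == ch, logical(1))]
      pw <- if (length(gch) >= 2) pairwise_fst(gch) else NULL
      out[[ch]] <- list(partition = part, pairwise = pw,
                        pcoa = if (!is.null(pw)) pcoa_fst(pw) else NULL)
    }
    out
  })

  run_stage("linkage", {
    dm <- dm_scan(ht, B = config$B, min_group_size = config$min_group_size,
                  fdr_method = config$fdr_method, alpha = config$alpha)
    # interallelic D' where the D'm scan flagged significance
    sig <- dm[dm$significant, , drop = FALSE]
    allele_d <- list()
    df <- as.data.frame(ht)
    for (i in seq_len(nrow(sig))) {
      sub <- df[df$chromosome == sig$chromosome[i] &
                  df$population == sig$population[i], , drop = FALSE]
      sub_ht <- haplotype_table(sub, lm, meta, attr(ht, "arrangements"))
      tab <- gametic_table(sub_ht, sig$locus[i])
      if (nrow(tab) >= 2 && ncol(tab) >= 2)
        allele_d[[paste(sig$locus[i], sig$population[i], sep = "/")]] <-
          allele_inversion_dprime(tab, min_obs = config$min_obs)
    }
    # Ohta components for inside-locus pairs within each arrangement
    ohta <- list()
    for (ch in chroms) {
      loci_in <- lm$locus[lm$chromosome == ch & nzchar(lm$inside_of)]
      if (length(loci_in) < 2) next
      arrs <- unique(vapply(gro[vapply(gro, function(g)
        g$chromosome == ch, logical(1))], `[[`, character(1), "arrangement"))
      for (arr in arrs) {
        comb <- utils::combn(loci_in, 2)
        for (j in seq_len(ncol(comb))) {
          oc <- tryCatch(ohta_locus_pair(ht, ch, comb[1, j], comb[2, j],
                                         arrangement = arr),
                         error = function(e) NULL)
          if (!is.null(oc))
            ohta[[paste(arr, comb[1, j], comb[2, j], sep = "/")]] <- oc
        }
      }
    }
    list(dm = dm, allele_dprime = allele_d, ohta = ohta)
  })

  run_stage("clines", {
    af <- arrangement_frequencies(ht)
    arr_fits <- list()
    for (i in seq_len(nrow(unique(af[, c("chromosome", "arrangement")])))) {
      key <- unique(af[, c("chromosome", "arrangement")])[i, ]
      sel <- af$chromosome == key$chromosome &
        af$arrangement == key$arrangement
      v <- stats::setNames(af$frequency[sel], af$population[sel])
      if (length(v) >= 4)
        arr_fits[[key$arrangement]] <- latitude_polynomial_fit(
          v, meta, degree = 1, transform = "arcsin-sqrt")
    }
    # He (arrangement-frequency diversity) vs latitude, quadratic
    he_fits <- list()
    for (ch in unique(af$chromosome)) {
      sub <- af[af$chromosome == ch, ]
      he <- vapply(split(sub, sub$population), function(s)
        arrangement_diversity(s$frequency / sum(s$frequency)), numeric(1))
      if (length(he) >= 4)
        he_fits[[ch]] <- latitude_polynomial_fit(he, meta, degree = 2,
                                                 transform = "arcsin-sqrt")
    }
    scan <- allele_cline_scan(gro, meta, fdr_method = config$fdr_method,
                              alpha = config$alpha)
    # IBD per arrangement carried by >= 4 populations
    ibd <- list()
    for (ch in chroms) {
      arrs <- unique(vapply(gro[vapply(gro, function(g)
        g$chromosome == ch, logical(1))], `[[`, character(1), "arrangement"))
      for (arr in arrs) {
        ga <- gro[vapply(gro, function(g)
          g$chromosome == ch && g$arrangement == arr, logical(1))]
        if (length(ga) < 4) next
        pw <- pairwise_fst(ga)
        rownames(pw$matrix) <- colnames(pw$matrix) <-
          vapply(ga, `[[`, character(1), "population")
        ibd[[arr]] <- ibd_regression(pw$matrix, meta, B = config$B)
      }
    }
    list(arrangement_fits = arr_fits, he_latitude = he_fits,
         allele_scan = scan, ibd = ibd)
  })

  if (config$run_outliers) run_stage("outliers", {
    out <- list()
    for (ch in chroms) {
      arrs <- unique(vapply(gro[vapply(gro, function(g)
        g$chromosome == ch, logical(1))], `[[`, character(1), "arrangement"))
      for (arr in arrs) {
        ga <- gro[vapply(gro, function(g)
          g$chromosome == ch && g$arrangement == arr, logical(1))]
        if (length(ga) < 2) next
        out[[arr]] <- outlier_scan(ga, n_loci = config$outlier_loci,
                                   n_pilot = min(config$outlier_loci, 2000))
      }
    }
    out
  })

  structure(list(stages = stages, errors = errors,
                 partial = length(errors) > 0, config = config),
            class = "pipeline_bundle")
}

#' Significance stars
#'
#' @param p p-values
#' @return "***" for p < 0.001, "**" for p < 0.01, "*" for p < 0.05, else ""
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                         ifelse(p < 0.05, "*", ""))))
}

#' Render a report bundle as study-shaped TSV tables
#'
#' Writes a diversity table (arrangements x populations with n and He
#' interleaved), a marker-inversion D'm table (loci x populations with
#' significance stars), an allele-cline table (R-squared per locus x
#' arrangement for MCA and SMCA) and a summary text file. Missing stages are
#' noted in the summary of a partial bundle.
#'
#' @param bundle a `pipeline_bundle`
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
render_report <- function(bundle, dir) {
  if (!length(bundle$stages)) stop("empty bundle")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(x, f) {
    p <- file.path(dir, f)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "-")
    paths <<- c(paths, p)
  }
  if (!is.null(bundle$stages$diversity)) {
    dt <- bundle$stages$diversity$table
    dt <- dt[dt$locus == "all", ]
    pops <- unique(dt$population)
    keys <- unique(dt[, c("chromosome", "arrangement")])
    out <- data.frame(arrangement = rep(keys$arrangement, each = 2),
                      quantity = rep(c("n", "He"), nrow(keys)),
                      stringsAsFactors = FALSE)
    for (p in pops) {
      col <- character(nrow(out))
      for (i in seq_len(nrow(keys))) {
        sel <- dt$population == p & dt$arrangement == keys$arrangement[i]
        col[2 * i - 1] <- if (any(sel)) as.character(dt$n[sel][1]) else "-"
        col[2 * i] <- if (any(sel)) sprintf("%.3f", dt$He[sel][1]) else "-"
      }
      out[[p]] <- col
    }
    w(out, "diversity_by_arrangement.tsv")
  }
  if (!is.null(bundle$stages$linkage)) {
    dm <- bundle$stages$linkage$dm
    pops <- unique(dm$population)
    keys <- unique(dm[, c("chromosome", "locus")])
    out <- keys
    for (p in pops) {
      col <- character(nrow(keys))
      for (i in seq_len(nrow(keys))) {
        sel <- dm$population == p & dm$locus == keys$locus[i]
        col[i] <- if (any(sel))
          paste0(sprintf("%.3f", dm$Dm[sel][1]),
                 significance_stars(dm$p_adjusted[sel][1]))
        else "-"
      }
      out[[p]] <- col
    }
    w(out, "marker_inversion_dm.tsv")
  }
  if (!is.null(bundle$stages$clines)) {
    sc <- bundle$stages$clines$allele_scan
    out <- sc[, c("chromosome", "locus", "arrangement", "rank", "allele")]
    out$r_squared <- sprintf("%.3f%s", sc$r_squared,
                             ifelse(sc$significant, "*", ""))
    w(out, "allele_clines.tsv")
  }
  summ <- c(sprintf("pipeline bundle: %d stage(s) complete%s",
                    length(bundle$stages),
                    if (bundle$partial) " (PARTIAL)" else ""))
  if (bundle$partial)
    summ <- c(summ, paste0("missing stage ", names(bundle$errors), ": ",
                           unlist(bundle$errors)))
  if (!is.null(bundle$stages$structure)) {
    for (ch in names(bundle$stages$structure)) {
      part <- bundle$stages$structure[[ch]]$partition
      if (is.null(part)) next
      summ <- c(summ, sprintf(
        "chromosome %s: between-arrangement theta = %.4f, mean within = %.4f, Wilcoxon p = %.4g",
        ch, part$between$theta,
        mean(vapply(part$within, `[[`, numeric(1), "theta")),
        part$wilcoxon_p))
    }
  }
  p <- file.path(dir, "summary.txt")
  writeLines(summ, p)
  paths <- c(paths, p)
  invisible(paths)
}
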