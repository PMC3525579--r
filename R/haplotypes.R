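#' Construct and validate a haplotype table
#'
#' A haplotype table holds one row per phased wild chromosome: the individual
#' and population it came from, the chromosome, the gene arrangement
#' (karyotypic class) it carries, and one column per microsatellite locus with
#' the allele as an integer fragment size in base pairs (NA = missing).
#' Alleles may only be scored at loci belonging to the row's chromosome.
#'
#' @param df data frame with columns `individual`, `population`,
#'   `chromosome`, `arrangement`, then one column per locus
#' @param locus_map data frame (locus, chromosome, cyto_order, inside_of,
#'   region), see [study_design()]
#' @param pop_meta data frame (population, latitude, longitude, ...)
#' @param arrangements data frame (chromosome, arrangement) declaring the
#'   valid arrangements per chromosome
#' @return the validated data frame with class `haplotype_table` and the
#'   three metadata tables attached as attributes
#' @export
haplotype_table <- function(df, locus_map, pop_meta, arrangements) {
  req <- c("individual", "population", "chromosome", "arrangement")
  if (!all(req %in% names(df)))
    stop("haplotype table must have columns: ", paste(req, collapse = ", "))
  .validate_pop_meta(pop_meta)
  locus_cols <- setdiff(names(df), req)
  unknown <- setdiff(locus_cols, locus_map$locus)
  if (length(unknown))
    stop("columns not in locus map: ", paste(unknown, collapse = ", "))

  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!(r$population %in% pop_meta$population))
      stop(sprintf("row %d: unknown population '%s'", i, r$population))
    decl <- arrangements$arrangement[arrangements$chromosome == r$chromosome]
    if (!length(decl))
      stop(sprintf("row %d: unknown chromosome '%s'", i, r$chromosome))
    if (!(r$arrangement %in% decl))
      stop(sprintf("row %d: arrangement '%s' not declared for chromosome '%s'",
                   i, r$arrangement, r$chromosome))
    chrom_loci <- locus_map$locus[locus_map$chromosome == r$chromosome]
    scored <- locus_cols[!is.na(unlist(df[i, locus_cols]))]
    off <- setdiff(scored, chrom_loci)
    if (length(off))
      stop(sprintf("row %d: allele scored at locus not on chromosome '%s': %s",
                   i, r$chromosome, paste(off, collapse = ", ")))
    vals <- unlist(df[i, scored])
    if (length(vals) && any(vals != round(vals) | vals <= 0))
      stop(sprintf("row %d: alleles must be positive integers (bp sizes)", i))
  }
  dup <- duplicated(df[, c("individual", "chromosome")])
  if (any(dup))
    stop("duplicate (individual, chromosome): row ",
         paste(which(dup), collapse = ", "))

  structure(df, locus_map = locus_map, pop_meta = pop_meta,
            arrangements = arrangements,
            class = c("haplotype_table", "data.frame"))
}

.validate_pop_meta <- function(pop_meta) {
  stopifnot(all(c("population", "latitude", "longitude") %in% names(pop_meta)))
  if (any(abs(pop_meta$latitude) > 90) || any(abs(pop_meta$longitude) > 180))
    stop("population coordinates out of range")
  invisible(pop_meta)
}

#' Read a haplotype table from a delimited text file
#'
#' The file must be TSV (or CSV for a `.csv` extension) with a header naming
#' `individual`, `population`, `chromosome`, `arrangement` followed by one
#' column per locus; missing alleles are empty cells or "NA". Rows are
#' validated against the locus map, population metadata and declared
#' arrangements; validation errors name the offending row.
#'
#' @inheritParams haplotype_table
#' @param path file path
#' @return a [haplotype_table()]
#' @export
read_haplotype_table <- function(path, locus_map, pop_meta, arrangements) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  haplotype_table(df, locus_map, pop_meta, arrangements)
}

#' Write a haplotype table to TSV
#'
#' Inverse of [read_haplotype_table()]: a read-write-read round trip
#' preserves records exactly.
#'
#' @param ht a haplotype table
#' @param path output path
#' @export
write_haplotype_table <- function(ht, path) {
  utils::write.table(as.data.frame(ht), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a locus map / population metadata file
#'
#' @param path TSV with columns locus, chromosome, cyto_order, inside_of,
#'   region (locus map) or population, latitude, longitude, year (metadata)
#' @return data frame
#' @export
read_locus_map <- function(path) {
  lm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  if (!"inside_of" %in% names(lm)) lm$inside_of <- ""
  lm$inside_of[is.na(lm$inside_of)] <- ""
  if (anyDuplicated(lm$locus)) stop("duplicated locus in map")
  lm
}

#' @rdname read_locus_map
#' @export
read_population_meta <- function(path) {
  pm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  .validate_pop_meta(pm)
  pm
}

#' Group haplotypes into population x arrangement analysis units
#'
#' Haplotypes carrying the same arrangement in the same population form one
#' study unit. Groups smaller than `min_group_size` are dropped (with a
#' warning), mirroring the field practice of excluding rare-arrangement
#' samples; the default of 7 is the smallest group size retained in the
#' motivating study. Missing alleles are excluded locus-wise, so per-locus
#' sample sizes may vary within a group.
#'
#' @param ht a [haplotype_table()]
#' @param min_group_size minimum haplotypes per group (default 7)
#' @param loci optional subset of loci to tabulate
#' @return an object of class `group_counts`: a list of groups, each a list
#'   with `population`, `chromosome`, `arrangement`, `n` (group size),
#'   `counts` (per locus, a named integer vector of allele counts) and
#'   `n_locus` (haplotypes scored per locus)
#' @export
group_counts <- function(ht, min_group_size = 7, loci = NULL) {
  lm <- attr(ht, "locus_map")
  df <- as.data.frame(ht)
  key <- interaction(df$population, df$chromosome, df$arrangement, drop = TRUE)
  groups <- list()
  dropped <- character(0)
  for (k in levels(key)) {
    rows <- df[key == k, , drop = FALSE]
    r1 <- rows[1, ]
    if (nrow(rows) < min_group_size) {
      dropped <- c(dropped, sprintf("%s/%s/%s (n=%d)", r1$population,
                                    r1$chromosome, r1$arrangement, nrow(rows)))
      next
    }
    chrom_loci <- lm$locus[lm$chromosome == r1$chromosome]
    chrom_loci <- intersect(chrom_loci, names(rows))
    if (!is.null(loci)) chrom_loci <- intersect(chrom_loci, loci)
    counts <- lapply(chrom_loci, function(l) {
      a <- rows[[l]]
      a <- a[!is.na(a)]
      tab <- table(a)
      stats::setNames(as.integer(tab), names(tab))
    })
    names(counts) <- chrom_loci
    g <- list(population = r1$population, chromosome = r1$chromosome,
              arrangement = r1$arrangement, n = nrow(rows),
              counts = counts,
              n_locus = vapply(counts, sum, integer(1)))
    class(g) <- "hap_group"
    groups[[k]] <- g
  }
  if (length(dropped))
    warning("dropped groups below min_group_size: ",
            paste(dropped, collapse = "; "))
  structure(groups, class = "group_counts")
}

#' @export
print.group_counts <- function(x, ...) {
  cat(sprintf("group_counts: %d groups\n", length(x)))
  for (g in x)
    cat(sprintf("  %s / %s / %s : n = %d\n", g$population, g$chromosome,
                g$arrangement, g$n))
  invisible(x)
}

#' Allele frequencies of one locus in one group
#'
#' @param group a group from [group_counts()]
#' @param locus locus name
#' @return named numeric vector of frequencies summing to 1
#' @export
allele_frequencies <- function(group, locus) {
  cnt <- group$counts[[locus]]
  if (is.null(cnt) || sum(cnt) < 1)
    stop("locus not scored in group: ", locus)
  cnt / sum(cnt)
}

#' Export groups as a haploid-as-homozygous Genepop file
#'
#' Haploid data are written in the Genepop dialect used by LinkDos-era tools:
#' each haplotype becomes a homozygous diploid genotype, alleles rank-encoded
#' per locus into 3-digit codes. A sidecar file `<path>.codes.tsv` records the
#' allele-size/code mapping so fragment sizes can be restored.
#'
#' @param groups a [group_counts()] object (non-empty)
#' @param path output path
#' @return invisibly, the code map data frame (locus, allele, code)
#' @export
write_genepop <- function(groups, path) {
  if (!length(groups)) stop("empty group list")
  loci <- unique(unlist(lapply(groups, function(g) names(g$counts))))
  code_map <- do.call(rbind, lapply(loci, function(l) {
    alleles <- sort(unique(as.integer(unlist(
      lapply(groups, function(g) names(g$counts[[l]]))))))
    if (length(alleles) > 999)
      stop("more than 999 distinct alleles at locus ", l)
    data.frame(locus = l, allele = alleles,
               code = sprintf("%03d", seq_along(alleles)),
               stringsAsFactors = FALSE)
  }))
  lines <- c("invclines haploid-as-homozygous export", loci)
  for (g in groups) {
    lines <- c(lines, "Pop")
    # expand counts back to pseudo-individual genotype strings
    n <- g$n
    geno <- matrix("000000", nrow = n, ncol = length(loci))
    for (j in seq_along(loci)) {
      cnt <- g$counts[[loci[j]]]
      if (is.null(cnt) || !sum(cnt)) next
      cm <- code_map[code_map$locus == loci[j], ]
      codes <- rep(cm$code[match(as.integer(names(cnt)), cm$allele)], cnt)
      geno[seq_along(codes), j] <- paste0(codes, codes)
    }
    id <- sprintf("%s_%s_%s_%d", g$population, g$chromosome, g$arrangement,
                  seq_len(n))
    lines <- c(lines, paste(id, ",", apply(geno, 1, paste, collapse = " ")))
  }
  writeLines(lines, path)
  utils::write.table(code_map, paste0(path, ".codes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(code_map)
}
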