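#' Default study design: nine clinal populations, three chromosomes, 19 loci
#'
#' Returns the sampling design used throughout the package as defaults: nine
#' European populations spanning roughly 24 degrees of latitude, three
#' chromosomes (the A sex chromosome and the J and U autosomes) with their
#' frequent gene arrangements, and nineteen microsatellite loci with their
#' cytological order and inside/outside classification relative to the
#' inversions. Latitudes are decimal degrees converted from printed
#' degree-minute positions; longitudes are gazetteer values for the nine
#' towns (the field study printed only latitudes), so downstream geographic
#' distances are approximate.
#'
#' @return A list with components `pop_meta` (population, latitude,
#'   longitude, year), `arrangements` (chromosome, arrangement) and
#'   `locus_map` (locus, chromosome, cyto_order, inside_of, region).
#'   `inside_of` is a comma-separated set of arrangement labels for which the
#'   locus lies inside the inverted segment ("" for outside loci); `region`
#'   partitions the A chromosome into its three comparison regions and is NA
#'   elsewhere.
#' @export
study_design <- function() {
  pop_meta <- data.frame(
    population = c("MAL", "VAL", "RAS", "BCN", "MON", "DIJ", "GRO", "DRO", "SUN"),
    latitude   = c(36.717, 39.533, 40.950, 41.417, 43.583, 47.300, 53.217, 59.567, 60.133),
    longitude  = c(-4.421, -0.375, 0.596, 2.169, 3.877, 5.042, 6.567, 10.630, 13.133),
    year       = c(2008L, 2008L, 2008L, 2007L, 2009L, 2009L, 2009L, 2005L, 2005L),
    stringsAsFactors = FALSE
  )
  arrangements <- data.frame(
    chromosome  = c("A", "A", "A", "J", "J", "U", "U", "U"),
    arrangement = c("A_ST", "A_1", "A_2", "J_ST", "J_1", "U_ST", "U_1+2", "U_1+2+8"),
    stringsAsFactors = FALSE
  )
  locus_map <- data.frame(
    locus = c("dsub11", "dsub37", "dsub76", "dsub05", "dsub21", "dsub39",
              "dsub70", "dsub19",
              "dsub18", "dsub59", "dsub69", "dsub74", "dsub62", "dsub27",
              "dsub10", "dsub03", "dsub42", "dsub64", "dsub15"),
    chromosome = c(rep("A", 8), rep("J", 6), rep("U", 5)),
    cyto_order = c(1:8, 1:6, 1:5),
    inside_of = c("A_1", "A_1", "A_2", "A_2", "A_2", "A_2", "", "",
                  "", "J_1", "J_1", "", "", "",
                  "", "", "U_1+2,U_1+2+8", "U_1+2,U_1+2+8", ""),
    region = c("I", "I", "II", "II", "II", "II", "III", "III",
               rep(NA_character_, 11)),
    stringsAsFactors = FALSE
  )
  list(pop_meta = pop_meta, arrangements = arrangements, locus_map = locus_map)
}

#' @keywords internal
.inside_set <- function(inside_of) {
  if (is.na(inside_of) || !nzchar(inside_of)) character(0)
  else trimws(strsplit(inside_of, ",", fixed = TRUE)[[1]])
}

#' Is a locus inside a given arrangement's inverted segment?
#'
#' @param locus_map locus map data frame (see [study_design()])
#' @param locus locus name
#' @param arrangement arrangement label
#' @return logical
#' @export
locus_inside <- function(locus_map, locus, arrangement) {
  row <- locus_map[locus_map$locus == locus, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown locus: ", locus)
  arrangement %in% .inside_set(row$inside_of)
}
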