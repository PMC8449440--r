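# Arithmetic over a published MITE family census and the derived
# clustering / PAV proportions.  The package ships the pineapple census
# (family element counts, intact counts, total lengths, genome
# percentages) and the companion count table as plain TSV inputs under
# extdata; the functions below recompute the headline proportions from
# those raw counts.

#' Path to a packaged example data file
#'
#' @param name File name under the package's extdata directory; with no
#'   argument, lists the available files.
#' @return Full path (or vector of file names).
#' @export
mitesat_extdata <- function(name = NULL) {
  if (is.null(name)) {
    return(dir(system.file("extdata", package = "mitesat")))
  }
  path <- system.file("extdata", name, package = "mitesat")
  if (path == "") stop("no packaged file called ", name)
  path
}

#' Summary statistics of a MITE family census
#'
#' Recomputes, from raw per-family counts, the quantities usually quoted
#' from such a census: how many elements the focal families contain, the
#' share of total MITE length they account for, the share of the genome,
#' and the intact (full-length) fraction across all families.
#'
#' @param census Data frame with columns family, focal (logical),
#'   n_elements, n_intact, total_length_bp, pct_genome.  Defaults to the
#'   packaged pineapple census.
#' @return List: n_focal_elements, pct_of_mite_length, pct_genome_focal,
#'   pct_intact_all.
#' @export
mite_census_stats <- function(census = read_tsv(mitesat_extdata("pineapple_mite_census.tsv"))) {
  stopifnot(all(c("family", "focal", "n_elements", "n_intact",
                  "total_length_bp", "pct_genome") %in% names(census)))
  focal <- as.logical(census$focal)
  list(
    n_focal_elements = sum(census$n_elements[focal]),
    pct_of_mite_length = 100 * sum(census$total_length_bp[focal]) /
      sum(census$total_length_bp),
    pct_genome_focal = sum(census$pct_genome[focal]),
    pct_intact_all = 100 * sum(census$n_intact) / sum(census$n_elements)
  )
}

#' Clustering and PAV proportions from a census count table
#'
#' Recomputes the clustered fraction of full-length elements, the
#' mt- and ml-conserved fractions between two genomes, and the fraction
#' of clusters present in the second genome, from their raw numerators
#' and denominators.
#'
#' @param counts Data frame with columns quantity, value.  Defaults to
#'   the packaged pineapple count table.
#' @return List: pct_clustered, pct_mt_conserved, pct_ml_conserved,
#'   pct_clusters_present.
#' @export
mite_ratio_stats <- function(counts = read_tsv(mitesat_extdata("pineapple_mite_counts.tsv"))) {
  v <- stats::setNames(counts$value, counts$quantity)
  need <- c("full_length_total", "clustered_elements", "clusters_total",
            "mt_total", "ml_total", "mt_present", "ml_present",
            "clusters_present")
  miss <- setdiff(need, names(v))
  if (length(miss)) stop("count table missing: ", paste(miss, collapse = ", "))
  list(
    pct_clustered = 100 * v[["clustered_elements"]] / v[["full_length_total"]],
    pct_mt_conserved = 100 * v[["mt_present"]] / v[["mt_total"]],
    pct_ml_conserved = 100 * v[["ml_present"]] / v[["ml_total"]],
    pct_clusters_present = 100 * v[["clusters_present"]] / v[["clusters_total"]]
  )
}
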