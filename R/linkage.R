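# Genetic-linkage exclusion: library genes physically near a query locus
# show spurious fitness deficits because the double mutant is rarely
# recovered through meiosis; they are removed rather than scored.

#' Exclude library genes linked to a query locus
#'
#' A gene is excluded iff it lies on the same chromosome as the query
#' locus and the distance between interval midpoints is at most `window`
#' bp (boundary inclusive; at exactly `window` the gene is excluded,
#' at `window` + 1 it is retained). With `window = 0` only genes whose
#' midpoint coincides with the query midpoint are excluded (including the
#' query gene itself).
#'
#' @param genome an `sga_genome` data frame.
#' @param query_locus gene_id of the query mutation.
#' @param window half-width of the exclusion window in bp (default 500 kb).
#' @param query optional strain label to scope the exclusion to one query;
#'   NA (default) excludes the gene for the whole screen.
#' @return exclusion report rows: `gene_id`, `reason` (`"linked"`),
#'   `batch` (NA), `distance_bp`, `query`.
#' @export
apply_linkage_filter <- function(genome, query_locus, window = 500000,
                                 query = NA_character_) {
  if (!is_number(window) || window < 0) {
    stopf("sga_argument_error", "'window' must be a non-negative number of bp")
  }
  hit <- genome$gene_id == query_locus
  if (!any(hit)) {
    stopf("sga_lookup_error", "query locus '%s' not in genome map", query_locus)
  }
  locus <- genome[hit, ][1, ]
  mids <- gene_midpoint(genome)
  qmid <- (locus$start + locus$end) / 2
  d <- abs(mids - qmid)
  excl <- genome$chrom == locus$chrom & d <= window
  res <- data.frame(gene_id = genome$gene_id[excl], reason = "linked",
                    batch = NA_character_, distance_bp = d[excl],
                    query = query, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Linkage diagnostic profile around a query locus
#'
#' Tabulates, for one contrast, each gene's signed genomic distance to the
#' query locus (same chromosome only) against its fitted effect, with the
#' linkage-exclusion flag, for plots of the fitness dip around the locus.
#'
#' @param fits a fit table (one contrast) with `gene_id` and `effect`.
#' @param genome an `sga_genome` covering the fitted genes.
#' @param query_locus gene_id of the query mutation.
#' @param window exclusion window used for the flag (bp).
#' @return data frame `gene_id`, `distance_bp` (signed; NA off-chromosome),
#'   `effect`, `excluded`; attribute `empty_window` is TRUE when no fitted
#'   gene lies on the query chromosome.
#' @export
linkage_profile <- function(fits, genome, query_locus, window = 500000) {
  hit <- genome$gene_id == query_locus
  if (!any(hit)) {
    stopf("sga_lookup_error", "query locus '%s' not in genome map", query_locus)
  }
  locus <- genome[hit, ][1, ]
  qmid <- (locus$start + locus$end) / 2
  m <- match(fits$gene_id, genome$gene_id)
  on_chrom <- !is.na(m) & genome$chrom[m] == locus$chrom
  dist <- ifelse(on_chrom, gene_midpoint(genome)[m] - qmid, NA_real_)
  out <- data.frame(gene_id = fits$gene_id, distance_bp = dist,
                    effect = fits$effect,
                    excluded = !is.na(dist) & abs(dist) <= window,
                    stringsAsFactors = FALSE)
  attr(out, "empty_window") <- !any(on_chrom)
  out
}
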