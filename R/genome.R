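# Gene coordinate maps: construction and BED input/output.
#
# A genome map is a plain data frame (class "sga_genome") with columns
# gene_id, chrom, start, end, strand. Coordinates follow the BED
# convention: 0-based, half-open, so start < end always.

#' Build a regular synthetic genome map
#'
#' Lays `n_genes` genes out on `n_chromosomes` chromosomes in round-robin
#' order, at a fixed spacing between gene starts. Chromosome gene counts
#' therefore differ by at most one. Used by the synthetic screen generator
#' to exercise the linkage filter against known gene positions.
#'
#' @param n_genes number of genes (>= `n_chromosomes`).
#' @param n_chromosomes number of chromosomes.
#' @param spacing distance in bp between consecutive gene starts on one
#'   chromosome.
#' @param seed RNG seed (only strand assignment is random).
#' @param gene_width gene length in bp; truncated below `spacing` so genes
#'   never overlap.
#' @return data frame of class `sga_genome` with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand` (0-based half-open coordinates).
#' @export
#' @examples
#' g <- make_genome(10, 1, spacing = 10000, seed = 1)
#' g$start  # 0, 10000, ..., 90000
make_genome <- function(n_genes, n_chromosomes = 3L, spacing = 25000L, seed = 1L,
                        gene_width = 1000L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes")
  if (!is_number(spacing) || spacing <= 0) {
    stopf("sga_argument_error", "'spacing' must be a positive number of bp")
  }
  if (n_genes < n_chromosomes) {
    stopf("sga_argument_error", "need n_genes >= n_chromosomes")
  }
  width <- max(1, min(gene_width, spacing - 1))
  idx <- seq_len(n_genes) - 1L
  chrom_i <- idx %% n_chromosomes + 1L
  pos_i <- idx %/% n_chromosomes
  start <- pos_i * spacing
  set.seed(seed)
  g <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    chrom = as.character(utils::as.roman(chrom_i)),
    start = start,
    end = start + width,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )
  class(g) <- c("sga_genome", "data.frame")
  g
}

validate_genome <- function(g) {
  if (any(g$start >= g$end)) {
    bad <- which(g$start >= g$end)[1]
    stopf("sga_format_error", "gene '%s' has start >= end (%d >= %d)",
          g$gene_id[bad], g$start[bad], g$end[bad])
  }
  if (anyDuplicated(g$gene_id)) {
    stopf("sga_format_error", "duplicate gene ids in genome map: %s",
          paste(unique(g$gene_id[duplicated(g$gene_id)])[1:3], collapse = ", "))
  }
  invisible(g)
}

#' Read a gene coordinate map from a 6-column BED file
#'
#' @param path path to a BED file (chrom, start, end, name, score, strand).
#' @return an `sga_genome` data frame; coordinates kept 0-based half-open.
#' @export
read_genome_bed <- function(path) {
  if (!file.exists(path)) stopf("sga_format_error", "no such file: %s", path)
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("sga_genome", "data.frame")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stopf("sga_format_error",
                                           "malformed BED file %s: %s", path,
                                           conditionMessage(e)))
  df <- as.data.frame(gr)
  if (nrow(df) == 0L) return(empty)
  if (is.null(df$name) || anyNA(df$name)) {
    stopf("sga_format_error", "BED file %s lacks gene names in column 4", path)
  }
  g <- data.frame(
    gene_id = as.character(df$name),
    chrom = as.character(df$seqnames),
    # rtracklayer converts BED to 1-based closed intervals; undo that
    start = df$start - 1L,
    end = df$end,
    strand = ifelse(as.character(df$strand) %in% c("+", "-"),
                    as.character(df$strand), "+"),
    stringsAsFactors = FALSE
  )
  class(g) <- c("sga_genome", "data.frame")
  validate_genome(g)
  g
}

#' Write a gene coordinate map as BED
#'
#' @param genome an `sga_genome` data frame.
#' @param path output path.
#' @export
write_genome_bed <- function(genome, path) {
  validate_genome(genome)
  if (nrow(genome) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genome$chrom,
    ranges = IRanges::IRanges(start = genome$start + 1L, end = genome$end),
    strand = genome$strand
  )
  gr$name <- genome$gene_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
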