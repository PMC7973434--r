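# Synthetic SGA screen generator.
#
# Emulates a deletion-library screen crossed with several query mutants and
# one neutral control query, pinned in quadruplicate over several
# independent batches. Every nuisance the analysis has to remove is
# generated explicitly: plate/batch offsets, row/column offsets, a smooth
# spatial surface, intra-quadruplicate correlation, a variance trend that
# makes small colonies noisier, colony dropout, and a linkage-induced
# fitness penalty around each query locus. Ground truth (planted
# interaction effects delta on the log2 scale) is returned alongside the
# raw plate tables so downstream stages can be validated end to end.

#' Configuration of a synthetic SGA screen
#'
#' Defaults describe the study design the package targets: a genome-wide
#' deletion library crossed with 3 query mutants plus 1 control query, 3
#' independent batches, quadruplicate pinning on 32 x 48 (1536-format)
#' plates, so each (gene, query) double mutant yields 12 replicate
#' colonies.
#'
#' @param n_genes library size.
#' @param n_chromosomes,spacing genome layout passed to [make_genome()].
#' @param n_batches independent biological repeats of every cross.
#' @param quad technical replicates per plate (2x2 block; must be 4).
#' @param plate_rows,plate_cols colony grid dimensions.
#' @param control_empty_quadrants empty guide blocks per plate.
#' @param base_log2 baseline log2 colony size (arbitrary pixel-area units).
#' @param sigma0 baseline log2 SD of a single colony.
#' @param trend_strength slope of the variance trend: colony SD is
#'   `sigma0 * (1 + trend_strength * max(0, expected_deficit))`, so small
#'   (sick) colonies are noisier.
#' @param rho intra-quadruplicate correlation (shared block effect), in \[0,1).
#' @param batch_sd,rowcol_sd,spatial_amplitude nuisance magnitudes (log2).
#' @param dropout_p probability a colony fails to grow (emitted as size 0).
#' @param linkage_window bp window around each query locus inside which the
#'   linkage artifact acts.
#' @param linkage_penalty maximal log2 fitness penalty at the query locus;
#'   decays linearly to 0 at the window edge.
#' @param queries data frame describing the query strains: columns `name`,
#'   `control` (logical, exactly one TRUE), `locus` (gene_id or NA for
#'   automatic placement; all non-control queries default to one shared
#'   locus, mimicking several alleles of the same gene), `frac_pos`,
#'   `frac_neg` (fractions of the library with planted positive/negative
#'   interactions), `effect_mean`, `effect_sd` (magnitude distribution of
#'   planted effects: |delta| = |N(effect_mean, effect_sd)|).
#' @param seed RNG seed; the whole simulation is deterministic given the
#'   config.
#' @return a validated list of class `sga_sim_config`.
#' @export
sim_config <- function(n_genes = 1000L, n_chromosomes = 3L, spacing = 25000L,
                       n_batches = 3L, quad = 4L,
                       plate_rows = 32L, plate_cols = 48L,
                       control_empty_quadrants = 8L,
                       base_log2 = 10, sigma0 = 0.3, trend_strength = 0.3,
                       rho = 0.4, batch_sd = 0.2, rowcol_sd = 0.1,
                       spatial_amplitude = 0.2, dropout_p = 0.02,
                       linkage_window = 500000, linkage_penalty = 1.5,
                       queries = NULL, seed = 1L) {
  if (is.null(queries)) {
    queries <- data.frame(
      name = c("ctrl", "del", "ptA", "ptB"),
      control = c(TRUE, FALSE, FALSE, FALSE),
      locus = NA_character_,
      frac_pos = c(0, 0.05, 0.05, 0.05),
      frac_neg = c(0, 0.05, 0.05, 0.05),
      effect_mean = 1,
      effect_sd = 0.3,
      stringsAsFactors = FALSE
    )
  }
  need <- c("name", "control", "locus", "frac_pos", "frac_neg",
            "effect_mean", "effect_sd")
  if (!all(need %in% names(queries))) {
    stopf("sga_argument_error", "queries must have columns %s",
          paste(need, collapse = ", "))
  }
  if (sum(queries$control) != 1L) {
    stopf("sga_argument_error", "exactly one query must be the control")
  }
  if (anyDuplicated(queries$name)) {
    stopf("sga_argument_error", "query names must be unique")
  }
  if (any(queries$frac_pos + queries$frac_neg > 1)) {
    stopf("sga_argument_error", "frac_pos + frac_neg must be <= 1 per query")
  }
  for (nm in c("sigma0", "trend_strength", "batch_sd", "rowcol_sd",
               "spatial_amplitude", "linkage_penalty")) {
    v <- get(nm)
    if (!is_number(v) || v < 0) stopf("sga_argument_error", "'%s' must be >= 0", nm)
  }
  rho <- check_prob(rho, "rho", open_upper = TRUE)
  dropout_p <- check_prob(dropout_p, "dropout_p", open_upper = TRUE)
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    n_chromosomes = check_count(n_chromosomes, "n_chromosomes"),
    spacing = spacing, n_batches = check_count(n_batches, "n_batches"),
    quad = check_count(quad, "quad"),
    plate_rows = check_count(plate_rows, "plate_rows"),
    plate_cols = check_count(plate_cols, "plate_cols"),
    control_empty_quadrants = as.integer(control_empty_quadrants),
    base_log2 = base_log2, sigma0 = sigma0, trend_strength = trend_strength,
    rho = rho, batch_sd = batch_sd, rowcol_sd = rowcol_sd,
    spatial_amplitude = spatial_amplitude, dropout_p = dropout_p,
    linkage_window = linkage_window, linkage_penalty = linkage_penalty,
    queries = queries, seed = check_count(seed, "seed")
  )
  class(cfg) <- "sga_sim_config"
  cfg
}

# Fill NA query loci: all mutant alleles share one locus near the middle of
# chromosome 1 (several alleles of the same gene); the control gets a locus
# near the middle of the second chromosome (or the last one available).
resolve_query_loci <- function(config, genome) {
  q <- config$queries
  chroms <- unique(genome$chrom)
  mid_gene <- function(chrom) {
    on_c <- genome[genome$chrom == chrom, ]
    on_c$gene_id[which.min(abs(gene_midpoint(on_c) - stats::median(gene_midpoint(on_c))))]
  }
  if (any(is.na(q$locus) & !q$control)) {
    q$locus[is.na(q$locus) & !q$control] <- mid_gene(chroms[1])
  }
  if (any(is.na(q$locus) & q$control)) {
    q$locus[is.na(q$locus) & q$control] <- mid_gene(chroms[min(2, length(chroms))])
  }
  missing <- setdiff(q$locus, genome$gene_id)
  if (length(missing)) {
    stopf("sga_lookup_error", "query locus not in genome map: %s",
          paste(missing, collapse = ", "))
  }
  config$queries <- q
  config
}

#' Plant ground-truth interaction effects
#'
#' For every non-control query, a configured fraction of library genes is
#' assigned a positive interaction effect and a fraction a negative one
#' (counts rounded to the nearest integer); all other effects, and all
#' effects of the control query, are exactly 0. Genes inside the linkage
#' window of a query locus are flagged and additionally assigned the
#' linkage fitness penalty (`link_pen`, an additive log2 artifact distinct
#' from the interaction effect delta).
#'
#' @param genome an `sga_genome` data frame.
#' @param config an `sga_sim_config`; query loci are resolved against
#'   `genome` if left NA.
#' @return data frame of class `sga_truth`, one row per (gene, query):
#'   `gene_id`, `query`, `delta`, `linked`, `link_pen`, `dist_bp`.
#' @export
plant_truth <- function(genome, config) {
  validate_genome(genome)
  config <- resolve_query_loci(config, genome)
  q <- config$queries
  n <- nrow(genome)
  mids <- gene_midpoint(genome)
  set.seed(config$seed + 101L)
  rows <- vector("list", nrow(q))
  for (i in seq_len(nrow(q))) {
    locus <- genome[genome$gene_id == q$locus[i], ]
    d <- ifelse(genome$chrom == locus$chrom,
                abs(mids - gene_midpoint(locus)), NA_real_)
    linked <- !is.na(d) & d <= config$linkage_window
    pen <- ifelse(!is.na(d) & d < config$linkage_window,
                  -config$linkage_penalty * (1 - d / config$linkage_window), 0)
    delta <- numeric(n)
    if (!q$control[i]) {
      npos <- round(q$frac_pos[i] * n)
      nneg <- round(q$frac_neg[i] * n)
      if (npos + nneg > 0L) {
        hit <- sample.int(n, npos + nneg)
        mag <- abs(stats::rnorm(npos + nneg, q$effect_mean[i], q$effect_sd[i]))
        delta[hit] <- mag * rep(c(1, -1), c(npos, nneg))
      }
    }
    rows[[i]] <- data.frame(
      gene_id = genome$gene_id, query = q$name[i], delta = delta,
      linked = linked, link_pen = pen, dist_bp = d,
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, rows)
  attr(truth, "control") <- q$name[q$control]
  attr(truth, "seed") <- config$seed
  class(truth) <- c("sga_truth", "data.frame")
  truth
}

# smooth random spatial field on an nr x nc grid, scaled to +/- amplitude
random_spatial_field <- function(nr, nc, amplitude) {
  fr <- stats::runif(1, 0.4, 1.2)
  fc <- stats::runif(1, 0.4, 1.2)
  ph <- stats::runif(1, 0, 2 * pi)
  tilt <- stats::runif(2, -0.5, 0.5)
  r <- matrix(seq_len(nr), nr, nc)
  c_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  f <- sin(2 * pi * (fr * r / nr + fc * c_ / nc) + ph) +
    tilt[1] * (r / nr - 0.5) + tilt[2] * (c_ / nc - 0.5)
  if (max(abs(f)) > 0) f <- f / max(abs(f))
  amplitude * f
}

#' Simulate raw colony-size plate tables
#'
#' Raw colony size is `2^(base + delta + link_pen + batch + row + col +
#' spatial + block + eps)`. The block effect is shared by the 4 colonies of
#' one quadruplicate and carries a fraction `rho` of the colony variance;
#' `eps` is colony-level noise whose SD follows the configured decreasing
#' trend in expected colony size. Dropped-out colonies and empty positions
#' are emitted with size 0.
#'
#' @param layout an `sga_layout` (shared by all queries and batches).
#' @param truth an `sga_truth` from [plant_truth()] over the same genome.
#' @param config the `sga_sim_config` used for `truth`.
#' @return data frame of class `sga_plates` (the raw plate table): columns
#'   `batch`, `query`, `plate`, `row`, `col`, `size`, `position_kind`,
#'   `gene_id`. Attribute `nuisance` records the planted batch offsets.
#' @export
simulate_screen <- function(layout, truth, config) {
  missing_genes <- setdiff(stats::na.omit(layout$gene_id), truth$gene_id)
  if (length(missing_genes)) {
    stopf("sga_structural_error", "layout genes absent from truth: %s",
          paste(missing_genes[1:3], collapse = ", "))
  }
  set.seed(config$seed + 202L)
  batch_off <- stats::rnorm(config$n_batches, 0, config$batch_sd)
  queries <- config$queries$name
  plates <- unique(layout$plate)
  nr <- config$plate_rows; nc <- config$plate_cols
  lib <- layout$position_kind == "library"
  out <- vector("list", length(queries) * config$n_batches)
  k <- 0L
  for (q in queries) {
    tq <- truth[truth$query == q, ]
    m_gene <- config$base_log2 + tq$delta + tq$link_pen
    names(m_gene) <- tq$gene_id
    sd_gene <- config$sigma0 *
      (1 + config$trend_strength * pmax(0, config$base_log2 - m_gene))
    names(sd_gene) <- tq$gene_id
    for (b in seq_len(config$n_batches)) {
      lay <- layout
      m <- rep(NA_real_, nrow(lay))
      m[lib] <- m_gene[lay$gene_id[lib]]
      sdc <- rep(NA_real_, nrow(lay))
      sdc[lib] <- sd_gene[lay$gene_id[lib]]
      log2size <- m + batch_off[b]
      for (p in plates) {
        sel <- lay$plate == p
        roff <- stats::rnorm(nr, 0, config$rowcol_sd)
        coff <- stats::rnorm(nc, 0, config$rowcol_sd)
        sp <- random_spatial_field(nr, nc, config$spatial_amplitude)
        log2size[sel] <- log2size[sel] + roff[lay$row[sel]] + coff[lay$col[sel]] +
          sp[cbind(lay$row[sel], lay$col[sel])]
      }
      # block effect shared within each quadruplicate
      blocks <- lay$block[lib]
      ublk <- unique(blocks)
      blk_sd <- sqrt(config$rho) * sdc[lib][match(ublk, blocks)]
      blk_eff <- stats::rnorm(length(ublk), 0, blk_sd)
      eps <- stats::rnorm(sum(lib), 0, sqrt(1 - config$rho) * sdc[lib])
      log2size[lib] <- log2size[lib] + blk_eff[match(blocks, ublk)] + eps
      size <- ifelse(lib, 2^log2size, 0)
      if (config$dropout_p > 0) {
        drop <- lib & stats::runif(nrow(lay)) < config$dropout_p
        size[drop] <- 0
      }
      k <- k + 1L
      out[[k]] <- data.frame(
        batch = sprintf("b%d", b), query = q, plate = lay$plate,
        row = lay$row, col = lay$col, size = size,
        position_kind = lay$position_kind, gene_id = lay$gene_id,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "nuisance") <- list(batch_offsets = batch_off)
  class(res) <- c("sga_plates", "data.frame")
  res
}

#' Generate a complete synthetic screen bundle
#'
#' Convenience wrapper running [make_genome()], [make_layout()],
#' [plant_truth()] and [simulate_screen()] under one seed.
#'
#' @param config an `sga_sim_config`.
#' @return list of class `sga_sim` with elements `genome`, `layout`,
#'   `truth`, `plates`, `config` (loci resolved).
#' @export
simulate_sga <- function(config = sim_config()) {
  genome <- make_genome(config$n_genes, config$n_chromosomes, config$spacing,
                        seed = config$seed)
  config <- resolve_query_loci(config, genome)
  layout <- make_layout(genome, config$plate_rows, config$plate_cols,
                        quad = config$quad,
                        control_empty_quadrants = config$control_empty_quadrants,
                        seed = config$seed)
  truth <- plant_truth(genome, config)
  plates <- simulate_screen(layout, truth, config)
  structure(list(genome = genome, layout = layout, truth = truth,
                 plates = plates, config = config),
            class = "sga_sim")
}

#' @export
print.sga_sim <- function(x, ...) {
  cat(sprintf("Synthetic SGA screen: %d genes, %d queries x %d batches, %d plates/query\n",
              nrow(x$genome), nrow(x$config$queries), x$config$n_batches,
              length(unique(x$layout$plate))))
  cat(sprintf("  planted interactions: %d (of %d gene x mutant pairs)\n",
              sum(x$truth$delta != 0), sum(!x$truth$query %in% attr(x$truth, "control")) ))
  invisible(x)
}

#' Write a simulated screen bundle to disk
#'
#' Writes genome BED, layout TSV, truth TSV and one plate table TSV per
#' (query, batch) under `dir`.
#'
#' @param sim an `sga_sim` bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome_bed(sim$genome, file.path(dir, "genome.bed"))
  write_layout(sim$layout, file.path(dir, "layout.tsv"))
  tr <- sim$truth
  utils::write.table(tr[, c("gene_id", "query", "delta", "linked")],
                     file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pd <- file.path(dir, "plates")
  dir.create(pd, showWarnings = FALSE)
  sp <- split(sim$plates, list(sim$plates$query, sim$plates$batch), drop = TRUE)
  for (nm in names(sp)) {
    write_plate_table(sp[[nm]], file.path(pd, paste0(nm, ".tsv")))
  }
  invisible(dir)
}
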