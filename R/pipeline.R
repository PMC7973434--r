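# End-to-end orchestration: normalize -> fit -> call -> classify ->
# enrich -> report, from simulated or on-disk plate tables, with a
# provenance manifest.

#' Run the full screen-analysis pipeline
#'
#' With `config$simulate = TRUE` (default) a synthetic screen is generated
#' from `config$sim` and analysed; otherwise plate tables, genome and
#' layout are read from `config$inputs`. Stages: failed-mutant flagging on
#' the control plates, plate normalization, linkage exclusion around every
#' query locus, matrix assembly, differential-fitness fitting, interaction
#' calling and overlap accounting, trifecta classification of each allele
#' against the reference (when both are present), PCA and clustering
#' summaries, linkage profiles, and (when annotation inputs are given)
#' enrichment and disease mapping. All stages are deterministic given the
#' config.
#'
#' @param config a resolved `sga_config` ([resolve_config()]/
#'   [load_config()]), or a named list of overrides.
#' @param out_dir optional directory; when given, all result tables plus a
#'   `manifest.json` with provenance (package version, seed, config and
#'   input hashes) are written there.
#' @return list of class `sga_pipeline` with the stage outputs:
#'   `exclusions`, `matrix`, `fit`, `calls`, `overlap`, `trifecta`,
#'   `pca`, `cluster`, `linkage_profiles`, plus `sim` when simulated.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (!inherits(config, "sga_config")) config <- resolve_config(config)
  input_hashes <- list()

  if (isTRUE(config$simulate)) {
    sim_args <- config$sim
    sim_args$seed <- sim_args$seed %||% config$seed
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_sga(scfg)
    genome <- sim$genome; layout <- sim$layout; plates <- sim$plates
    queries <- sim$config$queries
  } else {
    sim <- NULL
    for (key in c("plates", "genome", "layout")) {
      if (is.null(config$inputs[[key]])) {
        stopf("sga_config_error", "inputs.%s is required when simulate is FALSE", key)
      }
      paths <- config$inputs[[key]]
      missing <- paths[!file.exists(paths)]
      if (length(missing)) {
        stopf("sga_config_error", "missing input file: %s", missing[1])
      }
    }
    genome <- read_genome_bed(config$inputs$genome)
    layout <- read_layout(config$inputs$layout)
    plate_files <- config$inputs$plates
    if (length(plate_files) == 1L && dir.exists(plate_files)) {
      plate_files <- list.files(plate_files, pattern = "\\.tsv$", full.names = TRUE)
    }
    plates <- do.call(rbind, lapply(sort(plate_files), read_plate_table))
    input_hashes <- as.list(tools::md5sum(sort(c(config$inputs$genome,
                                                 config$inputs$layout,
                                                 plate_files))))
    queries <- NULL
  }

  control <- if (!is.null(queries)) queries$name[queries$control] else config$control
  reference <- config$reference
  if (!reference %in% unique(plates$query)) reference <- NULL

  # exclusions: failed mutants per batch on control plates, linkage around
  # every query locus (applied screen-wide, since every contrast involves
  # the control)
  failed <- flag_failed_mutants(plates[plates$query == control, ],
                                min_fraction = config$min_fraction)
  linked <- list()
  if (!is.null(queries)) {
    for (i in seq_len(nrow(queries))) {
      linked[[i]] <- apply_linkage_filter(genome, queries$locus[i],
                                          window = config$linkage_window)
    }
  }
  exclusions <- rbind(failed, do.call(rbind, linked))

  normalized <- normalize_screen(plates)
  mat <- assemble_matrix(normalized, layout, exclusions)
  fit <- fit_screen(mat, control = control, reference = reference)
  calls <- call_interactions(fit, alpha = config$alpha)
  overlap <- if (length(unique(calls$strain)) >= 2L) overlap_counts(calls) else NULL

  trifecta <- list()
  mutants <- setdiff(unique(mat$query), control)
  if (!is.null(reference)) {
    for (m in setdiff(mutants, reference)) {
      an <- paste0(m, "_vs_", control)
      bn <- paste0(reference, "_vs_", control)
      dn <- paste0(m, "_vs_", reference)
      fa <- contrast_table(fit, an); fb <- contrast_table(fit, bn)
      fd <- contrast_table(fit, dn)
      common <- Reduce(intersect, list(fa$gene_id, fb$gene_id, fd$gene_id))
      trifecta[[m]] <- classify_trifecta(fa[fa$gene_id %in% common, ],
                                         fb[fb$gene_id %in% common, ],
                                         fd[fd$gene_id %in% common, ],
                                         alpha = config$alpha)
    }
  }

  cm <- condition_means(mat)
  adj <- remove_batch_effect(cm)
  pca <- pca_scores(adj)
  eff <- coef(fit)[, grep(paste0("_vs_", control, "$"), names(fit$contrasts)),
                   drop = FALSE]
  eff_c <- eff[stats::complete.cases(eff), , drop = FALSE]
  cluster <- if (nrow(eff_c) >= 2L) hcluster(eff_c) else NULL

  lp <- list()
  if (!is.null(queries)) {
    for (i in which(!queries$control)) {
      cn <- paste0(queries$name[i], "_vs_", control)
      lp[[queries$name[i]]] <- linkage_profile(contrast_table(fit, cn), genome,
                                               queries$locus[i],
                                               window = config$linkage_window)
    }
  }

  enrichment <- diseases <- NULL
  if (!is.null(config$inputs$gmt)) {
    sets <- read_gmt(config$inputs$gmt)
    background <- sort(unique(mat$gene_id))
    enrichment <- lapply(split(calls$gene_id, calls$strain), function(g) {
      enrich(intersect(g, background), sets, background,
             q_threshold = config$enrichment_fdr)
    })
  }
  if (!is.null(config$inputs$slim)) {
    slim <- read_disease_slim(config$inputs$slim)
    diseases <- lapply(split(calls$gene_id, calls$strain), map_diseases,
                       slim = slim)
  }

  res <- structure(list(config = config, sim = sim, exclusions = exclusions,
                        matrix = mat, fit = fit, calls = calls,
                        overlap = overlap, trifecta = trifecta, pca = pca,
                        cluster = cluster, linkage_profiles = lp,
                        enrichment = enrichment, diseases = diseases),
                   class = "sga_pipeline")
  if (!is.null(out_dir)) write_pipeline_bundle(res, out_dir, input_hashes)
  res
}

write_pipeline_bundle <- function(res, out_dir, input_hashes = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, name) {
    utils::write.table(d, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  if (!is.null(res$sim)) write_sim_bundle(res$sim, file.path(out_dir, "sim"))
  tsv(res$exclusions, "exclusions.tsv")
  tsv(res$matrix, "screen_matrix.tsv")
  tsv(res$fit$table, "fits.tsv")
  tsv(as.data.frame(res$calls), "calls.tsv")
  if (!is.null(res$overlap)) {
    tsv(res$overlap$per_strain, "overlap_per_strain.tsv")
    tsv(res$overlap$shared, "overlap_shared.tsv")
  }
  for (m in names(res$trifecta)) {
    tsv(as.data.frame(res$trifecta[[m]]), sprintf("trifecta_%s.tsv", m))
  }
  tsv(res$pca$scores, "pca_scores.tsv")
  tsv(data.frame(component = seq_along(res$pca$var_explained),
                 var_explained = res$pca$var_explained), "pca_variance.tsv")
  if (!is.null(res$cluster)) {
    tsv(data.frame(gene_id = res$cluster$labels[res$cluster$order]),
        "cluster_order.tsv")
    tsv(data.frame(step = seq_along(res$cluster$height),
                   left = res$cluster$merge[, 1], right = res$cluster$merge[, 2],
                   height = res$cluster$height), "cluster_merges.tsv")
  }
  for (m in names(res$linkage_profiles)) {
    tsv(res$linkage_profiles[[m]], sprintf("linkage_profile_%s.tsv", m))
  }
  cfg_file <- file.path(out_dir, "config.yaml")
  write_config(res$config, cfg_file)
  manifest <- list(
    package = "sgascreen",
    version = as.character(utils::packageVersion("sgascreen")),
    seed = res$config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    input_md5 = input_hashes,
    n_genes = res$fit$n_genes,
    contrasts = names(res$fit$contrasts)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.sga_pipeline <- function(x, ...) {
  cat("SGA pipeline result\n")
  print(x$fit)
  if (nrow(x$calls)) {
    cat("  calls per strain:\n")
    print(table(x$calls$strain, x$calls$sign))
  }
  invisible(x)
}
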