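# Fixture builders shared across test files. Everything is generated in
# code at test time; no stored data.

# Long-format screen matrix with clean compound-symmetric noise: one value
# per (gene, query, batch, colony), block effects carrying a fraction rho
# of the variance. deltas: optional named list query -> per-gene effect
# vector (added to the non-control queries).
make_cs_matrix <- function(n_genes = 50, queries = c("ctrl", "del", "ptA", "ptB"),
                           n_batches = 3, quad = 4, rho = 0.4, sigma = 0.3,
                           deltas = NULL, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  grid <- expand.grid(replicate = seq_len(quad), batch = paste0("b", seq_len(n_batches)),
                      query = queries, gene_id = genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  blk <- paste(grid$gene_id, grid$query, grid$batch, sep = ".")
  ub <- unique(blk)
  be <- stats::rnorm(length(ub), 0, sqrt(rho) * sigma)[match(blk, ub)]
  val <- be + stats::rnorm(nrow(grid), 0, sqrt(1 - rho) * sigma)
  if (!is.null(deltas)) {
    for (q in names(deltas)) {
      hit <- grid$query == q
      val[hit] <- val[hit] + deltas[[q]][match(grid$gene_id[hit], genes)]
    }
  }
  out <- data.frame(gene_id = grid$gene_id, query = grid$query,
                    batch = grid$batch, replicate = grid$replicate,
                    value = val, weight = 1, block_id = blk,
                    stringsAsFactors = FALSE)
  class(out) <- c("sga_matrix", "data.frame")
  out
}

# One normalized + assembled synthetic screen with exclusions applied,
# as run_pipeline would produce it.
make_screen <- function(n_genes = 300, seed = 1, frac_pos = 0.05,
                        frac_neg = 0.05, effect_sd = 0.3, ...) {
  qz <- data.frame(name = c("ctrl", "del", "ptA", "ptB"),
                   control = c(TRUE, FALSE, FALSE, FALSE), locus = NA,
                   frac_pos = frac_pos, frac_neg = frac_neg,
                   effect_mean = 1, effect_sd = effect_sd,
                   stringsAsFactors = FALSE)
  qz$frac_pos[1] <- qz$frac_neg[1] <- 0
  cfg <- sim_config(n_genes = n_genes, queries = qz, seed = seed, ...)
  sim <- simulate_sga(cfg)
  failed <- flag_failed_mutants(sim$plates[sim$plates$query == "ctrl", ])
  linked <- do.call(rbind, lapply(unique(sim$config$queries$locus), function(l) {
    apply_linkage_filter(sim$genome, l)
  }))
  nrm <- normalize_screen(sim$plates)
  mat <- assemble_matrix(nrm, sim$layout, rbind(failed, linked))
  list(sim = sim, matrix = mat)
}

# uniform raw plate on the standard 1536 grid
make_uniform_plate <- function(size = 1024, n_genes = 350, seed = 1) {
  g <- make_genome(n_genes, 1, spacing = 10000, seed = seed)
  lay <- make_layout(g, seed = seed)
  data.frame(batch = "b1", query = "q", plate = "p01", row = lay$row,
             col = lay$col,
             size = ifelse(lay$position_kind == "library", size, 0),
             position_kind = lay$position_kind, gene_id = lay$gene_id,
             stringsAsFactors = FALSE)
}

# brute-force BH step-up (independent oracle for adjust_bh)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# exhaustive hypergeometric upper tail P(X >= k) via binomial coefficients
hyper_tail_oracle <- function(k, K, n, N) {
  j <- k:min(K, n)
  if (!length(j) || k > min(K, n)) return(if (k <= 0) 1 else 0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# brute-force average-linkage agglomeration returning merge heights
average_linkage_oracle <- function(D) {
  n <- nrow(D)
  members <- as.list(seq_len(n))
  active <- seq_len(n)
  heights <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    bd <- Inf; bi <- bj <- NA
    for (ai in seq_along(active)) {
      for (aj in seq_len(ai - 1)) {
        d <- mean(D[members[[active[ai]]], members[[active[aj]]]])
        if (d < bd - 1e-12) { bd <- d; bi <- active[ai]; bj <- active[aj] }
      }
    }
    members[[length(members) + 1]] <- c(members[[bi]], members[[bj]])
    heights[s] <- bd
    active <- c(setdiff(active, c(bi, bj)), length(members))
  }
  list(height = heights, members = members)
}
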