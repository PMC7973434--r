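# Plate normalization, failed-mutant flagging, linkage filter, matrix
# assembly, batch-effect removal.

test_that("a uniform plate normalizes to all zeros", {
  p <- make_uniform_plate(size = 777)
  np <- normalize_plate(p)
  v <- np$value[np$position_kind == "library"]
  expect_equal(max(abs(v)), 0, tolerance = 1e-12)
  expect_true(all(is.na(np$value[np$position_kind == "empty"])))
})

test_that("a pure row effect is absorbed by the polish", {
  p <- make_uniform_plate(size = 1)
  lib <- p$position_kind == "library"
  p$size[lib] <- 2^(p$row[lib] * 0.2)
  np <- normalize_plate(p)
  expect_lt(max(abs(np$value[lib])), 1e-9)
})

test_that("complete plates end with zero plate/row/column medians", {
  set.seed(31)
  g <- make_genome(384, 1, spacing = 10000, seed = 31)
  lay <- make_layout(g)     # completely full plate
  p <- data.frame(batch = "b1", query = "q", plate = "p01", row = lay$row,
                  col = lay$col, size = 2^rnorm(nrow(lay), 10, 0.5),
                  position_kind = lay$position_kind, gene_id = lay$gene_id)
  np <- normalize_plate(p)
  M <- matrix(NA_real_, 32, 48)
  M[cbind(np$row, np$col)] <- np$value
  expect_lt(abs(median(M)), 1e-9)
  expect_lt(max(abs(apply(M, 1, median))), 1e-9)
  expect_lt(max(abs(apply(M, 2, median))), 1e-9)
})

test_that("a planted smooth gradient of amplitude 0.5 is reduced below 0.1", {
  p <- make_uniform_plate(size = 1024)
  lib <- p$position_kind == "library"
  d <- sqrt(((p$row - 16.5) / 16)^2 + ((p$col - 24.5) / 24)^2)
  grad <- 0.5 * (1 - d / max(d))
  p$size[lib] <- p$size[lib] * 2^grad[lib]
  np <- normalize_plate(p)
  expect_lt(diff(range(np$value[lib])), 0.1)
})

test_that("normalization is invariant to a global rescaling of sizes", {
  set.seed(7)
  p <- make_uniform_plate()
  lib <- p$position_kind == "library"
  p$size[lib] <- p$size[lib] * 2^rnorm(sum(lib), 0, 0.3)
  v1 <- normalize_plate(p)$value
  p2 <- p; p2$size <- p2$size * 37.5
  v2 <- normalize_plate(p2)$value
  expect_equal(v1, v2, tolerance = 1e-10)
})

test_that("zero-size colonies become missing; dead plates are rejected", {
  set.seed(8)
  p <- make_uniform_plate()
  lib <- which(p$position_kind == "library")
  p$size[lib[1:4]] <- 0
  np <- normalize_plate(p)
  expect_true(all(is.na(np$value[lib[1:4]])))
  p$size[lib] <- 0
  expect_error(normalize_plate(p), class = "sga_processing_error")
})

test_that("failed mutants are flagged per batch with a strict threshold", {
  p1 <- make_uniform_plate(size = 100)
  p1$batch <- "b1"; p1$query <- "ctrl"
  p2 <- p1; p2$batch <- "b2"
  fail_gene <- p1$gene_id[p1$position_kind == "library"][1]
  p1$size[!is.na(p1$gene_id) & p1$gene_id == fail_gene] <- 0
  # boundary gene sits exactly at min_fraction * plate median in batch 2
  edge_gene <- p2$gene_id[p2$position_kind == "library"][5]
  p2$size[!is.na(p2$gene_id) & p2$gene_id == edge_gene] <- 10
  rep_ <- flag_failed_mutants(rbind(p1, p2), min_fraction = 0.1)
  expect_equal(rep_$gene_id[rep_$batch == "b1"], fail_gene)
  expect_false(edge_gene %in% rep_$gene_id)   # strict <
  # flagged in batch 1 only
  expect_false(fail_gene %in% rep_$gene_id[rep_$batch == "b2"])
  expect_error(flag_failed_mutants(p1[0, ]), class = "sga_processing_error")
})

test_that("linkage filter uses midpoints, same chromosome, inclusive window", {
  g <- data.frame(gene_id = c("q", "near", "edge", "out", "far"),
                  chrom = c("I", "I", "I", "I", "II"),
                  start = c(1000000, 1100000, 1500000, 1500001, 1100000),
                  end = c(1000100, 1100100, 1500100, 1500201, 1100100),
                  strand = "+")
  class(g) <- c("sga_genome", "data.frame")
  rep_ <- apply_linkage_filter(g, "q", window = 500000)
  expect_setequal(rep_$gene_id, c("q", "near", "edge"))  # edge: exactly 500 kb
  expect_equal(rep_$distance_bp[rep_$gene_id == "q"], 0)
  # window 0 excludes only midpoint-identical genes
  rep0 <- apply_linkage_filter(g, "q", window = 0)
  expect_equal(rep0$gene_id, "q")
  expect_error(apply_linkage_filter(g, "ghost"), class = "sga_lookup_error")
})

test_that("assemble_matrix yields 48 observations per clean gene", {
  scr <- make_screen(n_genes = 60, seed = 21, frac_pos = 0, frac_neg = 0,
                     dropout_p = 0, control_empty_quadrants = 0)
  mat <- scr$matrix
  linked <- unique(scr$sim$truth$gene_id[scr$sim$truth$linked])
  clean <- setdiff(unique(mat$gene_id), linked)
  counts <- table(mat$gene_id[mat$gene_id %in% clean])
  expect_true(all(counts == 48L))  # 4 queries x 3 batches x 4 replicates
  expect_true(all(table(mat$block_id) <= 4L))
})

test_that("exclusions remove the right observations", {
  scr <- make_screen(n_genes = 60, seed = 22, frac_pos = 0, frac_neg = 0,
                     dropout_p = 0, control_empty_quadrants = 0,
                     linkage_penalty = 0)
  sim <- scr$sim
  nrm <- normalize_screen(sim$plates)
  gene <- "g0007"
  excl_fail <- data.frame(gene_id = gene, reason = "failed_control",
                          batch = "b2", distance_bp = NA, query = NA)
  m1 <- assemble_matrix(nrm, sim$layout, excl_fail)
  expect_equal(sum(m1$gene_id == gene), 32L)  # 48 - 16
  excl_link <- data.frame(gene_id = gene, reason = "linked", batch = NA,
                          distance_bp = 0, query = "del")
  m2 <- assemble_matrix(nrm, sim$layout, excl_link)
  expect_equal(sum(m2$gene_id == gene & m2$query == "del"), 0L)
  expect_equal(sum(m2$gene_id == gene), 36L)  # other queries untouched
})

test_that("assemble_matrix detects layout mismatches", {
  scr <- make_screen(n_genes = 30, seed = 23)
  nrm <- normalize_screen(scr$sim$plates)
  bad <- scr$sim$layout
  bad <- bad[bad$row != 1, ]
  expect_error(assemble_matrix(nrm, bad), class = "sga_structural_error")
})

test_that("remove_batch_effect recovers an additive decomposition exactly", {
  genes <- 40
  qs <- c("ctrl", "del"); bs <- c("b1", "b2", "b3")
  off <- c(b1 = -1, b2 = 0, b3 = 1)
  qeff <- matrix(rnorm(genes * 2, 0, 1), genes, 2)
  M <- matrix(NA_real_, genes, 6)
  colnames(M) <- paste(rep(qs, each = 3), rep(bs, 2), sep = ".")
  for (qi in 1:2) for (bi in 1:3) M[, (qi - 1) * 3 + bi] <- qeff[, qi] + off[bi]
  attr(M, "query") <- rep(qs, each = 3)
  attr(M, "batch") <- rep(bs, 2)
  adj <- remove_batch_effect(M)
  # per-batch means equalized
  bm <- sapply(bs, function(b) mean(adj[, attr(M, "batch") == b]))
  expect_lt(diff(range(bm)), 1e-10)
  # query effect + grand batch mean recovered exactly
  expect_equal(unname(adj[, 1]), unname(qeff[, 1] + mean(off)), tolerance = 1e-10)
  # zero offsets: identity
  M0 <- M - rep(off, 2)[col(M)]
  expect_equal(unname(remove_batch_effect(M0)), unname(M0), tolerance = 1e-10)
  # single batch: identity with warning
  expect_warning(out <- remove_batch_effect(M[, c(1, 4)],
                                            batch_labels = c("b1", "b1"),
                                            query_labels = qs),
                 "single batch")
  expect_equal(out, M[, c(1, 4)], ignore_attr = TRUE)
})
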