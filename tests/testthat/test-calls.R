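# Interaction calling, overlap accounting, trifecta classification,
# 2D-volcano tables.

fake_fits <- function(genes, effect, padj, contrast = "m_vs_ctrl") {
  data.frame(gene_id = genes, contrast = contrast, effect = effect,
             se = 0.1, t = effect / 0.1, df = 40, p = padj, padj = padj,
             stringsAsFactors = FALSE)
}

test_that("calls follow the padj threshold and effect sign only", {
  tb <- fake_fits(c("a", "b", "c"), c(-0.6, 1.4, 0.2), c(0.04, 0.06, 0.01))
  calls <- call_interactions(tb, alpha = 0.05)
  expect_setequal(calls$gene_id, c("a", "c"))
  expect_equal(calls$sign[calls$gene_id == "a"], "negative")
  expect_equal(calls$sign[calls$gene_id == "c"], "positive")  # no magnitude floor
  expect_error(call_interactions(tb, alpha = 1.5), class = "sga_argument_error")
})

test_that("overlap counts equal brute-force set arithmetic", {
  A <- sprintf("g%02d", 1:5); B <- sprintf("g%02d", 3:6); C <- sprintf("g%02d", c(1, 4, 9))
  calls <- data.frame(
    gene_id = c(A, B, C),
    strain = rep(c("sA", "sB", "sC"), c(5, 4, 3)),
    sign = "negative", effect = -1, padj = 0.01, stringsAsFactors = FALSE)
  ov <- overlap_counts(calls)
  shared <- setNames(ov$shared$n_shared, ov$shared$members)
  expect_equal(unname(shared["sA+sB"]), length(intersect(A, B)))
  expect_equal(unname(shared["sA+sC"]), length(intersect(A, C)))
  expect_equal(unname(shared["sB+sC"]), length(intersect(B, C)))
  expect_equal(unname(shared["sA+sB+sC"]),
               length(Reduce(intersect, list(A, B, C))))
  per <- ov$per_strain
  expect_equal(per$n_total, c(5L, 4L, 3L))
  expect_equal(per$n_unique[per$strain == "sC"], sum(!C %in% c(A, B)))
})

test_that("disjoint and identical call sets give the boundary overlaps", {
  mk <- function(g, s) data.frame(gene_id = g, strain = s, sign = "positive",
                                  effect = 1, padj = 0.01)
  dis <- rbind(mk(c("a", "b"), "s1"), mk(c("c", "d"), "s2"))
  ov <- overlap_counts(dis)
  expect_true(all(ov$shared$n_shared == 0))
  ident <- rbind(mk(c("a", "b"), "s1"), mk(c("a", "b"), "s2"))
  ov2 <- overlap_counts(ident)
  expect_equal(ov2$shared$n_shared, 2L)
  expect_true(all(ov2$per_strain$n_unique == 0))
})

test_that("sign consistency restricts shared counts", {
  calls <- data.frame(gene_id = c("a", "b", "a", "b"),
                      strain = rep(c("s1", "s2"), each = 2),
                      sign = c("positive", "negative", "positive", "positive"),
                      effect = c(1, -1, 1, 1), padj = 0.01)
  expect_equal(overlap_counts(calls)$shared$n_shared, 2L)
  expect_equal(overlap_counts(calls, sign_consistent = TRUE)$shared$n_shared, 1L)
})

test_that("trifecta rules reproduce the quadrant semantics", {
  g <- c("restored", "unique_neg", "shared_neg", "sens", "null")
  A <- fake_fits(g, effect = c(0.1, -1.2, -1.0, -2.0, 0.0),
                 padj = c(0.50, 0.01, 0.01, 0.01, 0.90), contrast = "A")
  B <- fake_fits(g, effect = c(-1.0, 0.1, -1.1, -1.0, 0.0),
                 padj = c(0.01, 0.60, 0.01, 0.01, 0.80), contrast = "B")
  D <- fake_fits(g, effect = c(1.1, -1.3, 0.1, -1.0, 0.0),
                 padj = c(0.01, 0.01, 0.70, 0.01, 0.95), contrast = "D")
  tc <- classify_trifecta(A, B, D)
  got <- setNames(tc$category, tc$gene_id)
  # reference interacts negatively, allele reverts it -> retained function
  expect_equal(unname(got["restored"]), "residual_restored")
  # allele-only interaction with the reference silent -> gained function
  expect_equal(unname(got["unique_neg"]), "unique_gain_negative")
  # both alleles sick, no allele-reference difference -> lost function
  expect_equal(unname(got["shared_neg"]), "shared_negative")
  expect_equal(unname(got["sens"]), "increased_sensitivity")
  expect_equal(unname(got["null"]), "none")
})

test_that("every gene receives exactly one trifecta category", {
  set.seed(30)
  cats <- c("shared_positive", "shared_negative", "residual_restored",
            "increased_sensitivity", "unique_gain_positive",
            "unique_gain_negative", "none")
  for (i in 1:50) {
    n <- 40
    g <- sprintf("g%02d", 1:n)
    mk <- function() fake_fits(g, effect = rnorm(n), padj = runif(n))
    tc <- classify_trifecta(mk(), mk(), mk())
    expect_equal(nrow(tc), n)
    expect_true(all(tc$category %in% cats))
    expect_equal(anyDuplicated(tc$gene_id), 0L)
  }
})

test_that("trifecta refuses mismatched gene universes", {
  A <- fake_fits(c("a", "b"), c(1, 1), c(0.1, 0.1))
  B <- fake_fits(c("a", "c"), c(1, 1), c(0.1, 0.1))
  expect_error(classify_trifecta(A, B, A), class = "sga_structural_error")
})

test_that("2D-volcano tables assign quadrants and scores", {
  X <- fake_fits(c("a", "b", "c"), c(-1, 0, 2), c(0.01, 0.5, 0.2))
  Y <- fake_fits(c("a", "b", "c"), c(-1, 0, -3), c(0.20, 0.9, 0.01))
  v <- volcano2d_table(X, Y)
  expect_equal(v$quadrant, c("lower_left", "none", "lower_right"))
  expect_equal(v$score, -log10(pmin(X$padj, Y$padj)))
  # identical contrasts plot on the diagonal
  v2 <- volcano2d_table(X, X)
  expect_equal(v2$x, v2$y)
})
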