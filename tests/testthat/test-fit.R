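# Differential-fitness machinery: trend, weights, replicate correlation,
# GLS fits, moderation, moderated contrasts, BH adjustment.

test_that("homoscedastic screens give a flat mean-variance trend", {
  mat <- make_cs_matrix(n_genes = 300, rho = 0.3, sigma = 0.3, seed = 5)
  tr <- fit_trend(mat)
  pred <- predict(tr, seq(-0.2, 0.2, length.out = 11))
  expect_true(all(abs(pred - sqrt(0.3)) / sqrt(0.3) < 0.1))
})

test_that("the trend tracks SD doubling at small colony sizes", {
  set.seed(6)
  genes <- sprintf("g%03d", 1:300)
  m_g <- seq(-2, 0, length.out = 300)
  sd_g <- 0.3 * (1 - m_g / 2)           # doubles at the smallest sizes
  rows <- lapply(seq_along(genes), function(i) {
    grid <- expand.grid(replicate = 1:4, batch = paste0("b", 1:3),
                        query = c("ctrl", "del"), stringsAsFactors = FALSE)
    data.frame(gene_id = genes[i], grid,
               value = m_g[i] + rnorm(nrow(grid), 0, sd_g[i]), weight = 1,
               block_id = paste(genes[i], grid$query, grid$batch))
  })
  mat <- do.call(rbind, rows)
  class(mat) <- c("sga_matrix", "data.frame")
  tr <- fit_trend(mat)
  sd_small <- predict(tr, quantile(m_g, 0.05))^2
  sd_large <- predict(tr, quantile(m_g, 0.95))^2
  expect_gte(sd_small / sd_large, 1.5)
})

test_that("a single-knot trend predicts a constant everywhere", {
  tr <- structure(list(knots = data.frame(mean = 0, sqrt_sd = 0.7)),
                  class = "sga_trend")
  expect_equal(predict(tr, c(-5, 0, 5)), rep(0.7, 3))
})

test_that("weights are the inverse predicted variance", {
  tr <- structure(list(knots = data.frame(mean = c(-1, 1),
                                          sqrt_sd = c(sqrt(0.5), sqrt(0.5)))),
                  class = "sga_trend")
  # flat trend at SD 0.5 -> weights 1/0.5^2
  expect_equal(compute_weights(tr, c(-2, 0, 3)), rep(0.5^-2, 3))
  tr2 <- structure(list(knots = data.frame(mean = c(0, 1), sqrt_sd = c(0.8, 0.4))),
                   class = "sga_trend")
  # knot value used exactly; halving predicted sqrt-SD multiplies weight by 16
  expect_equal(compute_weights(tr2, 0), 0.8^-4)
  expect_equal(compute_weights(tr2, 1), 0.4^-4)
  expect_equal(compute_weights(tr2, 1) / compute_weights(tr2, 0), 16)
})

test_that("perfect within-block agreement drives the consensus toward 1", {
  set.seed(9)
  genes <- sprintf("g%03d", 1:60)
  grid <- expand.grid(replicate = 1:4, batch = paste0("b", 1:3),
                      query = c("ctrl", "del"), gene_id = genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  blk <- paste(grid$gene_id, grid$query, grid$batch)
  bv <- rnorm(length(unique(blk)))
  mat <- data.frame(grid, value = bv[match(blk, unique(blk))], weight = 1,
                    block_id = blk)
  class(mat) <- c("sga_matrix", "data.frame")
  expect_gte(estimate_block_correlation(mat)$consensus, 0.95)
})

test_that("independent observations give a consensus near zero", {
  mat <- make_cs_matrix(n_genes = 500, rho = 0, seed = 13)
  expect_lt(abs(estimate_block_correlation(mat)$consensus), 0.05)
})

test_that("singleton blocks make the correlation unidentifiable", {
  mat <- make_cs_matrix(n_genes = 5, seed = 1)
  mat <- mat[mat$replicate == 1, ]
  expect_error(estimate_block_correlation(mat), class = "sga_processing_error")
})

test_that("GLS reduces to OLS at rho 0 with equal weights", {
  set.seed(14)
  for (i in 1:100) {
    n <- sample(8:16, 1)
    X <- cbind(1, matrix(rnorm(n * 2), n, 2))
    colnames(X) <- c("a", "b", "c")
    y <- rnorm(n)
    f <- fit_gene_model(y, X, rho = 0)
    ref <- lm.fit(X, y)
    expect_equal(unname(f$coefficients), unname(ref$coefficients),
                 tolerance = 1e-8)
    expect_equal(f$s2, sum(ref$residuals^2) / (n - 3), tolerance = 1e-8)
    expect_equal(unname(f$cov_unscaled), unname(solve(crossprod(X))),
                 tolerance = 1e-8)
  }
})

test_that("noiseless data is interpolated exactly", {
  X <- cbind(q1 = rep(c(1, 0), each = 6), q2 = rep(c(0, 1), each = 6))
  y <- drop(X %*% c(2.5, -1.25))
  f <- fit_gene_model(y, X, rho = 0.3,
                      blocks = rep(1:4, each = 3))
  expect_equal(unname(f$coefficients), c(2.5, -1.25))
  expect_equal(f$s2, 0)
})

test_that("higher replicate correlation inflates contrast SEs", {
  set.seed(15)
  blocks <- rep(1:6, each = 4)
  X <- cbind(q1 = rep(c(1, 0), each = 12), q2 = rep(c(0, 1), each = 12))
  y <- rnorm(24)
  se_of <- function(rho) {
    f <- fit_gene_model(y, X, rho = rho, blocks = blocks)
    cvec <- c(1, -1)
    sqrt(f$s2 * drop(t(cvec) %*% f$cov_unscaled %*% cvec))
  }
  expect_gt(se_of(0.9), se_of(0))
})

test_that("rank-deficient designs are refused", {
  X <- cbind(a = rep(1, 8), b = rep(1, 8))
  expect_error(fit_gene_model(rnorm(8), X), class = "sga_rank_error")
})

test_that("moderation pools variances by the prior-weighted formula", {
  set.seed(16)
  d0 <- 10; s0 <- 0.5; d <- 12
  s2 <- s0 * d0 / rchisq(2000, d0) * rchisq(2000, d) / d
  mod <- moderate_variances(s2, rep(d, 2000))
  expect_lt(abs(mod$df_prior - d0) / d0, 0.30)
  expect_lt(abs(mod$var_prior - s0) / s0, 0.15)
  # posterior is the pooling formula and lies between s2 and the prior
  expect_equal(mod$var_post,
               (mod$df_prior * mod$var_prior + d * s2) / (mod$df_prior + d))
  expect_true(all(mod$var_post >= pmin(s2, mod$var_prior) - 1e-12))
  expect_true(all(mod$var_post <= pmax(s2, mod$var_prior) + 1e-12))
  # strictly monotone in s2 for finite d0
  o <- order(s2)
  expect_true(all(diff(mod$var_post[o]) > 0))
})

test_that("equal variances give an infinite prior df and no shrinkage", {
  mod <- moderate_variances(rep(3.7, 50), rep(8, 50))
  expect_identical(mod$df_prior, Inf)
  expect_equal(mod$var_post, rep(3.7, 50))
  expect_error(moderate_variances(rep(0, 20), rep(5, 20)),
               class = "sga_processing_error")
})

test_that("moderation agrees with the limma empirical-Bayes estimator", {
  set.seed(17)
  s2 <- 0.8 * 6 / rchisq(500, 6) * rchisq(500, 10) / 10
  mod <- moderate_variances(s2, rep(10, 500))
  sq <- limma::squeezeVar(s2, df = 10)
  expect_equal(mod$df_prior, sq$df.prior, tolerance = 1e-6)
  expect_equal(mod$var_prior, sq$var.prior, tolerance = 1e-6)
  expect_equal(mod$var_post, sq$var.post, tolerance = 1e-6)
})

test_that("moderated tests behave at the degenerate corners", {
  fits <- list(
    g1 = list(coefficients = c(q1 = 1, q2 = 1), s2 = 1, df = 5,
              cov_unscaled = diag(2, 2, 2) |>
                `dimnames<-`(list(c("q1", "q2"), c("q1", "q2"))), n = 7, rank = 2),
    g2 = list(coefficients = c(q1 = 2, q2 = 0.5), s2 = 1, df = 5,
              cov_unscaled = diag(2, 2, 2) |>
                `dimnames<-`(list(c("q1", "q2"), c("q1", "q2"))), n = 7, rank = 2)
  )
  mod <- structure(list(df_prior = Inf, var_prior = 1, var_post = c(1, 1)),
                   class = "sga_moderation")
  tb <- test_contrasts(fits, mod, list(d = c(q1 = 1, q2 = -1)))
  # zero effect -> t = 0, p = 1
  expect_equal(tb$t[tb$gene_id == "g1"], 0)
  expect_equal(tb$p[tb$gene_id == "g1"], 1)
  # infinite prior df -> z-like statistic with the pooled SD
  z <- 1.5 / sqrt(1 * 4)
  expect_equal(tb$p[tb$gene_id == "g2"], 2 * pnorm(-abs(z)))
  expect_error(test_contrasts(fits, mod, list(bad = c(q9 = 1))),
               class = "sga_argument_error")
})

test_that("null screens give uniform moderated p-values", {
  # correlation matched to the generator: moderated p-values are uniform
  mat <- make_cs_matrix(n_genes = 2000, rho = 0.4, sigma = 0.3, seed = 19)
  fit <- fit_screen(mat, control = "ctrl", rho = 0.4)
  p <- fit$table$p[fit$table$contrast == "del_vs_ctrl"]
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  # rejection rate at alpha=0.05 over independent screens sits at alpha
  fracs <- vapply(c(18, 19, 20), function(s) {
    m <- make_cs_matrix(n_genes = 1000, rho = 0.4, sigma = 0.3, seed = s)
    f <- fit_screen(m, control = "ctrl", rho = 0.4)
    mean(f$table$p[f$table$contrast == "del_vs_ctrl"] < 0.05)
  }, 0)
  expect_lt(abs(mean(fracs) - 0.05), 0.015)
  # with the consensus estimated from the data (slightly conservative-biased
  # downward by construction) BH still keeps the null screen clean
  fit2 <- fit_screen(mat, control = "ctrl")
  expect_lt(mean(fit2$table$padj < 0.05), 0.001)
  expect_lt(abs(fit2$correlation$consensus - 0.4), 0.1)
})

test_that("fit_screen is deterministic and exposes its S3 surface", {
  mat <- make_cs_matrix(n_genes = 60, seed = 19,
                        deltas = list(del = c(rep(-1, 5), rep(0, 55))))
  f1 <- suppressWarnings(fit_screen(mat, control = "ctrl", reference = "del"))
  f2 <- suppressWarnings(fit_screen(mat, control = "ctrl", reference = "del"))
  expect_identical(f1$table, f2$table)
  expect_setequal(names(f1$contrasts),
                  c("del_vs_ctrl", "ptA_vs_ctrl", "ptB_vs_ctrl",
                    "ptA_vs_del", "ptB_vs_del"))
  sm <- summary(f1)
  expect_true(all(c("contrast", "n_significant") %in% names(sm)))
  cf <- coef(f1)
  expect_equal(dim(cf), c(60L, 5L))
  # planted strong negatives dominate the del contrast
  expect_lt(mean(cf[1:5, "del_vs_ctrl"]), -0.5)
  expect_output(print(f1), "consensus replicate correlation")
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.03), 0.03)
  set.seed(20)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    adj <- adjust_bh(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p))
  }
  expect_error(adjust_bh(c(0.5, 1.2)), class = "sga_argument_error")
  expect_error(adjust_bh(c(-0.1)), class = "sga_argument_error")
})
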