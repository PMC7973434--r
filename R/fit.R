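# Differential colony fitness: per-gene weighted mixed linear models with
# empirical-Bayes variance moderation.
#
# Model per gene: value ~ query + batch, fitted by generalized least
# squares with (i) observation weights from a mean-variance trend (small
# colonies are noisier) and (ii) a compound-symmetric correlation rho
# shared by the 4 technical replicates of one quadruplicate block. Per-gene
# residual variances are shrunk toward a common prior before moderated
# t-tests of the contrasts of interest (each mutant vs control, each
# mutant vs the reference deletion), with Benjamini-Hochberg adjustment
# within each contrast.

# ---- design helpers ---------------------------------------------------

build_design <- function(query, batch, query_levels, batch_levels) {
  qf <- factor(query, levels = query_levels)
  X <- stats::model.matrix(~ 0 + qf)
  colnames(X) <- paste0("query_", query_levels)
  if (length(batch_levels) > 1L) {
    bf <- factor(batch, levels = batch_levels)
    B <- stats::model.matrix(~ bf)[, -1, drop = FALSE]
    colnames(B) <- paste0("batch_", batch_levels[-1])
    X <- cbind(X, B)
  }
  X
}

# ---- mean-variance trend ----------------------------------------------

#' Fit the mean-variance trend of a screen
#'
#' Per-gene unweighted model fits give a residual SD and a mean fitted
#' log2 size; the trend is a robust local regression (lowess) of
#' sqrt(residual SD) on the mean fitted value, discretized to a grid of
#' knots and interpolated piecewise-linearly with flat extrapolation
#' beyond the outermost knots.
#'
#' @param matrix an `sga_matrix`.
#' @param n_knots number of knots the smooth is discretized to (>= 20 for
#'   a non-degenerate trend).
#' @param span lowess span.
#' @param min_genes below this many genes the trend degenerates to a
#'   constant, with a warning.
#' @return object of class `sga_trend` with a `knots` data frame
#'   (`mean`, `sqrt_sd`); use `predict()` to evaluate it.
#' @export
fit_trend <- function(matrix, n_knots = 30L, span = 0.3, min_genes = 50L) {
  pf <- gene_prelim_fits(matrix)
  ok <- is.finite(pf$sigma) & pf$sigma > 0 & is.finite(pf$mean_fitted)
  x <- pf$mean_fitted[ok]
  y <- sqrt(pf$sigma[ok])
  new_trend <- function(knots) {
    structure(list(knots = knots), class = "sga_trend")
  }
  if (length(x) < min_genes || length(unique(x)) < 2L) {
    warnf("only %d usable genes: mean-variance trend degenerates to a constant",
          length(x))
    v <- if (length(y)) stats::median(y) else 1
    return(new_trend(data.frame(mean = 0, sqrt_sd = max(v, 1e-8))))
  }
  lo <- stats::lowess(x, y, f = span, iter = 3L)
  grid <- seq(min(x), max(x), length.out = n_knots)
  v <- stats::approx(lo$x, lo$y, xout = grid, rule = 2, ties = mean)$y
  new_trend(data.frame(mean = grid, sqrt_sd = pmax(v, 1e-8)))
}

#' @param object an `sga_trend`.
#' @param newdata numeric vector of mean fitted log2 sizes.
#' @param ... unused.
#' @rdname fit_trend
#' @export
predict.sga_trend <- function(object, newdata, ...) {
  k <- object$knots
  if (nrow(k) == 1L) return(rep(k$sqrt_sd, length(newdata)))
  stats::approx(k$mean, k$sqrt_sd, xout = newdata, rule = 2, ties = mean)$y
}

#' Precision weights from a mean-variance trend
#'
#' The trend predicts sqrt(SD); the weight is its fourth inverse power,
#' i.e. the inverse predicted variance.
#'
#' @param trend an `sga_trend`.
#' @param fitted per-observation mean fitted log2 sizes.
#' @return strictly positive weight vector.
#' @export
compute_weights <- function(trend, fitted) {
  predict(trend, fitted)^(-4)
}

# ---- technical-replicate correlation ----------------------------------

# one-way ANOVA moment estimator of the intra-block correlation from the
# residuals of one gene; p = rank of the (block-constant) design
block_icc <- function(r, blocks, p) {
  kb <- as.vector(table(blocks))
  B <- length(kb)
  n <- length(r)
  if (n - B < 1L || B - p < 1L) return(NA_real_)
  bm <- as.vector(rowsum(r, blocks)) / kb
  ssw <- sum(r^2) - sum(kb * bm^2)
  msw <- ssw / (n - B)
  ssb <- sum(kb * (bm - mean(r))^2)
  msb <- ssb / (B - p)
  k0 <- (n - sum(kb^2) / n) / (B - 1)
  denom <- msb + (k0 - 1) * msw
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  (msb - msw) / denom
}

#' Consensus correlation of technical replicates
#'
#' Each quadruplicate is a block of technical replicates; per gene, the
#' within-block correlation of the (unweighted) model residuals is
#' estimated by a one-way ANOVA moment estimator, clamped to
#' (-1/(k-1)+0.01, 0.99), and a single consensus value is formed as the
#' 15%-trimmed mean on the atanh scale, back-transformed. One shared value
#' is used for all genes because the per-gene estimates are individually
#' noisy.
#'
#' @param matrix an `sga_matrix` with `block_id` labels.
#' @param trim trim fraction of the consensus mean.
#' @return object of class `sga_correlation`: `consensus`, per-gene
#'   estimates `rho_gene`, block size `k`.
#' @export
estimate_block_correlation <- function(matrix, trim = 0.15) {
  pf <- gene_prelim_fits(matrix)
  k <- max(table(matrix$block_id))
  if (k < 2L) {
    stopf("sga_processing_error",
          "all quadruplicate blocks are singletons: correlation unidentifiable")
  }
  rho <- pf$rho_gene
  rho <- rho[!is.na(rho)]
  if (!length(rho)) {
    stopf("sga_processing_error", "no gene yields a block-correlation estimate")
  }
  lower <- -1 / (k - 1) + 0.01
  z <- atanh(pmin(pmax(rho, lower), 0.99))
  structure(list(consensus = tanh(mean(z, trim = trim)),
                 rho_gene = pf$rho_gene, k = k),
            class = "sga_correlation")
}

#' @export
print.sga_correlation <- function(x, ...) {
  cat(sprintf("Consensus technical-replicate correlation: %.3f (%d genes, blocks of %d)\n",
              x$consensus, sum(!is.na(x$rho_gene)), x$k))
  invisible(x)
}

# ---- per-gene generalized least squares -------------------------------

#' Fit one gene's weighted mixed linear model
#'
#' Generalized least squares under Cov = D^-1/2 R D^-1/2 with D the
#' diagonal of `weights` and R block-compound-symmetric with correlation
#' `rho` inside each quadruplicate block. The whitening uses the analytic
#' inverse square root of an exchangeable correlation matrix, so no
#' per-gene matrix factorization is needed.
#'
#' @param y numeric observations for one gene.
#' @param design design matrix (rows = observations); must be full rank.
#' @param weights positive observation weights (inverse variances).
#' @param rho intra-block correlation in \[0, 1).
#' @param blocks block labels (quadruplicates); NULL = all independent.
#' @return list with `coefficients`, residual variance `s2`, residual df
#'   `df`, `cov_unscaled` (contrast variance factors), `n`, `rank`.
#' @export
fit_gene_model <- function(y, design, weights = NULL, rho = 0, blocks = NULL) {
  n <- length(y)
  design <- as.matrix(design)
  if (nrow(design) != n) stopf("sga_argument_error", "design/observation length mismatch")
  if (!is_number(rho) || rho < 0 || rho >= 1) {
    stopf("sga_argument_error", "'rho' must be in [0, 1)")
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stopf("sga_argument_error", "weights must be positive")
  if (is.null(blocks)) blocks <- seq_len(n)
  blocks <- factor(blocks)
  sw <- sqrt(weights)
  u <- sw * y
  U <- design * sw
  if (rho > 0) {
    kb <- as.vector(table(blocks))[as.integer(blocks)]
    a <- 1 / sqrt(1 - rho)
    bcoef <- (1 / sqrt(1 + (kb - 1) * rho) - a) / kb
    su <- rowsum(u, blocks)[as.integer(blocks), , drop = TRUE]
    SU <- rowsum(U, blocks)[as.integer(blocks), , drop = FALSE]
    u <- a * u + bcoef * su
    U <- a * U + bcoef * SU
  }
  fit <- stats::lm.fit(U, u)
  p <- ncol(design)
  if (fit$rank < p) {
    stopf("sga_rank_error", "design is rank deficient (%d < %d)", fit$rank, p)
  }
  res <- fit$residuals
  df <- n - p
  s2 <- if (df >= 1L) sum(res^2) / df else NA_real_
  R <- qr.R(fit$qr)
  piv <- fit$qr$pivot
  A <- matrix(NA_real_, p, p, dimnames = list(colnames(design), colnames(design)))
  A[piv, piv] <- chol2inv(R)
  list(coefficients = fit$coefficients, s2 = s2, df = df, cov_unscaled = A,
       n = n, rank = fit$rank)
}

# ---- empirical-Bayes moderation ---------------------------------------

# Newton inversion of the trigamma function (for the prior df estimate)
trigamma_inverse <- function(y) {
  if (y <= 0) stopf("sga_argument_error", "trigamma_inverse needs y > 0")
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Shrink per-gene residual variances toward a common prior
#'
#' The prior df `d0` and prior variance `s0^2` are estimated by moment
#' matching on log s2: with s2_g ~ s0^2 * F(d_g, d0), the corrected log
#' values e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2) have variance
#' trigamma(d_g/2) + trigamma(d0/2); the excess of their empirical
#' variance over the first term is inverted through the trigamma function.
#' A non-positive excess means no detectable between-gene variance
#' heterogeneity: d0 = Inf and every posterior variance equals the
#' df-weighted pooled variance (unbiased under the sampling model, and
#' equal to the common value when all s2 coincide). Otherwise the
#' posterior is the pooled `(d0*s0^2 + d_g*s2_g) / (d0 + d_g)`.
#'
#' @param s2 per-gene residual variances.
#' @param d per-gene residual degrees of freedom.
#' @return list of class `sga_moderation`: `df_prior`, `var_prior`,
#'   `var_post`.
#' @export
moderate_variances <- function(s2, d) {
  if (length(s2) != length(d)) stopf("sga_argument_error", "s2 and d lengths differ")
  if (all(!is.finite(s2) | s2 == 0)) {
    stopf("sga_processing_error", "all residual variances are zero: degenerate data")
  }
  use <- is.finite(s2) & s2 > 0 & d >= 1
  pooled <- sum(d[use] * s2[use]) / sum(d[use])
  if (sum(use) < 10L) {
    warnf("only %d genes usable for moderation; using an infinite prior df",
          sum(use))
    return(structure(list(df_prior = Inf, var_prior = pooled,
                          var_post = rep(pooled, length(s2))),
                     class = "sga_moderation"))
  }
  e <- log(s2[use]) - digamma(d[use] / 2) + log(d[use] / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(d[use] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s2_ <- ifelse(is.finite(s2), s2, 0)
    d_ <- ifelse(is.finite(s2), d, 0)
    post <- (d0 * s0 + d_ * s2_) / (d0 + d_)
  } else {
    d0 <- Inf
    s0 <- pooled
    post <- rep(s0, length(s2))
  }
  structure(list(df_prior = d0, var_prior = s0, var_post = post),
            class = "sga_moderation")
}

# ---- moderated contrast tests -----------------------------------------

#' Moderated t-tests of design contrasts
#'
#' For each gene and contrast c: effect = c'beta, SE = s_tilde *
#' sqrt(c'Ac) with A the unscaled covariance of the gene's GLS fit and
#' s_tilde^2 the moderated variance; t = effect/SE on d0 + d_g degrees of
#' freedom (a z-like statistic when d0 is infinite), two-sided p, and
#' Benjamini-Hochberg adjustment within each contrast.
#'
#' @param fits named list (by gene) of [fit_gene_model()] results.
#' @param moderation an `sga_moderation` aligned with `fits`.
#' @param contrasts named list of named numeric contrast vectors over the
#'   design columns.
#' @return fit table: `gene_id`, `contrast`, `effect`, `se`, `t`, `df`,
#'   `p`, `padj`. Genes not estimable for a contrast are omitted and
#'   listed in the `skipped` attribute.
#' @export
test_contrasts <- function(fits, moderation, contrasts) {
  all_cols <- unique(unlist(lapply(fits, function(f) names(f$coefficients))))
  skipped <- character()
  rows <- vector("list", length(contrasts))
  genes <- names(fits)
  d0 <- moderation$df_prior
  for (ci in seq_along(contrasts)) {
    cvec <- contrasts[[ci]]
    cname <- names(contrasts)[ci]
    used <- names(cvec)[cvec != 0]
    if (!all(used %in% all_cols)) {
      stopf("sga_argument_error", "contrast '%s' references absent column(s): %s",
            cname, paste(setdiff(used, all_cols), collapse = ", "))
    }
    eff <- se <- rep(NA_real_, length(fits))
    dfv <- rep(NA_real_, length(fits))
    for (gi in seq_along(fits)) {
      f <- fits[[gi]]
      b <- f$coefficients[used]
      if (anyNA(b)) next
      A <- f$cov_unscaled[used, used, drop = FALSE]
      v <- drop(t(cvec[used]) %*% A %*% cvec[used])
      st2 <- moderation$var_post[gi]
      eff[gi] <- sum(cvec[used] * b)
      se[gi] <- sqrt(st2 * v)
      dfv[gi] <- d0 + f$df
    }
    ok <- !is.na(eff) & is.finite(se) & se > 0
    skipped <- union(skipped, genes[!ok])
    tstat <- eff[ok] / se[ok]
    p <- 2 * stats::pt(-abs(tstat), df = dfv[ok])
    rows[[ci]] <- data.frame(gene_id = genes[ok], contrast = cname,
                             effect = eff[ok], se = se[ok], t = tstat,
                             df = dfv[ok], p = p, padj = adjust_bh(p),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

# ---- orchestration ----------------------------------------------------

# per-gene unweighted OLS pass: residual SDs, fitted means, block ICCs
gene_prelim_fits <- function(matrix) {
  query_levels <- unique(matrix$query)
  batch_levels <- sort(unique(matrix$batch))
  X <- build_design(matrix$query, matrix$batch, query_levels, batch_levels)
  sp <- split(seq_len(nrow(matrix)), matrix$gene_id)
  genes <- names(sp)
  ng <- length(genes)
  sigma <- mean_fitted <- rho_gene <- rep(NA_real_, ng)
  fitted_obs <- rep(NA_real_, nrow(matrix))
  dropped <- character()
  for (i in seq_len(ng)) {
    idx <- sp[[i]]
    Xi <- X[idx, , drop = FALSE]
    keep <- colSums(abs(Xi)) > 0
    Xi <- Xi[, keep, drop = FALSE]
    fit <- stats::lm.fit(Xi, matrix$value[idx])
    if (fit$rank < ncol(Xi)) {
      dropped <- c(dropped, genes[i])
      next
    }
    fitted_obs[idx] <- fit$fitted.values
    mean_fitted[i] <- mean(fit$fitted.values)
    df <- length(idx) - fit$rank
    if (df >= 1L) sigma[i] <- sqrt(sum(fit$residuals^2) / df)
    rho_gene[i] <- block_icc(fit$residuals, matrix$block_id[idx], fit$rank)
  }
  list(genes = genes, sigma = sigma, mean_fitted = mean_fitted,
       rho_gene = rho_gene, fitted_obs = fitted_obs, split = sp,
       design = X, query_levels = query_levels, batch_levels = batch_levels,
       dropped = dropped)
}

#' Fit the differential-fitness model of a whole screen
#'
#' Runs the full inference sequence on a normalized screen matrix:
#' mean-variance trend, precision weights, consensus technical-replicate
#' correlation, per-gene weighted GLS fits with batch as a model term,
#' empirical-Bayes variance moderation, moderated t-tests of every mutant
#' vs control contrast (and mutant vs reference contrasts when a reference
#' strain is given), each BH-adjusted across genes.
#'
#' @param matrix an `sga_matrix` from [assemble_matrix()].
#' @param control name of the control query strain.
#' @param reference optional reference mutant (typically the full deletion)
#'   for allele-vs-reference contrasts.
#' @param rho fixed technical-replicate correlation; NULL (default)
#'   estimates the consensus from the data.
#' @param use_weights set FALSE to skip trend-based precision weighting.
#' @return object of class `sga_fit`: `table` (the fit table), `trend`,
#'   `correlation`, `moderation`, `contrasts`, `control`, `reference`,
#'   `genes_dropped`.
#' @export
fit_screen <- function(matrix, control, reference = NULL, rho = NULL,
                       use_weights = TRUE) {
  queries <- unique(matrix$query)
  if (!control %in% queries) {
    stopf("sga_lookup_error", "control query '%s' not present in matrix", control)
  }
  if (!is.null(reference) && !reference %in% queries) {
    stopf("sga_lookup_error", "reference query '%s' not present in matrix", reference)
  }
  query_levels <- c(control, setdiff(queries, control))
  matrix <- matrix[order(match(matrix$query, query_levels), matrix$batch,
                         matrix$gene_id), ]
  pf <- gene_prelim_fits(matrix)

  trend <- fit_trend(matrix)
  w <- if (use_weights) {
    fv <- pf$fitted_obs
    fv[is.na(fv)] <- mean(fv, na.rm = TRUE)
    compute_weights(trend, fv)
  } else rep(1, nrow(matrix))

  correlation <- if (is.null(rho)) estimate_block_correlation(matrix) else
    structure(list(consensus = rho, rho_gene = NULL, k = max(table(matrix$block_id))),
              class = "sga_correlation")
  rho_use <- max(0, correlation$consensus)

  fits <- vector("list", length(pf$split))
  names(fits) <- pf$genes
  dropped <- pf$dropped
  for (i in seq_along(pf$split)) {
    g <- pf$genes[i]
    if (g %in% dropped) next
    idx <- pf$split[[i]]
    Xi <- pf$design[idx, , drop = FALSE]
    keep <- colSums(abs(Xi)) > 0
    fits[[i]] <- tryCatch(
      fit_gene_model(matrix$value[idx], Xi[, keep, drop = FALSE],
                     weights = w[idx], rho = rho_use,
                     blocks = matrix$block_id[idx]),
      error = function(e) NULL
    )
    if (is.null(fits[[i]])) dropped <- c(dropped, g)
  }
  ok <- !vapply(fits, is.null, TRUE)
  fits <- fits[ok]

  moderation <- moderate_variances(vapply(fits, `[[`, 0, "s2"),
                                   vapply(fits, `[[`, 0, "df"))

  mutants <- setdiff(query_levels, control)
  contrasts <- list()
  for (m in mutants) {
    cv <- stats::setNames(c(1, -1), paste0("query_", c(m, control)))
    contrasts[[paste0(m, "_vs_", control)]] <- cv
  }
  if (!is.null(reference)) {
    for (m in setdiff(mutants, reference)) {
      cv <- stats::setNames(c(1, -1), paste0("query_", c(m, reference)))
      contrasts[[paste0(m, "_vs_", reference)]] <- cv
    }
  }
  table <- test_contrasts(fits, moderation, contrasts)

  structure(list(table = table, trend = trend, correlation = correlation,
                 moderation = moderation, contrasts = contrasts,
                 control = control, reference = reference,
                 genes_dropped = unique(dropped),
                 n_genes = length(fits), n_obs = nrow(matrix)),
            class = "sga_fit")
}

#' @export
print.sga_fit <- function(x, ...) {
  cat(sprintf("SGA differential-fitness fit: %d genes, %d observations\n",
              x$n_genes, x$n_obs))
  cat(sprintf("  consensus replicate correlation: %.3f\n", x$correlation$consensus))
  cat(sprintf("  prior df: %s, prior variance: %.4g\n",
              format(x$moderation$df_prior, digits = 3), x$moderation$var_prior))
  cat(sprintf("  contrasts: %s\n", paste(names(x$contrasts), collapse = ", ")))
  if (length(x$genes_dropped)) {
    cat(sprintf("  dropped (rank deficient): %d gene(s)\n", length(x$genes_dropped)))
  }
  invisible(x)
}

#' @param object an `sga_fit`.
#' @param alpha significance threshold on the adjusted p-values.
#' @param ... unused.
#' @rdname fit_screen
#' @export
summary.sga_fit <- function(object, alpha = 0.05, ...) {
  tb <- object$table
  out <- do.call(rbind, lapply(split(tb, tb$contrast), function(d) {
    data.frame(contrast = d$contrast[1], n_genes = nrow(d),
               n_significant = sum(d$padj < alpha),
               n_positive = sum(d$padj < alpha & d$effect > 0),
               n_negative = sum(d$padj < alpha & d$effect < 0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @rdname fit_screen
#' @export
coef.sga_fit <- function(object, ...) {
  tb <- object$table
  genes <- sort(unique(tb$gene_id))
  cons <- names(object$contrasts)
  M <- matrix(NA_real_, length(genes), length(cons),
              dimnames = list(genes, cons))
  M[cbind(match(tb$gene_id, genes), match(tb$contrast, cons))] <- tb$effect
  M
}
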