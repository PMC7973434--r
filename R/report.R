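# Exploratory summaries: PCA of screen samples, hierarchical clustering of
# interaction profiles, and plot-ready diagnostic tables. All outputs are
# plain tables; plotting is left to the caller.

#' PCA of screen samples
#'
#' Centered principal component analysis of the (query, batch) samples of
#' a gene x sample matrix (typically batch-adjusted condition means).
#' Missing values are imputed by the gene mean. Component signs are fixed
#' by making each component's largest-magnitude loading positive, so
#' results are fully deterministic.
#'
#' @param matrix numeric gene x sample matrix.
#' @return list of class `sga_pca`: `scores` (sample x PC data frame),
#'   `loadings`, `var_explained` (percent; sums to 100).
#' @export
pca_scores <- function(matrix) {
  if (ncol(matrix) < 2L) stopf("sga_argument_error", "PCA needs >= 2 samples")
  M <- as.matrix(matrix)
  gm <- rowMeans(M, na.rm = TRUE)
  gm[is.nan(gm)] <- 0
  na <- which(is.na(M), arr.ind = TRUE)
  if (nrow(na)) M[na] <- gm[na[, 1]]
  pc <- stats::prcomp(t(M), center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = data.frame(sample = colnames(M), pc$x, stringsAsFactors = FALSE,
                        row.names = NULL),
    loadings = pc$rotation,
    var_explained = ve
  ), class = "sga_pca")
}

# uncentered correlation: cos similarity of raw profiles (no centering),
# the clustering default of the classic colony-screen cluster tool
uncentered_cor_dist <- function(M) {
  norms <- sqrt(rowSums(M^2))
  zero <- norms == 0
  if (any(zero)) {
    warnf("%d constant-zero profile(s) assigned maximal distance", sum(zero))
    norms[zero] <- 1
  }
  S <- tcrossprod(M / norms)
  D <- 1 - S
  D[zero, ] <- 2
  D[, zero] <- 2
  diag(D) <- 0
  D
}

#' Hierarchical clustering of interaction profiles
#'
#' Agglomerative clustering of genes over their per-strain normalized
#' colony-size differences, using uncentered correlation distance and
#' average linkage by default. Per-gene display color classes use the
#' conventional reporting thresholds (negative below -0.5, positive above
#' +0.5); these are display-only constants, never used for calling.
#'
#' @param matrix numeric gene x strain matrix (NA imputed by gene mean).
#' @param metric "uncentered" (default), "correlation", or "euclidean".
#' @param linkage linkage method passed to [stats::hclust()].
#' @param color_threshold display threshold for the color classes.
#' @return list of class `sga_cluster`: `order`, `merge`, `height`,
#'   `labels`, `classes` (gene x strain character matrix), `hclust`.
#' @export
hcluster <- function(matrix, metric = c("uncentered", "correlation", "euclidean"),
                     linkage = "average", color_threshold = 0.5) {
  metric <- match.arg(metric)
  M <- as.matrix(matrix)
  if (nrow(M) < 2L) stopf("sga_argument_error", "clustering needs >= 2 genes")
  gm <- rowMeans(M, na.rm = TRUE)
  gm[is.nan(gm)] <- 0
  na <- which(is.na(M), arr.ind = TRUE)
  if (nrow(na)) M[na] <- gm[na[, 1]]
  D <- switch(metric,
    uncentered = stats::as.dist(uncentered_cor_dist(M)),
    correlation = stats::as.dist(1 - stats::cor(t(M))),
    euclidean = stats::dist(M)
  )
  hc <- stats::hclust(D, method = linkage)
  classes <- matrix("neutral", nrow(M), ncol(M), dimnames = dimnames(M))
  classes[M < -color_threshold] <- "negative"
  classes[M > color_threshold] <- "positive"
  structure(list(order = hc$order, merge = hc$merge, height = hc$height,
                 labels = rownames(M), classes = classes, hclust = hc),
            class = "sga_cluster")
}
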