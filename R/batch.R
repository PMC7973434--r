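# Display-side batch correction and condition means. Used only for PCA and
# clustering; inference keeps batch as a model term instead.

#' Per-condition mean matrix
#'
#' Collapses a long screen matrix to gene x (query, batch) sample means,
#' the input shape for PCA, clustering and batch-effect removal.
#'
#' @param matrix an `sga_matrix`.
#' @return numeric matrix, rows = genes, columns = `query.batch` samples;
#'   attributes `query` and `batch` give the per-column labels.
#' @export
condition_means <- function(matrix) {
  sample_id <- paste(matrix$query, matrix$batch, sep = ".")
  genes <- sort(unique(matrix$gene_id))
  samples <- unique(sample_id[order(matrix$query, matrix$batch)])
  M <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  agg <- tapply(matrix$value, list(matrix$gene_id, sample_id), mean)
  M[rownames(agg), colnames(agg)] <- agg
  structure(M,
            query = sub("\\.[^.]+$", "", samples),
            batch = sub("^.*\\.", "", samples))
}

#' Remove batch effects for display
#'
#' Subtracts per-gene batch effects estimated jointly with the query
#' effects in an additive linear model (delegated to
#' `limma::removeBatchEffect`, with the query design protected). The grand
#' mean is preserved. Intended only for PCA and cluster displays -- the
#' differential-fitness model keeps batch as a term and must not be fed
#' batch-corrected values.
#'
#' @param matrix gene x sample numeric matrix (e.g. [condition_means()]).
#' @param batch_labels batch label per column; defaults to the `batch`
#'   attribute of `matrix`.
#' @param query_labels query label per column (protected covariate);
#'   defaults to the `query` attribute.
#' @return adjusted matrix of the same shape.
#' @export
remove_batch_effect <- function(matrix, batch_labels = attr(matrix, "batch"),
                                query_labels = attr(matrix, "query")) {
  if (is.null(batch_labels) || length(batch_labels) != ncol(matrix)) {
    stopf("sga_argument_error", "need one batch label per column")
  }
  if (length(unique(batch_labels)) < 2L) {
    warnf("single batch: batch-effect removal is the identity")
    return(matrix)
  }
  design <- if (!is.null(query_labels) && length(unique(query_labels)) > 1L) {
    stats::model.matrix(~ factor(query_labels))
  } else {
    matrix(1, ncol(matrix), 1)
  }
  adj <- limma::removeBatchEffect(matrix, batch = factor(batch_labels),
                                  design = design)
  attributes(adj)[c("query", "batch")] <- attributes(matrix)[c("query", "batch")]
  adj
}
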