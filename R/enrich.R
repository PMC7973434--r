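# Over-representation analysis of interaction gene sets and disease-slim
# mapping.

#' Hypergeometric over-representation of annotation terms
#'
#' One-sided hypergeometric tail test P(X >= k) per term, where k is the
#' overlap of the query set with the term, K the term size within the
#' background, n the query size and N the background size. Term gene sets
#' are intersected with the background before testing. BH adjustment runs
#' across all tested terms of the collection; rows with q below
#' `q_threshold` are flagged enriched. The background should be the screen
#' universe: all library genes surviving the failed-mutant and linkage
#' filters.
#'
#' @param query_genes character vector of interacting genes (duplicates
#'   ignored); must be a subset of `background`.
#' @param sets an `sga_genesets` collection ([read_gmt()]).
#' @param background character vector of tested genes.
#' @param q_threshold FDR threshold for the `enriched` flag (default 0.1).
#' @return data frame sorted by p: `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `p`, `q`, `enriched`, list-column `overlap`.
#' @export
enrich <- function(query_genes, sets, background, q_threshold = 0.1) {
  query <- unique(query_genes)
  background <- unique(background)
  if (!length(query) || !length(background)) {
    stopf("sga_argument_error", "query and background must be non-empty")
  }
  out_of_bg <- setdiff(query, background)
  if (length(out_of_bg)) {
    stopf("sga_argument_error", "query gene(s) outside the background: %s",
          paste(out_of_bg[seq_len(min(3, length(out_of_bg)))], collapse = ", "))
  }
  N <- length(background)
  n <- length(query)
  term_bg <- lapply(sets$genes, intersect, background)
  keep <- lengths(term_bg) > 0L
  term_bg <- term_bg[keep]
  overlap <- lapply(term_bg, intersect, query)
  k <- lengths(overlap)
  K <- lengths(term_bg)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  q <- adjust_bh(p)
  out <- data.frame(term_id = sets$term_id[keep], term_name = sets$term_name[keep],
                    k = k, K = K, n = n, N = N, p = p, q = q,
                    enriched = q < q_threshold, stringsAsFactors = FALSE)
  out$overlap <- I(lapply(overlap, sort))
  out <- out[order(out$p, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Map interacting genes onto a disease slim
#'
#' Per disease term, the intersection of the query set with the disease's
#' gene set and its size; diseases with empty intersections are omitted. A
#' gene may contribute to several diseases.
#'
#' @param query_genes character vector of interacting genes.
#' @param slim an `sga_slim` ([read_disease_slim()]).
#' @return data frame sorted by decreasing count: `disease_id`,
#'   `disease_name`, `count`, list-column `genes`.
#' @export
map_diseases <- function(query_genes, slim) {
  query <- unique(query_genes)
  hits <- lapply(slim$genes, intersect, query)
  keep <- lengths(hits) > 0L
  out <- data.frame(disease_id = slim$disease_id[keep],
                    disease_name = slim$disease_name[keep],
                    count = lengths(hits[keep]), stringsAsFactors = FALSE)
  out$genes <- I(lapply(hits[keep], sort))
  out <- out[order(-out$count, out$disease_id), ]
  rownames(out) <- NULL
  out
}
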