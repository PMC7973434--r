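# Annotation gene sets (GMT) and disease-slim term->gene maps.

#' Read annotation gene sets from a GMT file
#'
#' GMT: one term per line, tab-separated: term id, description, then member
#' genes. Duplicate genes within a term are collapsed; terms with no genes
#' are dropped with a warning. (A hand parser is used here because the
#' available GMT readers discard the description column, which is kept as
#' the human-readable term name.)
#'
#' @param path GMT file path.
#' @return data frame of class `sga_genesets`: columns `term_id`,
#'   `term_name` and list-column `genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("sga_format_error", "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 2L
  if (any(short)) {
    stopf("sga_format_error", "%s: GMT line %d has fewer than 2 fields",
          path, which(short)[1])
  }
  term_id <- vapply(parts, `[[`, "", 1L)
  term_name <- vapply(parts, `[[`, "", 2L)
  genes <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  keep <- lengths(genes) > 0L
  if (any(!keep)) {
    warnf("dropping %d GMT term(s) with empty gene lists (%s)",
          sum(!keep), paste(term_id[!keep][1:min(3, sum(!keep))], collapse = ", "))
  }
  if (anyDuplicated(term_id[keep])) {
    stopf("sga_format_error", "%s: duplicate term id %s", path,
          term_id[keep][duplicated(term_id[keep])][1])
  }
  out <- data.frame(term_id = term_id[keep], term_name = term_name[keep],
                    stringsAsFactors = FALSE)
  out$genes <- I(genes[keep])
  class(out) <- c("sga_genesets", "data.frame")
  out
}

#' Read a disease-slim mapping (disease term -> gene)
#'
#' TSV with columns `disease_id`, `disease_name`, `gene_id`, one gene per
#' row; a gene may map to several diseases. Rows are aggregated per
#' disease.
#'
#' @param path TSV file path.
#' @return data frame of class `sga_slim`: `disease_id`, `disease_name`,
#'   list-column `genes`.
#' @export
read_disease_slim <- function(path) {
  if (!file.exists(path)) stopf("sga_format_error", "no such file: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("disease_id", "disease_name", "gene_id")
  if (!all(need %in% names(df))) {
    stopf("sga_format_error", "%s: expected columns %s", path,
          paste(need, collapse = ", "))
  }
  ids <- unique(df$disease_id)
  name_of <- df$disease_name[match(ids, df$disease_id)]
  clash <- vapply(ids, function(i) length(unique(df$disease_name[df$disease_id == i])) > 1L,
                  TRUE)
  if (any(clash)) {
    stopf("sga_format_error", "%s: disease id %s has conflicting names", path,
          ids[clash][1])
  }
  genes <- lapply(ids, function(i) unique(df$gene_id[df$disease_id == i]))
  out <- data.frame(disease_id = ids, disease_name = name_of,
                    stringsAsFactors = FALSE)
  out$genes <- I(genes)
  class(out) <- c("sga_slim", "data.frame")
  out
}
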