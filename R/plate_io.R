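# Raw colony-size plate tables (quantifier output): TSV with one row per
# grid position. '#'-prefixed lines are comments. Sizes are arbitrary
# pixel-area units; everything downstream is scale-invariant after log2 /
# median normalization.

plate_columns <- c("batch", "query", "plate", "row", "col", "size",
                   "position_kind", "gene_id")

validate_plate_table <- function(df, path = "<data>", line_of = NULL) {
  where <- function(i) {
    if (is.null(line_of)) sprintf("row %d", i) else sprintf("line %d", line_of[i])
  }
  bad <- which(!is.finite(df$size) | df$size < 0)
  if (length(bad)) {
    stopf("sga_format_error", "%s: negative or non-numeric colony size at %s",
          path, where(bad[1]))
  }
  key <- paste(df$batch, df$query, df$plate, df$row, df$col)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stopf("sga_format_error", "%s: duplicate plate position at %s", path,
          where(dup[1]))
  }
  miss <- which(df$position_kind == "library" & (is.na(df$gene_id) | !nzchar(df$gene_id)))
  if (length(miss)) {
    stopf("sga_format_error", "%s: library position without gene_id at %s",
          path, where(miss[1]))
  }
  extra <- which(df$position_kind != "library" & !is.na(df$gene_id) & nzchar(df$gene_id))
  if (length(extra)) {
    stopf("sga_format_error", "%s: gene_id on non-library position at %s",
          path, where(extra[1]))
  }
  invisible(df)
}

#' Read / write a raw colony-size plate table
#'
#' The on-disk format is a TSV with a header line and columns `batch`,
#' `query`, `plate`, `row`, `col`, `size`, `position_kind`, `gene_id`
#' (empty on non-library positions). Comment lines starting with `#` are
#' ignored. Malformed rows are reported with their file line number.
#'
#' @param path file path.
#' @return `read_plate_table`: a data frame of class `sga_plates`.
#' @export
read_plate_table <- function(path) {
  if (!file.exists(path)) stopf("sga_format_error", "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  body <- lines[keep]
  empty <- data.frame(batch = character(), query = character(),
                      plate = character(), row = integer(), col = integer(),
                      size = numeric(), position_kind = character(),
                      gene_id = character(), stringsAsFactors = FALSE)
  class(empty) <- c("sga_plates", "data.frame")
  if (length(body) == 0L) return(empty)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, plate_columns)) {
    stopf("sga_format_error", "%s: expected header '%s'", path,
          paste(plate_columns, collapse = "\t"))
  }
  if (length(body) == 1L) return(empty)
  df <- utils::read.table(text = body[-1], sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          col.names = plate_columns,
                          colClasses = c("character", "character", "character",
                                         "integer", "integer", "numeric",
                                         "character", "character"),
                          na.strings = character())
  df$gene_id[!nzchar(df$gene_id)] <- NA_character_
  line_of <- which(keep)[-1]  # file line number of each data row
  validate_plate_table(df, path, line_of)
  class(df) <- c("sga_plates", "data.frame")
  df
}

#' @param table a plate table (`sga_plates` or plain data frame with the
#'   same columns).
#' @rdname read_plate_table
#' @export
write_plate_table <- function(table, path) {
  if (!all(plate_columns %in% names(table))) {
    stopf("sga_argument_error", "plate table must have columns %s",
          paste(plate_columns, collapse = ", "))
  }
  df <- as.data.frame(table)[, plate_columns]
  validate_plate_table(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
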