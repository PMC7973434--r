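# Library plate layout: which grid position of which plate carries which
# deletion-library gene. Quadruplicate pinning means each gene occupies one
# 2x2 block of colonies; grid indices are 1-based with a top-left origin,
# matching common colony-quantifier output.

#' Assign library genes to quadruplicate plate positions
#'
#' Each gene occupies one 2x2 block on a rows x cols colony grid (1536
#' format by default: 32 x 48 colonies = 384 blocks per plate). Genes are
#' placed in genome order; extra plates are added when the library does not
#' fit on one. A configurable number of blocks per plate is reserved empty
#' (guide/control quadrants, kept empty on every query so the layout is
#' shared across the whole screen).
#'
#' @param genome an `sga_genome` data frame.
#' @param plate_rows,plate_cols colony grid dimensions (both even).
#' @param quad colonies per gene block; only 4 (a 2x2 block) is supported.
#' @param control_empty_quadrants blocks per plate left deliberately empty.
#' @param n_plates optional fixed plate count; an error is raised if the
#'   library does not fit.
#' @param seed RNG seed for the placement of the empty quadrants.
#' @return data frame of class `sga_layout` with one row per colony
#'   position: `plate`, `row`, `col`, `block`, `gene_id` (NA on empty
#'   positions), `position_kind` ("library"/"empty"), `forced_empty`.
#' @export
make_layout <- function(genome, plate_rows = 32L, plate_cols = 48L, quad = 4L,
                        control_empty_quadrants = 0L, n_plates = NULL, seed = 1L) {
  plate_rows <- check_count(plate_rows, "plate_rows")
  plate_cols <- check_count(plate_cols, "plate_cols")
  if (quad != 4L) stopf("sga_argument_error", "only quad = 4 (2x2 blocks) is supported")
  if (plate_rows %% 2L || plate_cols %% 2L) {
    stopf("sga_argument_error", "plate_rows and plate_cols must be even for 2x2 blocks")
  }
  validate_genome(genome)
  n_genes <- nrow(genome)
  bpp <- (plate_rows %/% 2L) * (plate_cols %/% 2L)  # blocks per plate
  if (control_empty_quadrants >= bpp) {
    stopf("sga_argument_error", "control_empty_quadrants must be < blocks per plate (%d)", bpp)
  }
  usable <- bpp - control_empty_quadrants
  np <- if (is.null(n_plates)) max(1L, as.integer(ceiling(n_genes / usable))) else
    check_count(n_plates, "n_plates")
  if (n_genes > np * usable) {
    stopf("sga_capacity_error",
          "library of %d genes does not fit on %d plate(s) of %d usable blocks",
          n_genes, np, usable)
  }

  set.seed(seed)
  brow <- rep(seq_len(plate_rows %/% 2L), each = plate_cols %/% 2L)
  bcol <- rep(seq_len(plate_cols %/% 2L), times = plate_rows %/% 2L)
  out <- vector("list", np)
  gene_cursor <- 0L
  for (p in seq_len(np)) {
    forced <- rep(FALSE, bpp)
    if (control_empty_quadrants > 0L) {
      forced[sample.int(bpp, control_empty_quadrants)] <- TRUE
    }
    gid <- rep(NA_character_, bpp)
    open <- which(!forced)
    take <- min(length(open), n_genes - gene_cursor)
    if (take > 0L) {
      gid[open[seq_len(take)]] <- genome$gene_id[gene_cursor + seq_len(take)]
      gene_cursor <- gene_cursor + take
    }
    block_global <- (p - 1L) * bpp + seq_len(bpp)
    # expand each block to its 2x2 colony positions
    idx <- rep(seq_len(bpp), each = 4L)
    dr <- rep(c(0L, 0L, 1L, 1L), times = bpp)
    dc <- rep(c(0L, 1L, 0L, 1L), times = bpp)
    out[[p]] <- data.frame(
      plate = sprintf("p%02d", p),
      row = 2L * brow[idx] - 1L + dr,
      col = 2L * bcol[idx] - 1L + dc,
      block = block_global[idx],
      gene_id = gid[idx],
      position_kind = ifelse(is.na(gid[idx]), "empty", "library"),
      forced_empty = forced[idx],
      stringsAsFactors = FALSE
    )
  }
  layout <- do.call(rbind, out)
  class(layout) <- c("sga_layout", "data.frame")
  layout
}

layout_columns <- c("plate", "row", "col", "block", "gene_id", "position_kind",
                    "forced_empty")

#' Write / read a plate layout as TSV
#'
#' Round-trip safe: `read_layout(write_layout(x, f))` reproduces `x`.
#'
#' @param layout an `sga_layout` data frame.
#' @param path file path.
#' @export
write_layout <- function(layout, path) {
  utils::write.table(layout[, layout_columns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = c(plate = "character", row = "integer",
                                         col = "integer", block = "integer",
                                         gene_id = "character",
                                         position_kind = "character",
                                         forced_empty = "logical"))
  if (!identical(names(df), layout_columns)) {
    stopf("sga_format_error", "layout file %s: expected columns %s", path,
          paste(layout_columns, collapse = ", "))
  }
  df$gene_id[!nzchar(df$gene_id) | is.na(df$gene_id)] <- NA_character_
  key <- paste(df$plate, df$row, df$col)
  if (anyDuplicated(key)) {
    stopf("sga_format_error", "layout file %s: duplicate position %s", path,
          key[duplicated(key)][1])
  }
  class(df) <- c("sga_layout", "data.frame")
  df
}
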