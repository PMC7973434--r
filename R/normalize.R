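# Plate normalization and screen-matrix assembly.
#
# Raw sizes are converted to log2 values relative to the plate median over
# library positions, then corrected for row/column effects (median polish)
# and for smooth spatial gradients (moving 2D median of the residuals).
# Zero-size colonies are growth failures, not fitness measurements, and
# become missing values. Medians are always taken over library positions
# only: empty control quadrants would otherwise bias them.

#' Flag library mutants that failed to grow on the control plates
#'
#' A library gene is flagged, independently for each batch, when its median
#' control colony size is below `min_fraction` times the median library
#' colony size of its plate (strict `<`). Flagged genes are removed from
#' that batch for all queries downstream.
#'
#' @param control_plates plate table restricted to the control query (any
#'   number of batches/plates).
#' @param min_fraction fraction of the plate median below which a mutant
#'   counts as failed (default 0.1).
#' @return exclusion report: data frame with `gene_id`, `reason`
#'   (`"failed_control"`), `batch`, `distance_bp` (NA), `query` (NA).
#' @export
flag_failed_mutants <- function(control_plates, min_fraction = 0.1) {
  if (nrow(control_plates) == 0L) {
    stopf("sga_processing_error", "no control plates supplied")
  }
  min_fraction <- check_prob(min_fraction, "min_fraction")
  lib <- control_plates[control_plates$position_kind == "library", ]
  if (nrow(lib) == 0L) stopf("sga_processing_error", "control plates have no library positions")
  out <- list()
  for (b in unique(lib$batch)) {
    lb <- lib[lib$batch == b, ]
    plate_med <- tapply(lb$size, lb$plate, stats::median)
    gene_med <- tapply(lb$size, lb$gene_id, stats::median)
    gene_plate <- tapply(lb$plate, lb$gene_id, function(p) p[1])
    failed <- names(gene_med)[gene_med < min_fraction * plate_med[gene_plate]]
    if (length(failed)) {
      out[[b]] <- data.frame(gene_id = failed, reason = "failed_control",
                             batch = b, distance_bp = NA_real_,
                             query = NA_character_, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), reason = character(), batch = character(),
               distance_bp = numeric(), query = character(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# Moving 2D median with half-window h, NA-tolerant; all-NA windows -> 0.
# With exclude_block = TRUE the four cells of the centre 2x2 quadruplicate
# are left out of their own window, so the surface estimate never
# subtracts the block effect (or planted interaction) it sits on.
moving_median_2d <- function(M, h = 4L, exclude_block = TRUE) {
  .moving_median_2d_cpp(M, as.integer(h), isTRUE(exclude_block))
}

# Iterate plate/row/column median subtraction to its fixed point. Plain
# alternating sweeps converge only at a power-law rate on even-sized rows
# and columns, so after a few sweeps the remaining offsets are removed by
# a Newton step: once the middle order statistics of every row/column are
# stable, "all medians zero" is a linear system in one global, nr row and
# nc column offsets, solved exactly.
polish_medians <- function(M, tol = 1e-11, max_iter = 8L) {
  for (round in seq_len(max_iter)) {
    M <- .polish_medians_cpp(M, tol, 20L)
    if (worst_median(M) < tol) return(M)
    M <- newton_polish(M)
    if (worst_median(M) < tol) return(M)
  }
  M
}

worst_median <- function(M) {
  g <- stats::median(M, na.rm = TRUE)
  r <- apply(M, 1, stats::median, na.rm = TRUE)
  c_ <- apply(M, 2, stats::median, na.rm = TRUE)
  max(abs(c(g, r, c_)), na.rm = TRUE)
}

newton_polish <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  nun <- 1L + nr + nc  # unknowns: global, row and column offsets
  M0 <- M
  M0[is.na(M0)] <- 0
  mid_weights <- function(v) {
    # weight per element of v expressing its median as a linear form
    ok <- which(!is.na(v))
    n <- length(ok)
    if (n == 0L) return(NULL)
    o <- ok[order(v[ok])]
    w <- numeric(length(v))
    if (n %% 2L) w[o[(n + 1L) %/% 2L]] <- 1 else
      w[o[c(n %/% 2L, n %/% 2L + 1L)]] <- 0.5
    w
  }
  A <- matrix(0, 1L + nr + nc, nun)
  rhs <- numeric(1L + nr + nc)
  gw <- mid_weights(as.vector(M))
  if (!is.null(gw)) {
    GW <- matrix(gw, nr, nc)
    A[1L, ] <- c(1, rowSums(GW), colSums(GW))
    rhs[1L] <- sum(GW * M0)
  }
  for (i in seq_len(nr)) {
    w <- mid_weights(M[i, ])
    if (is.null(w)) next
    A[1L + i, 1L] <- 1
    A[1L + i, 1L + i] <- 1
    A[1L + i, 1L + nr + seq_len(nc)] <- w
    rhs[1L + i] <- sum(w * M0[i, ])
  }
  for (j in seq_len(nc)) {
    w <- mid_weights(M[, j])
    if (is.null(w)) next
    A[1L + nr + j, 1L] <- 1
    A[1L + nr + j, 1L + nr + j] <- 1
    A[1L + nr + j, 1L + seq_len(nr)] <- w
    rhs[1L + nr + j] <- sum(w * M0[, j])
  }
  cf <- stats::lm.fit(A, rhs)$coefficients
  cf[is.na(cf)] <- 0
  M - (cf[1L] + outer(cf[1L + seq_len(nr)], cf[1L + nr + seq_len(nc)], `+`))
}

#' Normalize one plate of raw colony sizes
#'
#' Steps: log2, subtract plate median (library positions), iterated
#' row/column median polish, subtraction of a smooth spatial surface (9x9
#' moving median of the residuals), then a final short polish so plate,
#' row and column medians are all zero. Zero-size positions become NA.
#'
#' @param plate plate table rows for one physical plate (one batch, query,
#'   plate label).
#' @param min_live_fraction minimum fraction of library positions with
#'   nonzero size; below this the plate is rejected.
#' @param spatial_halfwidth half-width of the moving-median window
#'   (4 gives the 9x9 default).
#' @return the input rows with an added `value` column (normalized log2
#'   size; NA for empty or failed positions).
#' @export
normalize_plate <- function(plate, min_live_fraction = 0.5, spatial_halfwidth = 4L) {
  key <- unique(paste(plate$batch, plate$query, plate$plate))
  if (length(key) != 1L) {
    stopf("sga_argument_error", "normalize_plate expects rows of exactly one plate")
  }
  nr <- max(plate$row); nc <- max(plate$col)
  M <- matrix(NA_real_, nr, nc)
  lib <- plate$position_kind == "library"
  live <- lib & plate$size > 0
  if (sum(live) < min_live_fraction * sum(lib)) {
    stopf("sga_processing_error",
          "plate %s rejected: only %d of %d library colonies grew", key,
          sum(live), sum(lib))
  }
  M[cbind(plate$row[live], plate$col[live])] <- log2(plate$size[live])
  M <- M - stats::median(M, na.rm = TRUE)
  M <- polish_medians(M)
  M <- M - moving_median_2d(M, spatial_halfwidth)
  M <- polish_medians(M)
  plate$value <- M[cbind(plate$row, plate$col)]
  plate$value[!lib] <- NA_real_
  plate
}

#' Normalize every plate of a screen
#'
#' Applies [normalize_plate()] per (batch, query, plate); rejected plates
#' abort with a processing error naming the plate.
#'
#' @param plates full raw plate table.
#' @param ... passed to [normalize_plate()].
#' @return plate table with the `value` column filled.
#' @export
normalize_screen <- function(plates, ...) {
  sp <- split(seq_len(nrow(plates)),
              paste(plates$batch, plates$query, plates$plate))
  plates$value <- NA_real_
  for (idx in sp) {
    plates$value[idx] <- normalize_plate(plates[idx, , drop = FALSE], ...)$value
  }
  plates
}

#' Assemble the long-format screen matrix
#'
#' Collects normalized library observations into one long table keyed by
#' (gene, query, batch, replicate), drops excluded genes and missing
#' colonies, and assigns the quadruplicate block labels used by the mixed
#' model. Exclusions with reason `failed_control` remove a (gene, batch)
#' for every query; reason `linked` removes a (gene, query) pair (or the
#' gene everywhere when the report has no query column entry).
#'
#' @param normalized plate table with `value` column ([normalize_screen()]).
#' @param layout the `sga_layout` the plates were pinned from.
#' @param exclusions optional exclusion report (rbind of
#'   [flag_failed_mutants()] / [apply_linkage_filter()] outputs).
#' @return data frame of class `sga_matrix`: `gene_id`, `query`, `batch`,
#'   `replicate`, `value`, `weight`, `block_id`.
#' @export
assemble_matrix <- function(normalized, layout, exclusions = NULL) {
  if (is.null(normalized$value)) {
    stopf("sga_argument_error", "plates are not normalized (no 'value' column)")
  }
  lkey <- paste(layout$plate, layout$row, layout$col)
  pkey <- paste(normalized$plate, normalized$row, normalized$col)
  m <- match(pkey, lkey)
  if (anyNA(m)) {
    stopf("sga_structural_error", "plate position %s not present in layout",
          pkey[which(is.na(m))[1]])
  }
  same <- function(a, b) (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
  if (!all(same(normalized$gene_id, layout$gene_id[m]))) {
    stopf("sga_structural_error", "plate/layout gene assignment mismatch")
  }
  d <- normalized[normalized$position_kind == "library" & !is.na(normalized$value), ]
  d <- d[order(d$query, d$batch, d$gene_id, d$plate, d$row, d$col), ]
  blk <- paste(d$gene_id, d$query, d$batch, sep = ".")
  rep_idx <- stats::ave(seq_along(blk), blk, FUN = seq_along)
  out <- data.frame(gene_id = d$gene_id, query = d$query, batch = d$batch,
                    replicate = rep_idx, value = d$value, weight = 1,
                    block_id = blk, stringsAsFactors = FALSE)
  if (!is.null(exclusions) && nrow(exclusions)) {
    fe <- exclusions[exclusions$reason == "failed_control", ]
    if (nrow(fe)) {
      out <- out[!(paste(out$gene_id, out$batch) %in% paste(fe$gene_id, fe$batch)), ]
    }
    le <- exclusions[exclusions$reason == "linked", ]
    if (nrow(le)) {
      global <- le$gene_id[is.na(le$query)]
      out <- out[!(out$gene_id %in% global), ]
      perq <- le[!is.na(le$query), ]
      if (nrow(perq)) {
        out <- out[!(paste(out$gene_id, out$query) %in%
                       paste(perq$gene_id, perq$query)), ]
      }
    }
  }
  rownames(out) <- NULL
  class(out) <- c("sga_matrix", "data.frame")
  out
}
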