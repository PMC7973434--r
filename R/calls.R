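# Significant-interaction calling, overlap accounting, and the trifecta
# classification of an allele against the reference deletion: lost
# (shared), retained/restored (reversed), and gained (unique) functions.

#' Call significant genetic interactions
#'
#' A gene is called for a strain iff the adjusted p-value of its
#' mutant-vs-control contrast is below `alpha`; the interaction sign is
#' the sign of the effect. No effect-size floor is applied.
#'
#' @param fits an `sga_fit` or a fit table data frame.
#' @param alpha significance threshold in (0, 1).
#' @param contrasts optional character vector restricting which contrasts
#'   are treated as strain screens; defaults to every `*_vs_<control>`
#'   contrast of an `sga_fit`, or all contrasts of a plain table.
#' @return data frame of class `sga_calls`: `gene_id`, `strain`, `sign`,
#'   `effect`, `padj`.
#' @export
call_interactions <- function(fits, alpha = 0.05, contrasts = NULL) {
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    stopf("sga_argument_error", "'alpha' must be in (0, 1)")
  }
  tb <- if (inherits(fits, "sga_fit")) fits$table else fits
  if (is.null(contrasts)) {
    contrasts <- if (inherits(fits, "sga_fit")) {
      grep(paste0("_vs_", fits$control, "$"), names(fits$contrasts), value = TRUE)
    } else unique(tb$contrast)
  }
  d <- tb[tb$contrast %in% contrasts & tb$padj < alpha, ]
  out <- data.frame(
    gene_id = d$gene_id,
    strain = sub("_vs_.*$", "", d$contrast),
    sign = ifelse(d$effect > 0, "positive", "negative"),
    effect = d$effect, padj = d$padj,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("sga_calls", "data.frame")
  out
}

#' Overlap accounting between strain call sets
#'
#' Per-strain totals (positive/negative/total/unique) and shared counts
#' for every strain pair, triple, etc. With `sign_consistent = TRUE` a
#' gene only counts as shared when its interaction sign agrees in all
#' members of the combination.
#'
#' @param calls an `sga_calls` data frame covering >= 2 strains.
#' @param sign_consistent require sign agreement for shared counts.
#' @return list with `per_strain` and `shared` data frames.
#' @export
overlap_counts <- function(calls, sign_consistent = FALSE) {
  strains <- sort(unique(calls$strain))
  if (length(strains) < 2L) {
    stopf("sga_argument_error", "overlap accounting needs >= 2 strains")
  }
  sets <- lapply(strains, function(s) calls$gene_id[calls$strain == s])
  names(sets) <- strains
  signs <- lapply(strains, function(s) {
    stats::setNames(calls$sign[calls$strain == s], calls$gene_id[calls$strain == s])
  })
  names(signs) <- strains
  per_strain <- data.frame(
    strain = strains,
    n_positive = vapply(strains, function(s) sum(calls$strain == s & calls$sign == "positive"), 0L),
    n_negative = vapply(strains, function(s) sum(calls$strain == s & calls$sign == "negative"), 0L),
    stringsAsFactors = FALSE
  )
  per_strain$n_total <- per_strain$n_positive + per_strain$n_negative
  per_strain$n_unique <- vapply(strains, function(s) {
    others <- unique(unlist(sets[setdiff(strains, s)]))
    sum(!sets[[s]] %in% others)
  }, 0L)
  combos <- list()
  for (m in 2:length(strains)) {
    cm <- utils::combn(strains, m, simplify = FALSE)
    for (members in cm) {
      common <- Reduce(intersect, sets[members])
      if (sign_consistent && length(common)) {
        agree <- vapply(common, function(g) {
          length(unique(vapply(members, function(s) signs[[s]][[g]], ""))) == 1L
        }, TRUE)
        common <- common[agree]
      }
      combos[[length(combos) + 1L]] <- data.frame(
        members = paste(members, collapse = "+"), size = m,
        n_shared = length(common), stringsAsFactors = FALSE)
    }
  }
  list(per_strain = per_strain, shared = do.call(rbind, combos))
}

trifecta_categories <- c("shared_positive", "shared_negative",
                         "residual_restored", "increased_sensitivity",
                         "unique_gain_positive", "unique_gain_negative",
                         "none")

#' Trifecta classification of an allele against the reference deletion
#'
#' Compares three contrasts over one gene universe: A = allele vs control,
#' B = reference deletion vs control, D = allele vs reference. Priority
#' rules (first match wins) assign each gene exactly one category:
#'
#' 1. `unique_gain_{sign}` -- D significant, B not (an interaction the
#'    allele has but the deletion lacks; sign from A when A is
#'    significant, else from D);
#' 2. `residual_restored` -- D and B significant with opposite signs
#'    (the allele reverts the deletion's interaction: retained function);
#' 3. `increased_sensitivity` -- D and B significant with the same sign;
#' 4. `shared_{sign}` -- A and B significant with equal sign, D not
#'    (function lost by both alleles alike);
#' 5. `none`.
#'
#' @param fitA,fitB,fitD data frames with `gene_id`, `effect`, `padj` for
#'   the three contrasts, over identical gene sets.
#' @param alpha significance threshold on adjusted p-values.
#' @return data frame of class `sga_trifecta`: `gene_id`, `category`, and
#'   the supporting effects/padj of A, B and D.
#' @export
classify_trifecta <- function(fitA, fitB, fitD, alpha = 0.05) {
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    stopf("sga_argument_error", "'alpha' must be in (0, 1)")
  }
  gs <- sort(fitA$gene_id)
  if (!identical(gs, sort(fitB$gene_id)) || !identical(gs, sort(fitD$gene_id))) {
    stopf("sga_structural_error",
          "the three contrasts must cover the same gene universe")
  }
  A <- fitA[match(gs, fitA$gene_id), ]
  B <- fitB[match(gs, fitB$gene_id), ]
  D <- fitD[match(gs, fitD$gene_id), ]
  sigA <- A$padj < alpha; sigB <- B$padj < alpha; sigD <- D$padj < alpha
  sgn <- function(x) ifelse(x > 0, 1, ifelse(x < 0, -1, 0))
  cat <- rep("none", length(gs))
  lab <- function(s) ifelse(s > 0, "positive", "negative")
  # 1: unique gain
  i <- sigD & !sigB
  gain_sign <- ifelse(sigA, sgn(A$effect), sgn(D$effect))
  cat[i] <- paste0("unique_gain_", lab(gain_sign[i]))
  # 2/3: allele differs from reference which itself interacts
  i2 <- !i & sigD & sigB
  opp <- sgn(D$effect) == -sgn(B$effect)
  cat[i2 & opp] <- "residual_restored"
  cat[i2 & !opp] <- "increased_sensitivity"
  # 4: shared, same sign, no allele-reference difference
  i4 <- cat == "none" & sigA & sigB & !sigD & sgn(A$effect) == sgn(B$effect) &
    sgn(A$effect) != 0
  cat[i4] <- paste0("shared_", lab(sgn(A$effect)[i4]))
  out <- data.frame(gene_id = gs, category = cat,
                    effect_A = A$effect, padj_A = A$padj,
                    effect_B = B$effect, padj_B = B$padj,
                    effect_D = D$effect, padj_D = D$padj,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("sga_trifecta", "data.frame")
  out
}

#' Comparative 2D-volcano table
#'
#' Pairs two contrasts gene-by-gene for 2D-volcano displays: x/y effects,
#' a combined significance score (-log10 of the smaller, i.e. more
#' significant, adjusted p-value of the pair) and the quadrant label.
#'
#' @param fitX,fitY data frames with `gene_id`, `effect`, `padj` over the
#'   same genes.
#' @return data frame `gene_id`, `x`, `y`, `score`, `quadrant` (one of
#'   upper_right/upper_left/lower_left/lower_right/none).
#' @export
volcano2d_table <- function(fitX, fitY) {
  gs <- sort(fitX$gene_id)
  if (!identical(gs, sort(fitY$gene_id))) {
    stopf("sga_structural_error", "the two contrasts must cover the same genes")
  }
  X <- fitX[match(gs, fitX$gene_id), ]
  Y <- fitY[match(gs, fitY$gene_id), ]
  quadrant <- rep("none", length(gs))
  nz <- X$effect != 0 & Y$effect != 0
  quadrant[nz] <- paste0(ifelse(Y$effect[nz] > 0, "upper_", "lower_"),
                         ifelse(X$effect[nz] > 0, "right", "left"))
  data.frame(gene_id = gs, x = X$effect, y = Y$effect,
             score = -log10(pmin(X$padj, Y$padj)),
             quadrant = quadrant, stringsAsFactors = FALSE)
}

# convenience: pull one contrast of a fit table as a per-gene frame
contrast_table <- function(fits, contrast) {
  tb <- if (inherits(fits, "sga_fit")) fits$table else fits
  d <- tb[tb$contrast == contrast, c("gene_id", "effect", "padj")]
  if (!nrow(d)) stopf("sga_lookup_error", "no contrast '%s' in fit table", contrast)
  rownames(d) <- NULL
  d
}
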