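#' Barnyard species-mixing table
#'
#' For every cell barcode seen in either species' digital expression
#' matrix, tabulates its UMIs per species, the minority fraction
#' `min(umis_A, umis_B) / (umis_A + umis_B)`, and the collision flag: a
#' barcode "sharing over `theta` of its UMIs with the minority species"
#' (strictly greater than; default theta 0.10) is called a collision —
#' either a cross-species doublet or two cells that received the same
#' barcode combination.
#'
#' @param matrix_A,matrix_B genes x barcodes UMI count matrices for the
#'   two species (barcode union is taken; absent = 0).
#' @param theta minority-fraction threshold, in (0, 0.5).
#' @return data.table with columns `cell_barcode`, `umis_A`, `umis_B`,
#'   `minority_fraction`, `is_collision`, sorted by barcode.
#' @export
barnyard <- function(matrix_A, matrix_B, theta = 0.10) {
  if (theta <= 0 || theta >= 0.5)
    stop("theta must lie strictly inside (0, 0.5)")
  a <- Matrix::colSums(matrix_A)
  b <- Matrix::colSums(matrix_B)
  bcs <- sort(union(names(a), names(b)))
  umis_A <- ifelse(bcs %in% names(a), a[bcs], 0)
  umis_B <- ifelse(bcs %in% names(b), b[bcs], 0)
  tot <- umis_A + umis_B
  keep <- tot > 0
  rec <- data.table::data.table(
    cell_barcode = bcs[keep],
    umis_A = unname(umis_A[keep]),
    umis_B = unname(umis_B[keep]))
  rec[, minority_fraction := pmin(umis_A, umis_B) / (umis_A + umis_B)]
  rec[, is_collision := minority_fraction > theta]
  rec[]
}

#' Cell calling and exclusion filters with full accounting
#'
#' Applies the two-stage barcode filter used after matrix creation: keep
#' barcodes detecting at least `min_genes` genes (cell calling, default
#' 125), then exclude from those any barcode with more than `max_umi`
#' total UMIs (aggregates, default 5000) or flagged as a species
#' collision. The ledger records the accounting identity
#' `n_retained = n_pass_gene_threshold - n_excluded_high_umi_or_collision`,
#' with sub-counts of the two exclusion reasons for diagnostics.
#'
#' @param matrix genes x barcodes UMI count matrix for one species.
#' @param barnyard_records output of [barnyard()] over the same barcode
#'   namespace (optional; without it no collision exclusion is applied).
#' @param min_genes cell-calling threshold on detected genes (default 125).
#' @param max_umi exclusion ceiling on total UMIs, strict (default 5000).
#' @return list with `matrix` (the filtered matrix) and `ledger` (class
#'   `filter_ledger`).
#' @export
apply_filters <- function(matrix, barnyard_records = NULL, min_genes = 125L,
                          max_umi = 5000L) {
  genes_per_bc <- Matrix::colSums(matrix > 0)
  umis_per_bc <- Matrix::colSums(matrix)
  called <- genes_per_bc >= min_genes
  n_pass <- sum(called)
  high_umi <- called & umis_per_bc > max_umi
  coll <- rep(FALSE, ncol(matrix))
  if (!is.null(barnyard_records)) {
    coll_bcs <- barnyard_records$cell_barcode[barnyard_records$is_collision]
    coll <- called & colnames(matrix) %in% coll_bcs
  }
  excluded <- high_umi | coll
  keep <- called & !excluded
  ledger <- filter_ledger(n_pass_gene_threshold = n_pass,
                          n_excluded_high_umi_or_collision = sum(excluded),
                          n_high_umi = sum(high_umi),
                          n_collision = sum(coll),
                          min_genes = min_genes, max_umi = max_umi)
  list(matrix = matrix[, keep, drop = FALSE], ledger = ledger)
}

#' Filter ledger arithmetic
#'
#' The bookkeeping object for [apply_filters()]: given the number of
#' barcodes passing the gene-count calling threshold and the number
#' excluded for high UMI content or collisions, the retained-cell count is
#' their difference. Exposed directly so the accounting can be run on
#' externally reported inputs.
#'
#' @param n_pass_gene_threshold barcodes detecting >= `min_genes` genes.
#' @param n_excluded_high_umi_or_collision barcodes among those excluded
#'   for > `max_umi` UMIs or a collision flag (single combined count).
#' @param n_high_umi,n_collision optional exclusion sub-counts.
#' @param min_genes,max_umi,theta the thresholds in force.
#' @return object of class `filter_ledger` with `n_retained` computed.
#' @export
filter_ledger <- function(n_pass_gene_threshold,
                          n_excluded_high_umi_or_collision,
                          n_high_umi = NA_integer_,
                          n_collision = NA_integer_,
                          min_genes = 125L, max_umi = 5000L, theta = 0.10) {
  stopifnot(n_excluded_high_umi_or_collision <= n_pass_gene_threshold)
  structure(list(
    n_pass_gene_threshold = as.integer(n_pass_gene_threshold),
    n_excluded_high_umi_or_collision =
      as.integer(n_excluded_high_umi_or_collision),
    n_retained = as.integer(n_pass_gene_threshold) -
      as.integer(n_excluded_high_umi_or_collision),
    n_high_umi = as.integer(n_high_umi),
    n_collision = as.integer(n_collision),
    min_genes = as.integer(min_genes), max_umi = as.integer(max_umi),
    theta = theta), class = "filter_ledger")
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat(sprintf(paste0("Cell filter ledger: %d passed >= %d genes, ",
                     "%d excluded (> %d UMIs or collision) -> %d retained\n"),
              x$n_pass_gene_threshold, x$min_genes,
              x$n_excluded_high_umi_or_collision, x$max_umi, x$n_retained))
  invisible(x)
}

#' Calibrate the doublet rate from cross-species collisions
#'
#' Cross-species collisions are directly observable in a barnyard
#' experiment; doublets form cross-species with probability
#' `2 * p_A * p_B`, so the total (within- plus cross-species) doublet
#' load is extrapolated as `n_cross_collisions / (2 * p_A * p_B)`. The
#' species proportions default to the majority-species assignment of the
#' records themselves (ties counted toward species A; vanishingly rare).
#' A binomial 95% interval on the collision count propagates to the
#' estimate.
#'
#' @param records a [barnyard()] table.
#' @param proportions optional numeric pair `c(p_A, p_B)` summing to 1;
#'   if omitted, estimated from the records' majority species.
#' @return object of class `doublet_estimate`: `n_cross_collisions`,
#'   `p_A`, `p_B`, `estimated_total_doublets`, `estimated_doublet_rate`
#'   (relative to the number of barcodes in `records`), and `ci95`
#'   (interval on the rate).
#' @export
estimate_doublets <- function(records, proportions = NULL) {
  if (nrow(records) == 0L) stop("no barcodes observed")
  if (is.null(proportions)) {
    maj_A <- records$umis_A >= records$umis_B
    p_A <- mean(maj_A)
    p_B <- 1 - p_A
  } else {
    stopifnot(length(proportions) == 2L,
              abs(sum(proportions) - 1) < 1e-8)
    p_A <- proportions[1]; p_B <- proportions[2]
  }
  n_cross <- sum(records$is_collision)
  n_bc <- nrow(records)
  if (p_A * p_B == 0) {
    warning("single-species data: doublet extrapolation undefined")
    return(structure(list(n_cross_collisions = n_cross, p_A = p_A, p_B = p_B,
                          estimated_total_doublets = NA_real_,
                          estimated_doublet_rate = NA_real_,
                          ci95 = c(NA_real_, NA_real_)),
                     class = "doublet_estimate"))
  }
  total <- n_cross / (2 * p_A * p_B)
  ci <- if (n_cross <= n_bc)
    stats::binom.test(n_cross, n_bc)$conf.int else c(NA_real_, NA_real_)
  structure(list(n_cross_collisions = n_cross, p_A = p_A, p_B = p_B,
                 estimated_total_doublets = total,
                 estimated_doublet_rate = total / n_bc,
                 ci95 = as.numeric(ci) / (2 * p_A * p_B)),
            class = "doublet_estimate")
}

#' @export
print.doublet_estimate <- function(x, ...) {
  cat(sprintf(paste0("Doublet calibration: %d cross-species collisions, ",
                     "p = (%.3f, %.3f) -> %.1f total doublets (rate %.4f)\n"),
              x$n_cross_collisions, x$p_A, x$p_B,
              x$estimated_total_doublets, x$estimated_doublet_rate))
  invisible(x)
}
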