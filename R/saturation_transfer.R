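#' Downsampling saturation analysis over a fixed cell set
#'
#' Samples each fraction of the full-depth read-assignment table without
#' replacement, re-collapses UMIs per (barcode, gene), and reports the
#' median UMIs and median detected genes per cell over the barcode set
#' called at full depth. Cells absent from a subsample contribute zeros.
#' Subsamples are nested (a read kept at fraction f is kept at every
#' larger fraction), so per-cell counts are non-decreasing in the
#' fraction, read by read.
#'
#' @param read_assignments data.table with one row per read: columns
#'   `cell_barcode`, `gene_id`, `umi` (sentinel gene ids are ignored).
#' @param fractions sampling fractions in (0, 1\], default
#'   `c(0.10, 0.25, 0.50, 0.75, 1.00)`.
#' @param fixed_barcodes the cell barcodes called from the full-depth
#'   matrix; statistics are computed over exactly this set at every
#'   fraction.
#' @param seed integer seed for the subsampling permutation.
#' @return object of class `saturation_curve`: data.table with columns
#'   `fraction`, `median_umis`, `median_genes`, plus attribute
#'   `per_cell` (list of per-fraction per-cell count tables).
#' @export
saturation <- function(read_assignments,
                       fractions = c(0.10, 0.25, 0.50, 0.75, 1.00),
                       fixed_barcodes, seed = 1L) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  fractions <- sort(fractions)
  fixed_barcodes <- as.character(fixed_barcodes)
  if (length(fixed_barcodes) == 0L) {
    warning("empty fixed barcode set; saturation medians undefined")
    out <- data.table::data.table(fraction = fractions,
                                  median_umis = NA_real_,
                                  median_genes = NA_real_)
    return(structure(out[], class = c("saturation_curve", class(out)),
                     per_cell = list()))
  }
  ra <- data.table::as.data.table(read_assignments)
  ra <- ra[!gene_id %in% c("MULTIMAP", "UNASSIGNED")]
  n <- nrow(ra)
  set.seed(stage_seed(seed, "saturation"))
  perm <- sample.int(n)  # one permutation => nested subsamples
  per_cell <- list()
  out <- data.table::data.table(fraction = fractions,
                                median_umis = NA_real_,
                                median_genes = NA_real_)
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    sub <- ra[perm[seq_len(floor(f * n))]]
    per_umi <- sub[, .(n_reads = .N), by = .(cell_barcode, gene_id, umi)]
    counts <- per_umi[, .(n = collapse_umis(umi, n_reads)),
                      by = .(cell_barcode, gene_id)]
    stats_ <- counts[, .(umis = sum(n), genes = sum(n > 0)),
                     by = cell_barcode]
    cells <- data.table::data.table(cell_barcode = fixed_barcodes)
    cells <- merge(cells, stats_, by = "cell_barcode", all.x = TRUE)
    cells[is.na(umis), `:=`(umis = 0L, genes = 0L)]
    per_cell[[i]] <- cells
    out[i, `:=`(median_umis = stats::median(cells$umis),
                median_genes = stats::median(cells$genes))]
  }
  structure(out[], class = c("saturation_curve", class(out)),
            per_cell = per_cell)
}

cp10k_log1p <- function(mat) {
  depth <- Matrix::colSums(mat)
  depth[depth == 0] <- 1
  log1p(sweep(as.matrix(mat), 2L, depth, "/") * 1e4)
}

#' Correlation-based label transfer from a reference atlas
#'
#' Transfers cell-type labels from an annotated reference expression
#' matrix to a query matrix: both are depth-normalized (counts per 10,000,
#' log1p), features are the `n_features` most variable genes of the
#' reference intersected with the query's genes, and each query cell's
#' Pearson correlation is computed against every reference cell and every
#' other query cell. Its reference score is the mean of its top-`k`
#' reference correlations, its self score the mean of its top-`k`
#' correlations to other query cells, and its label the majority label of
#' the top-`k` reference neighbors. A cell is assigned when
#' `reference_score - self_score > margin`.
#'
#' @param query_matrix,ref_matrix genes x cells count matrices with gene
#'   ids as rownames.
#' @param ref_labels labels parallel to `colnames(ref_matrix)`.
#' @param k neighborhood size for the top-correlation means (default 20).
#' @param margin assignment threshold on `reference_score - self_score`
#'   (default 0, i.e. the reference must correlate strictly better).
#' @param n_features number of reference high-variance genes (default
#'   2000, capped at the shared gene count).
#' @return data.table with one row per query cell: `query_barcode`,
#'   `label`, `reference_score`, `self_score`, `assigned`.
#' @export
label_transfer <- function(query_matrix, ref_matrix, ref_labels, k = 20L,
                           margin = 0, n_features = 2000L) {
  stopifnot(k >= 1L, length(ref_labels) == ncol(ref_matrix))
  shared <- intersect(rownames(ref_matrix), rownames(query_matrix))
  if (length(shared) == 0L) stop("query and reference share no features")
  rn <- cp10k_log1p(ref_matrix[shared, , drop = FALSE])
  qn <- cp10k_log1p(query_matrix[shared, , drop = FALSE])
  v <- apply(rn, 1L, stats::var)
  feats <- names(sort(v, decreasing = TRUE))[seq_len(min(n_features,
                                                         length(v)))]
  rn <- rn[feats, , drop = FALSE]
  qn <- qn[feats, , drop = FALSE]
  cr <- stats::cor(qn, rn)              # query x reference
  cq <- stats::cor(qn)                  # query x query
  diag(cq) <- NA                        # exclude self-correlation
  kq <- min(k, ncol(rn))
  ks <- min(k, ncol(qn) - 1L)
  res <- lapply(seq_len(ncol(qn)), function(i) {
    ord <- order(cr[i, ], decreasing = TRUE)[seq_len(kq)]
    ref_score <- mean(cr[i, ord])
    labs <- ref_labels[ord]
    lab <- names(sort(table(labs), decreasing = TRUE))[1]
    self_score <- if (ks >= 1L)
      mean(sort(cq[i, ], decreasing = TRUE)[seq_len(ks)]) else -1
    data.table::data.table(query_barcode = colnames(qn)[i], label = lab,
                           reference_score = ref_score,
                           self_score = self_score,
                           assigned = ref_score - self_score > margin)
  })
  data.table::rbindlist(res)
}
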