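#' Build a unique-k-mer gene index over both species' references
#'
#' Indexes every k-mer that occurs in exactly one gene across the two
#' concatenated transcript sets; k-mers shared between genes (within or
#' between species) are discarded. This is the package's simplified,
#' transcript-level stand-in for splice-aware genome alignment: reads are
#' later assigned to the single gene whose unique k-mers they carry.
#'
#' @param refs list of `species_reference` objects.
#' @param k odd k-mer length in \[15, 63\] (default 31); must not exceed
#'   the shortest transcript.
#' @return a `kmer_index` object: list with `k`, `kmers`, `gene_of_kmer`
#'   (integer, parallel to `kmers`), `gene_ids`, `species_of_gene`.
#' @export
build_index <- function(refs, k = 31L) {
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 15L || k > 63L)
    stop("k must be odd and within [15, 63]")
  seqs <- do.call(c, unname(lapply(refs, `[[`, "sequences")))
  if (k > min(nchar(seqs)))
    stop("k exceeds the shortest transcript length")
  species <- unlist(lapply(refs, function(r)
    rep(r$species_id, length(r$gene_ids))))
  idx <- unique_kmer_index(unname(seqs), k)
  structure(list(k = k, kmers = idx$kmer, gene_of_kmer = idx$gene,
                 gene_ids = names(seqs), species_of_gene = unname(species)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("Unique-", x$k, "-mer index: ", length(x$kmers), " k-mers over ",
      length(x$gene_ids), " genes\n", sep = "")
  invisible(x)
}

#' Assign cDNA reads to genes by unique k-mer vote
#'
#' Scans every k-mer of each read against the index. Exactly one gene hit
#' assigns the read to that gene; hits to two or more distinct genes mark
#' it a multimapper (dropped downstream); no hits leave it unassigned.
#'
#' @param cdna_seq character vector of cDNA sequences.
#' @param index a `kmer_index` from [build_index()].
#' @return character vector of gene ids, with `"MULTIMAP"` and
#'   `"UNASSIGNED"` sentinels.
#' @export
assign_reads <- function(cdna_seq, index) {
  code <- assign_reads_kmer(cdna_seq, index$kmers, index$gene_of_kmer,
                            index$k)
  out <- rep("UNASSIGNED", length(code))
  out[code == -1L] <- "MULTIMAP"
  hit <- code > 0L
  out[hit] <- index$gene_ids[code[hit]]
  out
}

#' @rdname assign_reads
#' @export
assign_read <- function(cdna_seq, index) {
  stopifnot(length(cdna_seq) == 1L)
  assign_reads(cdna_seq, index)
}

#' Collapse a UMI multiset at edit distance 1
#'
#' Deduplicates the UMIs observed for one (gene, cell-barcode) pair the
#' way digital-expression tools do at `EDIT_DISTANCE=1`: UMIs are
#' processed in order of descending read count (ties lexicographic); a
#' UMI within hamming distance <= 1 of an already accepted UMI is absorbed
#' into it, otherwise it founds a new molecule. An alternative
#' connected-components rule (one molecule per distance-<=1 component) is
#' available for sensitivity analysis.
#'
#' @param umis character vector of equal-length, N-free UMIs.
#' @param counts read counts parallel to `umis` (default all 1).
#' @param max_dist absorption radius (default 1).
#' @param method `"greedy"` (default) or `"components"`.
#' @return the number of accepted molecules (integer).
#' @export
collapse_umis <- function(umis, counts = rep(1L, length(umis)),
                          max_dist = 1L, method = c("greedy", "components")) {
  method <- match.arg(method)
  if (length(umis) == 0L) return(0L)
  if (length(unique(nchar(umis))) != 1L)
    stop("UMIs of mixed lengths cannot be collapsed")
  o <- order(-counts, umis)
  umis <- umis[o]
  if (method == "greedy")
    return(collapse_umis_sorted(umis, as.integer(max_dist)))
  # connected components under the distance-<= max_dist relation
  n <- length(umis)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (sum(utf8ToInt(umis[i]) != utf8ToInt(umis[j])) <= max_dist) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Build per-species digital expression matrices
#'
#' Aggregates assigned reads into genes x cell-barcodes UMI counts, one
#' sparse matrix per species (the species of a read is the species of its
#' assigned gene). Within each (gene, barcode) the UMI multiset is
#' collapsed with [collapse_umis()]. Barcodes detecting fewer than
#' `creation_min_genes` genes are dropped from the matrix — the
#' matrix-creation floor (default 100), distinct from the later
#' cell-calling threshold. Gene and barcode orderings are lexicographic,
#' so the result is invariant to read order.
#'
#' @param assigned data.table with columns `cell_barcode`, `umi`,
#'   `gene_id` (sentinel gene ids `"MULTIMAP"`/`"UNASSIGNED"` are
#'   ignored).
#' @param index the `kmer_index` used for assignment (provides the
#'   gene-to-species map).
#' @param creation_min_genes minimum detected genes per retained barcode
#'   (default 100).
#' @param umi_method collapse rule, see [collapse_umis()].
#' @return named list of sparse dgCMatrix, one per species.
#' @export
build_matrix <- function(assigned, index, creation_min_genes = 100L,
                         umi_method = "greedy") {
  sp_of_gene <- stats::setNames(index$species_of_gene, index$gene_ids)
  assigned <- data.table::as.data.table(assigned)
  assigned <- assigned[gene_id %in% index$gene_ids]
  if (nrow(assigned) == 0L) {
    warning("no assigned reads; returning empty matrices")
    return(stats::setNames(
      lapply(unique(index$species_of_gene), function(sp)
        Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(0L, 0L))),
      unique(index$species_of_gene)))
  }
  # reads -> (barcode, gene, umi, n_reads) -> collapsed molecule counts
  per_umi <- assigned[, .(n_reads = .N), by = .(cell_barcode, gene_id, umi)]
  counts <- per_umi[, .(n = collapse_umis(umi, n_reads, method = umi_method)),
                    by = .(cell_barcode, gene_id)]
  counts[, species := sp_of_gene[gene_id]]
  out <- list()
  for (sp in sort(unique(index$species_of_gene))) {
    cs <- counts[species == sp]
    genes <- sort(index$gene_ids[index$species_of_gene == sp])
    if (nrow(cs) == 0L) {
      out[[sp]] <- Matrix::sparseMatrix(
        i = integer(0), j = integer(0), x = numeric(0),
        dims = c(length(genes), 0L), dimnames = list(genes, character(0)))
      next
    }
    bcs <- sort(unique(cs$cell_barcode))
    m <- Matrix::sparseMatrix(
      i = match(cs$gene_id, genes), j = match(cs$cell_barcode, bcs),
      x = cs$n, dims = c(length(genes), length(bcs)),
      dimnames = list(genes, bcs))
    keep <- Matrix::colSums(m > 0) >= creation_min_genes
    out[[sp]] <- m[, keep, drop = FALSE]
  }
  out
}
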