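# Independent reference implementations used as oracles. These are kept
# deliberately naive and separate from the package's code paths.

naive_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# brute-force scan of the whole whitelist
naive_correct <- function(raw, whitelist, max_h = 1L) {
  d <- vapply(whitelist, function(w) naive_hamming(raw, w), integer(1))
  if (any(d == 0L)) return(which(d == 0L)[1])
  hits <- which(d <= max_h)
  if (length(hits) == 0L) return(0L)
  if (length(hits) > 1L) return(-1L)
  hits
}

# greedy count-descending absorption, written independently of the
# package's sorted-C++ version
naive_collapse <- function(umis, counts) {
  o <- order(-counts, umis)
  accepted <- character(0)
  for (u in umis[o]) {
    near <- FALSE
    for (a in accepted) {
      if (naive_hamming(u, a) <= 1L) { near <- TRUE; break }
    }
    if (!near) accepted <- c(accepted, u)
  }
  length(accepted)
}

# molecule census from the simulator's per-read truth: distinct UMIs per
# (cell barcode, gene) after applying the naive dedup rule
naive_truth_census <- function(truth_reads) {
  tr <- data.table::as.data.table(truth_reads)
  per_umi <- tr[, .(n_reads = .N), by = .(cell_barcode, gene_id, umi)]
  per_umi[, .(n = naive_collapse(umi, n_reads)),
          by = .(cell_barcode, gene_id)]
}

# substring-scan gene assigner: a gene "hits" a read if any k-mer of the
# read occurs in the gene's sequence
naive_assign <- function(read, refs, k = 31L) {
  if (nchar(read) < k) return("UNASSIGNED")
  kmers <- unique(substring(read, 1:(nchar(read) - k + 1), k:nchar(read)))
  hits <- character(0)
  for (r in refs) {
    for (g in r$gene_ids) {
      if (any(vapply(kmers, function(km)
        grepl(km, r$sequences[[g]], fixed = TRUE), logical(1))))
        hits <- c(hits, g)
    }
  }
  if (length(hits) == 0L) return("UNASSIGNED")
  if (length(hits) > 1L) return("MULTIMAP")
  hits
}

random_umis <- function(n, len = 10L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
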