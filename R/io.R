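#' Write a FASTQ file (gzipped if the path ends in .gz)
#'
#' @param ids,seqs,quals parallel character vectors.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  q <- Biostrings::BStringSet(quals)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a data.table
#' @param path FASTQ path (gz accepted).
#' @return data.table with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.table::data.table(
    read_id = sub(" .*", "", names(x)),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write paired simulated reads plus ground truth to a directory
#'
#' Emits `reads_R1.fastq.gz` / `reads_R2.fastq.gz`, `truth_cells.tsv`,
#' `truth_reads.tsv`, the whitelist files, and a YAML echo of the
#' configuration.
#'
#' @param sim output of [generate_reads()].
#' @param truth the `truth_table` the reads were generated from.
#' @param whitelists the whitelists used.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_simulation <- function(sim, truth, whitelists, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fastq(sim$reads$read_id, sim$reads$seq1, sim$reads$qual1,
              file.path(dir, "reads_R1.fastq.gz"))
  write_fastq(sim$reads$read_id, sim$reads$seq2, sim$reads$qual2,
              file.path(dir, "reads_R2.fastq.gz"))
  data.table::fwrite(truth$cells, file.path(dir, "truth_cells.tsv"), sep = "\t")
  data.table::fwrite(sim$truth_reads, file.path(dir, "truth_reads.tsv"),
                     sep = "\t")
  write_whitelists(whitelists, dir)
  yaml::write_yaml(unclass(truth$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write a digital expression matrix as MatrixMarket + sidecars
#'
#' Writes `matrix.mtx`, `features.tsv` and `barcodes.tsv` under `dir`,
#' the conventional sparse exchange layout for gene-by-cell counts.
#'
#' @param mat a sparse genes-by-barcodes matrix (dimnames required).
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_matrix_mtx <- function(mat, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(mat, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(mat), file.path(dir, "features.tsv"))
  writeLines(colnames(mat), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a MatrixMarket digital expression matrix written by
#' [write_matrix_mtx()]
#' @param dir directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @return a sparse dgCMatrix with dimnames.
#' @export
read_matrix_mtx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  m
}
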