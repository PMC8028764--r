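#' Generate two synthetic species transcript references
#'
#' Builds one transcriptome per species with gene identifiers prefixed by
#' the species label (disjoint namespaces) and i.i.d. uniform random
#' nucleotide sequences. These stand in for per-species gene models in a
#' two-species mixing experiment: random sequences of a few hundred bases
#' are overwhelmingly species- and gene-specific at the k-mer level, which
#' is all the downstream unique-k-mer assigner requires.
#'
#' @param n_genes genes per species (>= 1).
#' @param length_range integer pair, inclusive range of transcript lengths
#'   in nt; must satisfy 200 <= min <= max <= 3000 by default convention
#'   (only min <= max and min >= 1 are enforced).
#' @param seed integer seed; output is a deterministic function of it.
#' @param species_ids labels for the two species, used as gene-id prefixes.
#' @return list of two `species_reference` objects, each a list with
#'   `species_id`, `gene_ids`, and `sequences` (named character vector).
#' @examples
#' refs <- make_references(n_genes = 5, length_range = c(200, 400), seed = 1)
#' names(refs[[1]]$sequences)[1:2]
#' @export
make_references <- function(n_genes, length_range = c(200L, 1000L), seed = 1L,
                            species_ids = c("smed", "djap")) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stop("n_genes must be a positive integer")
  if (length(length_range) != 2L || any(length_range < 1) ||
      length_range[1] > length_range[2])
    stop("length_range must be an increasing positive integer pair")
  stopifnot(length(species_ids) == 2L, species_ids[1] != species_ids[2])
  set.seed(seed)
  refs <- lapply(species_ids, function(sp) {
    len_pool <- seq.int(length_range[1], length_range[2])
    lens <- len_pool[sample.int(length(len_pool), n_genes, replace = TRUE)]
    seqs <- vapply(lens, function(L)
      paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""), character(1))
    gene_ids <- sprintf("%s_g%04d", sp, seq_len(n_genes))
    names(seqs) <- gene_ids
    structure(list(species_id = sp, gene_ids = gene_ids, sequences = seqs),
              class = "species_reference")
  })
  names(refs) <- species_ids
  refs
}

#' @export
print.species_reference <- function(x, ...) {
  cat("Species reference", x$species_id, "-", length(x$gene_ids), "genes,",
      "lengths", min(nchar(x$sequences)), "-", max(nchar(x$sequences)), "nt\n")
  invisible(x)
}

#' Write species references as FASTA
#' @param refs list of `species_reference` objects.
#' @param dir output directory.
#' @return invisibly, the FASTA paths.
#' @export
write_references <- function(refs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(refs, function(r) {
    p <- file.path(dir, paste0("ref_", r$species_id, ".fasta"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(r$sequences), p)
    p
  }, character(1))
  invisible(paths)
}

#' Read species references from FASTA files
#' @param paths named character vector of FASTA paths; names are species ids
#'   (defaults to stripping a `ref_` prefix from the file name).
#' @return list of `species_reference` objects.
#' @export
read_references <- function(paths) {
  if (is.null(names(paths)))
    names(paths) <- sub("^ref_", "", sub("\\.fasta$", "", basename(paths)))
  refs <- lapply(names(paths), function(sp) {
    ss <- Biostrings::readDNAStringSet(paths[[sp]])
    seqs <- as.character(ss)
    structure(list(species_id = sp, gene_ids = names(seqs), sequences = seqs),
              class = "species_reference")
  })
  names(refs) <- names(paths)
  refs
}
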