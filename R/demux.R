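#' Extract the UMI and raw round barcodes from read 2
#'
#' Cuts the layout's 0-based half-open segment intervals out of each
#' sequence. Reads must span the layout (length >= `min_span`); shorter
#' reads should have been removed by [trim_and_filter()].
#'
#' @param read2_seq character vector of read-2 sequences.
#' @param layout a [barcode_layout()].
#' @return data.table with columns `umi`, `raw_bc1`, `raw_bc2`, `raw_bc3`.
#' @export
extract_segments <- function(read2_seq, layout) {
  if (any(nchar(read2_seq) < layout$min_span))
    stop("reads shorter than the layout span cannot be demultiplexed")
  seg <- function(kind) {
    s <- layout_segment(layout, kind)
    substr(read2_seq, s$offset + 1L, s$offset + s$length)
  }
  data.table::data.table(umi = seg("UMI"), raw_bc1 = seg("BC1"),
                         raw_bc2 = seg("BC2"), raw_bc3 = seg("BC3"))
}

# Lookup table mapping every sequence within hamming distance max_hamming
# of a whitelist entry to that entry's index; strings reachable from two or
# more entries map to -1 (ambiguous). Exact entries always win over being
# a neighbor of another entry. N counts as a mismatch, so single-N
# barcodes remain correctable.
build_correction_table <- function(whitelist, max_hamming = 1L) {
  n <- length(whitelist)
  bc_len <- nchar(whitelist[1])
  tab <- new.env(parent = emptyenv(), size = n * (1L + 4L * bc_len))
  if (max_hamming >= 1L) {
    alphabet <- c(DNA_BASES, "N")
    for (i in seq_len(n)) {
      ch <- strsplit(whitelist[i], "", fixed = TRUE)[[1]]
      for (p in seq_len(bc_len)) {
        for (b in alphabet[alphabet != ch[p]]) {
          mut <- ch; mut[p] <- b
          key <- paste(mut, collapse = "")
          prev <- tab[[key]]
          tab[[key]] <- if (is.null(prev) || prev == i) i else -1L
        }
      }
    }
  }
  for (i in seq_len(n)) tab[[whitelist[i]]] <- i  # exact wins
  tab
}

#' Vectorized barcode correction
#'
#' Batch form of [correct_barcode()] using a precomputed radius-1
#' neighborhood lookup table.
#'
#' @param raws character vector of raw barcodes (whitelist length).
#' @param whitelist character vector of legal barcodes.
#' @param max_hamming correction radius (default 1).
#' @param table optional precomputed lookup table (internal reuse).
#' @return integer vector: positive whitelist index, 0 = NO_MATCH,
#'   -1 = AMBIGUOUS.
#' @export
correct_barcodes <- function(raws, whitelist, max_hamming = 1L,
                             table = NULL) {
  bc_len <- nchar(whitelist[1])
  if (any(nchar(raws) != bc_len))
    stop("raw barcode length differs from whitelist length ", bc_len)
  if (is.null(table)) table <- build_correction_table(whitelist, max_hamming)
  out <- integer(length(raws))
  uraw <- unique(raws)
  ures <- vapply(uraw, function(r) {
    v <- table[[r]]
    if (is.null(v)) 0L else v
  }, integer(1))
  out <- ures[match(raws, uraw)]
  names(out) <- NULL
  out
}

#' Error-correct one raw barcode against a whitelist
#'
#' Exact matches win immediately; otherwise the unique whitelist entry at
#' hamming distance <= `max_hamming` is returned. Two or more entries
#' within range is `AMBIGUOUS` (such reads are dropped downstream, never
#' arbitrarily assigned); none is `NO_MATCH`. N counts as a mismatch.
#'
#' @param raw a single barcode string of the whitelist's length.
#' @param whitelist character vector of legal barcodes.
#' @param max_hamming correction radius (default 1).
#' @return list with `index` (whitelist index or NA), `status` (one of
#'   `"MATCH"`, `"CORRECTED"`, `"NO_MATCH"`, `"AMBIGUOUS"`), and
#'   `corrected` (logical).
#' @export
correct_barcode <- function(raw, whitelist, max_hamming = 1L) {
  stopifnot(length(raw) == 1L)
  code <- correct_barcodes(raw, whitelist, max_hamming)
  if (code > 0L) {
    list(index = code,
         status = if (raw == whitelist[code]) "MATCH" else "CORRECTED",
         corrected = raw != whitelist[code])
  } else {
    list(index = NA_integer_,
         status = if (code == 0L) "NO_MATCH" else "AMBIGUOUS",
         corrected = FALSE)
  }
}

empty_demux_report <- function() {
  structure(list(n_input = 0L, n_tagged = 0L, n_fail_no_match = 0L,
                 n_fail_ambiguous = 0L, n_fail_umi_n = 0L,
                 per_round_correction_counts = c(round1 = 0L, round2 = 0L,
                                                 round3 = 0L)),
            class = "demux_report")
}

#' @export
print.demux_report <- function(x, ...) {
  cat("Demultiplexing report\n")
  cat(sprintf("  input %d, tagged %d, no-match %d, ambiguous %d, N-UMI %d\n",
              x$n_input, x$n_tagged, x$n_fail_no_match, x$n_fail_ambiguous,
              x$n_fail_umi_n))
  cat("  corrections per round:",
      paste(x$per_round_correction_counts, collapse = " / "), "\n")
  invisible(x)
}

#' Tag reads with corrected cell barcodes and UMIs
#'
#' Extracts the UMI and three round barcodes from read 2, corrects each
#' round against its whitelist (hamming distance <= 1), and emits only
#' reads with all three rounds resolved and an N-free UMI. The composite
#' cell barcode is `bc1 || bc2 || bc3 || sublib_char` (corrected whitelist
#' sequences, round order, with the sub-library character appended so
#' identical well combinations from different sub-libraries stay
#' distinct). One sub-library is processed per call, mirroring the
#' separate processing of PCR-indexed sub-library files.
#'
#' @param pairs data.table with `read_id`, `seq1` (cDNA) and `seq2`
#'   columns (post-filter).
#' @param layout a [barcode_layout()].
#' @param whitelists a `splitpool_whitelists`.
#' @param sublib_char the sub-library tag of this file; must be one of
#'   `whitelists$sublib_tags`.
#' @param max_hamming correction radius (default 1).
#' @return list with `tagged` (data.table: read_id, cdna_seq, umi,
#'   cell_barcode, corrected1..3) and `report` (a `demux_report`).
#' @export
tag_reads <- function(pairs, layout, whitelists, sublib_char,
                      max_hamming = 1L) {
  if (!sublib_char %in% whitelists$sublib_tags)
    stop("sublib_char must be one of the whitelist sub-library tags")
  rep_ <- empty_demux_report()
  rep_$n_input <- nrow(pairs)
  if (nrow(pairs) == 0L)
    return(list(tagged = data.table::data.table(), report = rep_))
  segs <- extract_segments(pairs$seq2, layout)
  codes <- list(
    correct_barcodes(segs$raw_bc1, whitelists$round1, max_hamming),
    correct_barcodes(segs$raw_bc2, whitelists$round2, max_hamming),
    correct_barcodes(segs$raw_bc3, whitelists$round3, max_hamming))
  any_no_match <- codes[[1]] == 0L | codes[[2]] == 0L | codes[[3]] == 0L
  any_ambig <- !any_no_match &
    (codes[[1]] < 0L | codes[[2]] < 0L | codes[[3]] < 0L)
  umi_n <- !any_no_match & !any_ambig & grepl("N", segs$umi, fixed = TRUE)
  keep <- !(any_no_match | any_ambig | umi_n)

  rep_$n_fail_no_match <- sum(any_no_match)
  rep_$n_fail_ambiguous <- sum(any_ambig)
  rep_$n_fail_umi_n <- sum(umi_n)
  rep_$n_tagged <- sum(keep)
  wl_seq <- list(whitelists$round1, whitelists$round2, whitelists$round3)
  raw <- list(segs$raw_bc1, segs$raw_bc2, segs$raw_bc3)
  corrected <- lapply(1:3, function(r)
    keep & raw[[r]] != wl_seq[[r]][pmax(codes[[r]], 1L)])
  rep_$per_round_correction_counts <- stats::setNames(
    vapply(corrected, sum, integer(1)), c("round1", "round2", "round3"))

  tagged <- data.table::data.table(
    read_id = pairs$read_id[keep],
    cdna_seq = pairs$seq1[keep],
    umi = segs$umi[keep],
    cell_barcode = paste0(wl_seq[[1]][codes[[1]][keep]],
                          wl_seq[[2]][codes[[2]][keep]],
                          wl_seq[[3]][codes[[3]][keep]],
                          sublib_char),
    corrected1 = corrected[[1]][keep],
    corrected2 = corrected[[2]][keep],
    corrected3 = corrected[[3]][keep])
  list(tagged = tagged, report = rep_)
}
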