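#' @useDynLib splitpool, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Fixed linker filler sequences between ligation barcodes in read 2.
# Arbitrary 30-nt strings; real plate oligos are configurable via
# barcode_layout(linkers = ...).
DEFAULT_LINKER1 <- "GTGGCCGATGTTTCGCATCGGCGTACGACT"
DEFAULT_LINKER2 <- "ATCCACGTGCTTGAGACTGTGGCCTTGGAG"

#' Positional layout of read 2
#'
#' Describes where the UMI, the three round barcodes and the fixed linker
#' sequences sit inside read 2 of a split-pool library. All coordinates are
#' 0-based, half-open. The default layout places the last barcode so that
#' its final base is at offset 94, the minimum read-2 length needed to span
#' all barcodes; reads shorter than `min_span` cannot be demultiplexed.
#'
#' @param umi_len UMI length in nt (default 10).
#' @param bc_len barcode length in nt per round (default 8).
#' @param linkers character vector of two fixed linker sequences placed
#'   between the barcode segments.
#' @return An object of class `splitpool_layout`: a list with `umi_len`,
#'   `bc_len`, `segments` (a data.frame of kind/offset/length, sorted by
#'   offset), `linkers`, and `min_span` (offset+length of the last
#'   non-linker segment).
#' @examples
#' lay <- barcode_layout()
#' lay$min_span  # 94
#' @export
barcode_layout <- function(umi_len = 10L, bc_len = 8L,
                           linkers = c(DEFAULT_LINKER1, DEFAULT_LINKER2)) {
  stopifnot(umi_len >= 1L, bc_len >= 1L, length(linkers) == 2L)
  l1 <- nchar(linkers[1]); l2 <- nchar(linkers[2])
  off_umi <- 0L
  off_bc3 <- umi_len
  off_l1  <- off_bc3 + bc_len
  off_bc2 <- off_l1 + l1
  off_l2  <- off_bc2 + bc_len
  off_bc1 <- off_l2 + l2
  segments <- data.frame(
    kind   = c("UMI", "BC3", "LINKER", "BC2", "LINKER", "BC1"),
    offset = as.integer(c(off_umi, off_bc3, off_l1, off_bc2, off_l2, off_bc1)),
    length = as.integer(c(umi_len, bc_len, l1, bc_len, l2, bc_len)),
    linker_id = c(NA, NA, 1L, NA, 2L, NA),
    stringsAsFactors = FALSE
  )
  validate_layout_segments(segments)
  non_linker <- segments[segments$kind != "LINKER", ]
  min_span <- max(non_linker$offset + non_linker$length)
  structure(
    list(umi_len = as.integer(umi_len), bc_len = as.integer(bc_len),
         segments = segments, linkers = toupper(linkers),
         min_span = as.integer(min_span)),
    class = "splitpool_layout"
  )
}

validate_layout_segments <- function(segments) {
  o <- order(segments$offset)
  s <- segments[o, ]
  ends <- s$offset + s$length
  if (any(s$offset[-1] < ends[-nrow(s)]))
    stop("layout segments overlap")
  invisible(TRUE)
}

layout_segment <- function(layout, kind) {
  seg <- layout$segments[layout$segments$kind == kind, , drop = FALSE]
  if (nrow(seg) == 0L) stop("layout has no segment of kind ", kind)
  seg
}

#' @export
print.splitpool_layout <- function(x, ...) {
  cat("Read-2 layout: UMI", x$umi_len, "nt, barcodes", x$bc_len,
      "nt, min span", x$min_span, "nt\n")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Generate barcode whitelists for the three split-pool rounds
#'
#' Draws 48 + 96 + 96 random barcodes (one set per round) such that within
#' each round every pair of barcodes is at hamming distance >= `min_dist`.
#' With `min_dist = 3` a single substitution can always be corrected to a
#' unique whitelist entry; this is a simulator idealization (real plates
#' carry no such guarantee) and can be relaxed with `min_dist = 1`.
#'
#' @param seed integer seed; the whitelists are a deterministic function of
#'   it.
#' @param sizes integer vector of round sizes, default `c(48, 96, 96)`.
#' @param bc_len barcode length, default 8.
#' @param min_dist minimum within-round pairwise hamming distance, default 3.
#' @param sublib_tags single characters distinguishing PCR sub-libraries,
#'   default `c("A","T","C")`; appended to the cell barcode at demux.
#' @return An object of class `splitpool_whitelists`: list with `round1`,
#'   `round2`, `round3` (character vectors), `sublib_tags`, `bc_len`, and
#'   `n_combinations` = prod(sizes) * length(sublib_tags).
#' @examples
#' wl <- generate_whitelists(seed = 1)
#' wl$n_combinations  # 1327104
#' @export
generate_whitelists <- function(seed, sizes = c(48L, 96L, 96L), bc_len = 8L,
                                min_dist = 3L, sublib_tags = c("A", "T", "C")) {
  stopifnot(length(sizes) == 3L, all(sizes >= 1L),
            all(nchar(sublib_tags) == 1L), !anyDuplicated(sublib_tags))
  set.seed(seed)
  rounds <- lapply(sizes, function(n) sample_code(n, bc_len, min_dist))
  wl <- structure(
    list(round1 = rounds[[1]], round2 = rounds[[2]], round3 = rounds[[3]],
         sublib_tags = sublib_tags, bc_len = as.integer(bc_len),
         n_combinations = prod(sizes) * length(sublib_tags)),
    class = "splitpool_whitelists"
  )
  validate_whitelists(wl, min_dist = min_dist)
  wl
}

sample_code <- function(n, bc_len, min_dist) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    cand <- paste(sample(DNA_BASES, bc_len, replace = TRUE), collapse = "")
    if (length(out) == 0L || all(hamming_to(cand, out) >= min_dist)) {
      out <- c(out, cand)
    }
    tries <- tries + 1L
    if (tries > 200000L) stop("whitelist rejection sampling did not converge; ",
                              "lower min_dist or sizes")
  }
  out
}

# hamming distance from one string to each of a vector of equal-length strings
hamming_to <- function(x, ys) {
  xm <- strsplit(x, "", fixed = TRUE)[[1]]
  vapply(strsplit(ys, "", fixed = TRUE),
         function(y) sum(xm != y), integer(1))
}

validate_whitelists <- function(wl, min_dist = 1L) {
  for (r in 1:3) {
    seqs <- wl[[paste0("round", r)]]
    if (anyDuplicated(seqs)) stop("duplicate barcode in round ", r)
    if (any(nchar(seqs) != wl$bc_len)) stop("barcode length mismatch in round ", r)
    if (min_dist > 1L) {
      for (i in seq_along(seqs)[-1]) {
        if (any(hamming_to(seqs[i], seqs[seq_len(i - 1L)]) < min_dist))
          stop("round ", r, " violates min pairwise distance ", min_dist)
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.splitpool_whitelists <- function(x, ...) {
  cat("Split-pool whitelists:",
      length(x$round1), "x", length(x$round2), "x", length(x$round3),
      "barcodes x", length(x$sublib_tags), "sub-libraries =",
      format(x$n_combinations, big.mark = ","), "combinations\n")
  invisible(x)
}

#' Write whitelists to a directory (one sequence per line per round)
#' @param wl a `splitpool_whitelists` object.
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_whitelists <- function(wl, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("bc_round1.txt", "bc_round2.txt", "bc_round3.txt",
                            "sublib_tags.txt"))
  writeLines(wl$round1, paths[1])
  writeLines(wl$round2, paths[2])
  writeLines(wl$round3, paths[3])
  writeLines(wl$sublib_tags, paths[4])
  invisible(paths)
}

#' Read whitelists from a directory written by [write_whitelists()]
#' @param dir directory containing `bc_round[123].txt` and `sublib_tags.txt`.
#' @return a `splitpool_whitelists` object.
#' @export
read_whitelists <- function(dir) {
  r1 <- readLines(file.path(dir, "bc_round1.txt"))
  r2 <- readLines(file.path(dir, "bc_round2.txt"))
  r3 <- readLines(file.path(dir, "bc_round3.txt"))
  tg <- readLines(file.path(dir, "sublib_tags.txt"))
  wl <- structure(
    list(round1 = r1, round2 = r2, round3 = r3, sublib_tags = tg,
         bc_len = nchar(r1[1]),
         n_combinations = length(r1) * length(r2) * length(r3) * length(tg)),
    class = "splitpool_whitelists"
  )
  validate_whitelists(wl)
  wl
}
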