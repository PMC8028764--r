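phred_scores <- function(quals) lapply(quals, function(q) utf8ToInt(q) - 33L)

# length of the maximal 3' run of bases with quality < cutoff
trailing_lowq_run <- function(quals, cutoff) {
  vapply(quals, function(q) {
    s <- utf8ToInt(q) - 33L
    n <- length(s)
    i <- n
    while (i >= 1L && s[i] < cutoff) i <- i - 1L
    n - i
  }, integer(1), USE.NAMES = FALSE)
}

# position (1-based) at which to cut a read carrying an adapter: exact
# occurrence anywhere, else a 3'-terminal suffix-prefix overlap of at least
# min_overlap nt. 0 = no adapter found. Vectorized over reads.
adapter_cut_pos <- function(seqs, adapter, min_overlap = 6L) {
  pos <- regexpr(adapter, seqs, fixed = TRUE)
  cut <- ifelse(pos > 0L, as.integer(pos), 0L)
  lens <- nchar(seqs)
  max_ov <- min(nchar(adapter) - 1L, max(lens, 0L))
  if (max_ov >= min_overlap) {
    for (ov in seq.int(max_ov, min_overlap)) {
      hit <- cut == 0L & lens >= ov & endsWith(seqs, substr(adapter, 1L, ov))
      cut[hit] <- lens[hit] - ov + 1L
    }
  }
  cut
}

empty_filter_report <- function() {
  structure(list(n_input = 0L, n_pass = 0L, n_fail_malformed = 0L,
                 n_fail_adapter = 0L, n_fail_short1 = 0L, n_fail_short2 = 0L,
                 n_fail_phase = 0L, n_fail_unpaired = 0L),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Read-pair filter report\n")
  for (f in names(x)) cat(sprintf("  %-18s %d\n", f, x[[f]]))
  invisible(x)
}

#' Quality, adapter, length and phase filtering of read pairs
#'
#' Reproduces the curation contract applied to raw split-pool libraries:
#' per mate, 3' quality trimming at `qual_cutoff`, stripping of terminal Ns
#' on read 2, adapter removal (exact occurrence anywhere, or a 3' terminal
#' suffix-prefix overlap of >= 6 nt), then a minimum-length requirement of
#' `min_len1` nt for the transcript mate and `min_len2` nt for the
#' UMI/barcode mate (94 nt is the minimum span of all barcodes under the
#' default layout). If `layout` is supplied, the barcode-phase check
#' ([check_phase()]) is applied last. Failure attribution is first-failure
#' in processing order (adapter-only reads, then short mate 1, short mate
#' 2, phase), so every input pair lands in exactly one report bucket.
#'
#' @param pairs data.table/data.frame with columns `read_id`, `seq1`,
#'   `qual1`, `seq2`, `qual2`.
#' @param min_len1,min_len2 minimum post-trim lengths (defaults 60 and 94).
#' @param adapter1,adapter2 adapter sequences for mates 1 and 2.
#' @param qual_cutoff Phred cutoff for 3' quality trimming (default 10).
#' @param layout optional [barcode_layout()]; if given, pairs failing the
#'   phase check are dropped and counted.
#' @param max_phase_mismatch substitutions tolerated per linker in the
#'   phase check.
#' @return list with `pairs` (the retained, trimmed pairs) and `report`
#'   (a `filter_report`).
#' @export
trim_and_filter <- function(pairs, min_len1 = 60L, min_len2 = 94L,
                            adapter1 = "AGATCGGAAGAG",
                            adapter2 = "CTGTCTCTTATA",
                            qual_cutoff = 10L, layout = NULL,
                            max_phase_mismatch = 1L) {
  stopifnot(nchar(adapter1) > 0L, nchar(adapter2) > 0L,
            grepl("^[ACGT]+$", adapter1), grepl("^[ACGT]+$", adapter2))
  pairs <- data.table::as.data.table(pairs)
  rep_ <- empty_filter_report()
  rep_$n_input <- nrow(pairs)
  if (nrow(pairs) == 0L) return(list(pairs = pairs, report = rep_))

  malformed <- nchar(pairs$seq1) != nchar(pairs$qual1) |
    nchar(pairs$seq2) != nchar(pairs$qual2)
  rep_$n_fail_malformed <- sum(malformed)
  pairs <- pairs[!malformed]

  # 3' quality trim per mate
  for (m in 1:2) {
    sq <- paste0("seq", m); qu <- paste0("qual", m)
    run <- trailing_lowq_run(pairs[[qu]], qual_cutoff)
    keep <- nchar(pairs[[sq]]) - run
    data.table::set(pairs, j = sq, value = substr(pairs[[sq]], 1L, keep))
    data.table::set(pairs, j = qu, value = substr(pairs[[qu]], 1L, keep))
  }

  # terminal Ns on read 2 (leading Ns shift phase and are caught there;
  # only the trailing side can be stripped without moving the barcodes)
  nlead <- attr(regexpr("^N*", pairs$seq2), "match.length")
  ntail <- attr(regexpr("N*$", pairs$seq2), "match.length")
  ntail[nchar(pairs$seq2) == 0L] <- 0L
  trimmed2 <- substr(pairs$seq2, 1L, nchar(pairs$seq2) - ntail)
  data.table::set(pairs, j = "seq2", value = trimmed2)
  data.table::set(pairs, j = "qual2",
                  value = substr(pairs$qual2, 1L, nchar(trimmed2)))

  # adapter trimming
  for (m in 1:2) {
    sq <- paste0("seq", m); qu <- paste0("qual", m)
    adp <- if (m == 1L) adapter1 else adapter2
    cut <- adapter_cut_pos(pairs[[sq]], adp)
    hit <- cut > 0L
    data.table::set(pairs, which(hit), sq,
                    substr(pairs[[sq]][hit], 1L, cut[hit] - 1L))
    data.table::set(pairs, which(hit), qu,
                    substr(pairs[[qu]][hit], 1L, cut[hit] - 1L))
  }

  # first-failure attribution: adapter-only, short1, short2, phase
  adapter_only <- nchar(pairs$seq1) == 0L | nchar(pairs$seq2) == 0L
  short1 <- !adapter_only & nchar(pairs$seq1) < min_len1
  short2 <- !adapter_only & !short1 & nchar(pairs$seq2) < min_len2
  rep_$n_fail_adapter <- sum(adapter_only)
  rep_$n_fail_short1 <- sum(short1)
  rep_$n_fail_short2 <- sum(short2)
  pairs <- pairs[!(adapter_only | short1 | short2)]

  if (!is.null(layout)) {
    ok <- check_phase(pairs$seq2, layout, max_mismatch = max_phase_mismatch)
    rep_$n_fail_phase <- sum(!ok)
    pairs <- pairs[ok]
  }

  rep_$n_pass <- nrow(pairs)
  list(pairs = pairs, report = rep_)
}

#' Barcode-phase check on read 2
#'
#' A read is "in phase" when every fixed linker segment of the layout sits
#' at its expected offset, i.e. matches its reference sequence there with
#' at most `max_mismatch` substitutions. Indels anywhere upstream shift
#' every later segment and fail the check; no rescue alignment is
#' attempted — out-of-phase reads are discarded.
#'
#' @param read2_seq character vector of read-2 sequences, each of length
#'   >= `layout$min_span`.
#' @param layout a [barcode_layout()].
#' @param max_mismatch substitutions tolerated per linker (default 1).
#' @return logical vector, TRUE for in-phase reads.
#' @export
check_phase <- function(read2_seq, layout, max_mismatch = 1L) {
  if (any(nchar(read2_seq) < layout$min_span))
    stop("check_phase requires reads of length >= layout$min_span; ",
         "short reads must be filtered upstream")
  segs <- layout$segments[layout$segments$kind == "LINKER", , drop = FALSE]
  ok <- rep(TRUE, length(read2_seq))
  for (i in seq_len(nrow(segs))) {
    ref <- layout$linkers[segs$linker_id[i]]
    if (nchar(ref) != segs$length[i])
      stop("layout/linker inconsistency: linker ", i, " length mismatch")
    off <- segs$offset[i]
    mm <- integer(length(read2_seq))
    for (p in seq_len(segs$length[i])) {
      mm <- mm + (substr(read2_seq, off + p, off + p) != substr(ref, p, p))
    }
    ok <- ok & (mm <= max_mismatch)
  }
  ok
}

#' Retain read ids present in both mates
#'
#' @param ids1,ids2 read-id vectors of the two mate files.
#' @return the intersection, in the order of `ids1`.
#' @export
retain_paired <- function(ids1, ids2) {
  ids1[ids1 %in% ids2]
}
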