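test_that("segment extraction matches a character-by-character oracle on a permuted layout", {
  e <- fx_clean()
  segs <- extract_segments(e$sim$reads$seq2[1:50], e$lay)
  for (i in 1:50) {
    s <- e$sim$reads$seq2[i]
    chars <- strsplit(s, "")[[1]]
    for (kind in c("UMI", "BC1", "BC2", "BC3")) {
      sg <- e$lay$segments[e$lay$segments$kind == kind, ]
      want <- paste(chars[(sg$offset + 1):(sg$offset + sg$length)],
                    collapse = "")
      got <- switch(kind, UMI = segs$umi[i], BC1 = segs$raw_bc1[i],
                    BC2 = segs$raw_bc2[i], BC3 = segs$raw_bc3[i])
      expect_identical(got, want)
    }
  }

  # a layout with permuted segment order extracts by kind, not position
  lay2 <- e$lay
  lay2$segments <- e$lay$segments[rev(seq_len(nrow(e$lay$segments))), ]
  segs2 <- extract_segments(e$sim$reads$seq2[1:50], lay2)
  expect_identical(segs2, segs)
  expect_error(extract_segments(strrep("A", 93), e$lay), "shorter")
})

test_that("barcode correction: exact wins, single errors correct, ties are ambiguous", {
  wl <- fx_whitelists()
  r <- correct_barcode(wl$round1[17], wl$round1)
  expect_equal(r$index, 17L)
  expect_false(r$corrected)

  raw <- wl$round1[17]
  substr(raw, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(raw, 3, 3))[1]
  r <- correct_barcode(raw, wl$round1)
  expect_equal(r$index, 17L)
  expect_true(r$corrected)

  # adversarial whitelist with min distance 1: two distance-1 hits
  r <- correct_barcode("AAAAAAAC", c("AAAAAAAA", "AAAAAAAT"))
  expect_equal(r$status, "AMBIGUOUS")
  expect_error(correct_barcodes("AAAA", wl$round1), "length")
})

test_that("correction agrees with a brute-force hamming scan on corrupted barcodes", {
  wl <- fx_whitelists()
  set.seed(21)
  n <- 3000L
  raws <- vapply(seq_len(n), function(i) {
    b <- sample(wl$round2, 1)
    n_mut <- sample(0:2, 1)
    ch <- strsplit(b, "")[[1]]
    for (p in sample(8, n_mut)) ch[p] <- sample(c("A", "C", "G", "T", "N"), 1)
    paste(ch, collapse = "")
  }, character(1))
  got <- correct_barcodes(raws, wl$round2)
  want <- vapply(raws, function(r) naive_correct(r, wl$round2), integer(1))
  expect_equal(unname(got), unname(want))
  # within-radius invariant: any returned index is within hamming 1
  hit <- got > 0
  d <- mapply(function(r, i) naive_hamming(r, wl$round2[i]),
              raws[hit], got[hit])
  expect_true(all(d <= 1))
})

test_that("any single substitution of a min-distance-3 whitelist corrects exactly", {
  wl <- fx_whitelists()
  set.seed(22)
  for (rep_ in 1:200) {
    i <- sample(length(wl$round3), 1)
    ch <- strsplit(wl$round3[i], "")[[1]]
    p <- sample(8, 1)
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    expect_equal(correct_barcodes(paste(ch, collapse = ""), wl$round3), i)
  }
})

test_that("tagging recovers all clean reads and keys sub-libraries apart", {
  e <- fx_clean()
  pairs <- e$sim$reads[sublib == "A", .(read_id, seq1, qual1, seq2, qual2)]
  outA <- tag_reads(pairs, e$lay, e$wl, "A")
  expect_equal(outA$report$n_tagged, outA$report$n_input)
  expect_equal(sum(outA$report$per_round_correction_counts), 0L)

  # conservation identity of the report
  rep_ <- outA$report
  expect_equal(rep_$n_input, rep_$n_tagged + rep_$n_fail_no_match +
                 rep_$n_fail_ambiguous + rep_$n_fail_umi_n)

  # same reads tagged under a different sub-library differ only in the
  # final barcode character, so merged streams never collide
  outT <- tag_reads(pairs, e$lay, e$wl, "T")
  bcA <- outA$tagged$cell_barcode; bcT <- outT$tagged$cell_barcode
  expect_identical(substr(bcA, 1, 24), substr(bcT, 1, 24))
  expect_true(all(substr(bcA, 25, 25) == "A"))
  expect_true(all(substr(bcT, 25, 25) == "T"))
  expect_length(intersect(bcA, bcT), 0L)

  # tagged barcodes equal the simulator's truth for this sub-library
  tru <- e$sim$truth_reads[match(outA$tagged$read_id, read_id)]
  expect_identical(outA$tagged$cell_barcode, tru$cell_barcode)
  expect_identical(outA$tagged$umi, tru$umi)
})

test_that("corrupted batches match a naive re-demultiplex and drop N-bearing UMIs", {
  e <- fx_clean()
  set.seed(23)
  pairs <- e$sim$reads[sublib == "C"][1:400,
    .(read_id, seq1, qual1, seq2, qual2)]
  # plant ~1 substitution per barcode region and a few N UMIs
  pairs[, seq2 := {
    s <- seq2
    for (i in seq_along(s)) {
      p <- sample(c(11:18, 49:56, 87:94), 1)  # inside a barcode segment
      substr(s[i], p, p) <- sample(c("A", "C", "G", "T", "N"), 1)
      if (i <= 20) substr(s[i], 1, 1) <- "N"  # N inside the UMI
    }
    s
  }]
  out <- tag_reads(pairs, e$lay, e$wl, "C")
  expect_equal(out$report$n_fail_umi_n, 20L)
  # oracle: naive per-read correction of all three rounds
  segs <- extract_segments(pairs$seq2, e$lay)
  ok <- vapply(seq_len(nrow(pairs)), function(i) {
    naive_correct(segs$raw_bc1[i], e$wl$round1) > 0 &&
      naive_correct(segs$raw_bc2[i], e$wl$round2) > 0 &&
      naive_correct(segs$raw_bc3[i], e$wl$round3) > 0 &&
      !grepl("N", segs$umi[i])
  }, logical(1))
  expect_equal(out$report$n_tagged, sum(ok))
  expect_setequal(out$tagged$read_id, pairs$read_id[ok])
})
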