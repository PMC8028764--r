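test_that("references respect the length range, are deterministic, and reject bad input", {
  refs <- make_references(1, c(200, 200), seed = 1)
  expect_length(refs, 2L)
  for (r in refs) {
    expect_length(r$sequences, 1L)
    expect_equal(nchar(r$sequences), 200L, ignore_attr = TRUE)
    expect_true(grepl("^[ACGT]+$", r$sequences))
  }
  expect_false(any(refs[[1]]$gene_ids %in% refs[[2]]$gene_ids))

  a <- make_references(100, c(200, 1000), seed = 7)
  b <- make_references(100, c(200, 1000), seed = 7)
  expect_identical(a, b)

  expect_error(make_references(0, c(200, 300)), "n_genes")
  expect_error(make_references(10, c(300, 200)), "length_range")
})

test_that("random references are k-mer distinguishable (brute-force census)", {
  refs <- make_references(25, c(200, 600), seed = 3)
  k <- 31L
  tab <- data.table::rbindlist(lapply(refs, function(r)
    data.table::rbindlist(lapply(r$gene_ids, function(g) {
      s <- r$sequences[[g]]
      data.table::data.table(
        kmer = unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s))),
        gene = g)
    }))))
  per_kmer <- tab[, .(n_genes = data.table::uniqueN(gene)), by = kmer]
  expect_gte(mean(per_kmer$n_genes == 1L), 0.99)
})

test_that("doublet bookkeeping: none at rate zero, half cross-species when balanced", {
  refs <- make_references(2, c(200, 200), seed = 2)
  cfg0 <- sim_config(n_cells_per_species = 500L,
                     per_round_retention = c(1, 1, 1),
                     doublet_rate = 0, seed = 4L)
  tr0 <- simulate_cells(refs, cfg0)
  expect_equal(sum(tr0$cells$is_doublet), 0L)

  cfg <- sim_config(n_cells_per_species = 5000L,
                    per_round_retention = c(1, 1, 1),
                    doublet_rate = 0.1, seed = 4L)
  tr <- simulate_cells(refs, cfg)
  dbl <- tr$cells[tr$cells$is_doublet == TRUE]
  frac_cross <- mean(grepl("\\+", dbl$species))
  # members are drawn uniformly: cross-species with prob 2*0.5*0.5 = 0.5
  expect_lt(abs(frac_cross - 0.5), 3 * sqrt(0.25 / nrow(dbl)))
  # realized doublet fraction among units equals the configured rate
  expect_lt(abs(mean(tr$cells$is_doublet) - 0.1), 0.005)
  expect_error(sim_config(doublet_rate = 0.6), "doublet_rate")
})

test_that("barcode collisions arise at the birthday-problem rate", {
  refs <- make_references(2, c(200, 200), seed = 2)
  cfg <- sim_config(n_cells_per_species = 10000L,
                    per_round_retention = c(1, 1, 1),
                    doublet_rate = 0, seed = 3L)
  tr <- simulate_cells(refs, cfg)
  n <- nrow(tr$cells)
  expect_equal(n, 20000L)
  shared <- duplicated(tr$cells$cell_barcode) |
    duplicated(tr$cells$cell_barcode, fromLast = TRUE)
  p <- 1 - (1 - 1 / 1327104) ^ (n - 1)
  expect_lt(abs(mean(shared) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("uncorrupted reads parse back to their truth barcodes and UMIs", {
  e <- fx_clean()
  segs <- extract_segments(e$sim$reads$seq2, e$lay)
  tru <- e$sim$truth_reads
  expect_identical(segs$umi, tru$umi)
  recomposed <- paste0(segs$raw_bc1, segs$raw_bc2, segs$raw_bc3,
                       e$sim$reads$sublib)
  expect_identical(recomposed, tru$cell_barcode)
})

test_that("read accounting and determinism hold", {
  e <- fx_clean()
  # every emitted read has exactly one truth row
  expect_identical(sort(e$sim$reads$read_id), sort(e$sim$truth_reads$read_id))
  n_ambient <- sum(e$sim$truth_reads$cell_id == "AMBIENT")
  expect_equal(nrow(e$sim$reads), sum(e$truth$members$n_umis) + n_ambient)

  # byte-identical FASTQ under an identical seed/config
  cfg <- sim_config(n_cells_per_species = 20L,
                    per_round_retention = c(1, 1, 1),
                    reads_per_cell_mean = 30, seed = 9L)
  run_once <- function() {
    tr <- simulate_cells(fx_refs(), cfg, fx_whitelists())
    generate_reads(tr, fx_refs(), fx_layout(), fx_whitelists(), cfg)
  }
  s1 <- run_once(); s2 <- run_once()
  expect_identical(s1$reads, s2$reads)
  p1 <- tempfile(fileext = ".fastq"); p2 <- tempfile(fileext = ".fastq")
  write_fastq(s1$reads$read_id, s1$reads$seq2, s1$reads$qual2, p1)
  write_fastq(s2$reads$read_id, s2$reads$seq2, s2$reads$qual2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("read-2 truncation hits the configured fraction", {
  cfg <- sim_config(n_cells_per_species = 60L,
                    per_round_retention = c(1, 1, 1),
                    reads_per_cell_mean = 60, error_rate = 0,
                    truncation_rate = 0.2, chimera_rate = 0, seed = 12L)
  tr <- simulate_cells(fx_refs(), cfg, fx_whitelists())
  sim <- generate_reads(tr, fx_refs(), fx_layout(), fx_whitelists(), cfg)
  n <- nrow(sim$reads)
  frac_short <- mean(nchar(sim$reads$seq2) < 94)
  expect_lt(abs(frac_short - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("simulated cell-type matrices separate types by construction", {
  sim <- simulate_cell_types(n_cells = 60, n_genes = 200, effect = 10,
                             seed = 2)
  expect_equal(dim(sim$counts), c(200L, 60L))
  expect_setequal(unique(sim$labels), c("type1", "type2"))
  # marker block of type 1 is elevated in type-1 cells
  m1 <- rowMeans(sim$counts[1:50, sim$labels == "type1", drop = FALSE])
  m2 <- rowMeans(sim$counts[1:50, sim$labels == "type2", drop = FALSE])
  expect_gt(mean(m1), 2 * mean(m2))
})
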