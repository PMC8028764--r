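test_that("index keeps only k-mers unique to one gene", {
  # identical single-gene references: every k-mer is shared
  seqs <- paste(rep("ACGT", 50), collapse = "")
  same <- list(
    structure(list(species_id = "a", gene_ids = "a_g1",
                   sequences = c(a_g1 = seqs)), class = "species_reference"),
    structure(list(species_id = "b", gene_ids = "b_g1",
                   sequences = c(b_g1 = seqs)), class = "species_reference"))
  expect_length(build_index(same)$kmers, 0L)

  # periodic gene vs a random gene: brute-force census oracle
  set.seed(5)
  other <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                 collapse = "")
  refs <- list(
    structure(list(species_id = "a", gene_ids = "a_g1",
                   sequences = c(a_g1 = seqs)), class = "species_reference"),
    structure(list(species_id = "b", gene_ids = "b_g1",
                   sequences = c(b_g1 = other)), class = "species_reference"))
  idx <- build_index(refs)
  census <- function(s) unique(substring(s, 1:(nchar(s) - 30), 31:nchar(s)))
  ka <- census(seqs); kb <- census(other)
  expect_setequal(idx$kmers, c(setdiff(ka, kb), setdiff(kb, ka)))
  expect_length(setdiff(ka, kb), 4L)  # period-4 sequence has 4 distinct 31-mers

  # disjoint random references index nearly everything
  refs2 <- make_references(20, c(200, 400), seed = 6)
  idx2 <- build_index(refs2)
  total <- sum(vapply(refs2, function(r)
    sum(nchar(r$sequences) - 30L), numeric(1)))
  expect_gte(length(idx2$kmers) / total, 0.99)

  expect_error(build_index(refs2, k = 30), "odd")
  short_refs <- make_references(5, c(40, 60), seed = 7)
  expect_error(build_index(short_refs, k = 63), "shortest transcript")
})

test_that("read assignment: clean reads map to their gene, chimeras multimap", {
  e <- fx_clean_quant()
  tru <- e$sim$truth_reads[match(e$tagged$read_id, read_id)]
  assigned <- e$tagged$gene_id
  ok <- assigned != "UNASSIGNED" & assigned != "MULTIMAP"
  expect_equal(mean(ok), 1)
  expect_identical(assigned[ok], tru$gene_id[ok])

  ga <- e$refs[[1]]$sequences[[1]]; gb <- e$refs[[2]]$sequences[[2]]
  chimera <- paste0(substr(ga, 1, 60), substr(gb, 1, 60))
  expect_equal(assign_read(chimera, e$idx), "MULTIMAP")
})

test_that("noisy assignment agrees with a substring-scan oracle", {
  refs <- make_references(6, c(200, 300), seed = 8)
  idx <- build_index(refs)
  set.seed(9)
  reads <- vapply(1:120, function(i) {
    r <- refs[[sample(2, 1)]]
    s <- r$sequences[[sample(length(r$gene_ids), 1)]]
    st <- sample(nchar(s) - 80, 1)
    frag <- substr(s, st, st + 79)
    ch <- strsplit(frag, "")[[1]]
    for (p in which(stats::runif(80) < 0.01))
      ch[p] <- sample(c("A", "C", "G", "T"), 1)
    paste(ch, collapse = "")
  }, character(1))
  got <- assign_reads(reads, idx)
  want <- vapply(reads, function(r) naive_assign(r, refs), character(1))
  agree <- mean(got == want)
  expect_gte(agree, 0.999)
})

test_that("UMI collapse follows the greedy rule and matches a naive oracle", {
  expect_equal(collapse_umis("AAAA"), 1L)
  expect_equal(collapse_umis(c("AAAA", "AAAT", "GGGG"), c(10L, 1L, 5L)), 2L)

  set.seed(10)
  for (i in 1:150) {
    n <- sample(2:25, 1)
    umis <- unique(random_umis(n, len = 5L))  # short UMIs force near pairs
    counts <- sample(1:20, length(umis), replace = TRUE)
    expect_equal(collapse_umis(umis, counts), naive_collapse(umis, counts))
  }
  expect_error(collapse_umis(c("AAAA", "AAAAA")), "mixed")

  # chain AAAA-AAAT-AATT: greedy keeps two molecules, components one
  expect_equal(collapse_umis(c("AAAA", "AAAT", "AATT"), c(10L, 2L, 1L)), 2L)
  expect_equal(collapse_umis(c("AAAA", "AAAT", "AATT"), c(10L, 2L, 1L),
                             method = "components"), 1L)
})

test_that("matrix creation thresholds, truth census and order invariance", {
  e <- fx_clean_quant()
  mats <- build_matrix(e$tagged, e$idx, creation_min_genes = 1L)
  census <- naive_truth_census(
    e$sim$truth_reads[read_id %in% e$passed_ids])
  expect_equal(sum(vapply(mats, sum, numeric(1))), sum(census$n))

  # a cell detecting 3 genes is dropped at the default creation floor
  small <- e$tagged[cell_barcode == e$tagged$cell_barcode[1]][
    gene_id %in% unique(gene_id)[1:3]]
  m_small <- suppressWarnings(build_matrix(small, e$idx,
                                           creation_min_genes = 100L))
  expect_equal(sum(vapply(m_small, ncol, integer(1))), 0L)

  # permuting read order leaves the matrix unchanged
  set.seed(11)
  perm <- e$tagged[sample(.N)]
  mats_perm <- build_matrix(perm, e$idx, creation_min_genes = 1L)
  for (sp in names(mats)) expect_equal(mats[[sp]], mats_perm[[sp]])

  # pipeline conservation: tagged reads = assigned + multimap + unassigned
  counts <- table(factor(e$tagged$gene_id %in% e$idx$gene_ids,
                         levels = c(TRUE, FALSE)))
  expect_equal(sum(counts), nrow(e$tagged))
})
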