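mk_mat <- function(counts, genes, bcs) {
  m <- Matrix::Matrix(counts, sparse = TRUE)
  dimnames(m) <- list(genes, bcs)
  m
}

test_that("collision calling is strictly greater-than the 10% threshold", {
  mA <- mk_mat(matrix(c(90, 89), 1), "gA", c("b1", "b2"))
  mB <- mk_mat(matrix(c(10, 11), 1), "gB", c("b1", "b2"))
  rec <- barnyard(mA, mB)
  expect_equal(rec$minority_fraction, c(0.10, 0.11))
  expect_equal(rec$is_collision, c(FALSE, TRUE))
  expect_error(barnyard(mA, mB, theta = 0.6), "theta")

  # label-swap invariance
  rec_sw <- barnyard(mB, mA)
  expect_equal(rec_sw$is_collision, rec$is_collision)
  expect_equal(rec_sw$minority_fraction, rec$minority_fraction)
})

test_that("filter ledger reproduces the published accounting", {
  l1 <- filter_ledger(19975L, 234L)
  expect_equal(l1$n_retained, 19741L)
  l2 <- filter_ledger(14263L, 177L)
  expect_equal(l2$n_retained, 14086L)
  expect_error(filter_ledger(100L, 200L))
})

test_that("apply_filters enforces thresholds with exact accounting", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:300)
  bcs <- sprintf("b%03d", 1:80)
  counts <- matrix(rpois(300 * 80, 1.2), 300)
  counts[, 1:10] <- 0                             # empty barcodes
  counts[, 11] <- 60                              # aggregate: 18000 UMIs
  m <- mk_mat(counts, genes, bcs)
  rec <- data.table::data.table(cell_barcode = "b012", umis_A = 80,
                                umis_B = 20, minority_fraction = 0.2,
                                is_collision = TRUE)
  out <- apply_filters(m, rec, min_genes = 125L, max_umi = 5000L)
  l <- out$ledger
  expect_equal(l$n_retained, l$n_pass_gene_threshold -
                 l$n_excluded_high_umi_or_collision)
  expect_equal(l$n_high_umi, 1L)
  expect_equal(l$n_collision, 1L)
  expect_equal(ncol(out$matrix), l$n_retained)
  expect_false(any(c("b011", "b012") %in% colnames(out$matrix)))

  # everything below the gene threshold: empty result
  out0 <- apply_filters(m, rec, min_genes = 1000L)
  expect_equal(out0$ledger$n_retained, 0L)
  expect_equal(ncol(out0$matrix), 0L)

  # monotonicity: raising min_genes never increases the pass count;
  # raising theta never increases the collision count
  passes <- vapply(c(50L, 125L, 200L), function(mg)
    apply_filters(m, rec, min_genes = mg)$ledger$n_pass_gene_threshold,
    integer(1))
  expect_true(all(diff(passes) <= 0))
  set.seed(32)
  mA <- mk_mat(matrix(rpois(40, 50), 1), "gA", sprintf("c%02d", 1:40))
  mB <- mk_mat(matrix(rpois(40, 10), 1), "gB", sprintf("c%02d", 1:40))
  colls <- vapply(c(0.05, 0.1, 0.2, 0.4), function(th)
    sum(barnyard(mA, mB, th)$is_collision), integer(1))
  expect_true(all(diff(colls) <= 0))
})

test_that("doublet extrapolation follows n_cross / (2 pA pB)", {
  rec <- data.table::data.table(
    cell_barcode = sprintf("b%03d", 1:200),
    umis_A = c(rep(100, 100), rep(5, 100)),
    umis_B = c(rep(5, 100), rep(100, 100)))
  rec[, minority_fraction := pmin(umis_A, umis_B) / (umis_A + umis_B)]
  rec[, is_collision := minority_fraction > 0.1]
  # no collisions in this table
  est0 <- estimate_doublets(rec)
  expect_equal(est0$n_cross_collisions, 0L)
  expect_equal(est0$estimated_total_doublets, 0)

  rec2 <- data.table::copy(rec)
  rec2[1:50, `:=`(umis_A = 50, umis_B = 50)]
  rec2[, minority_fraction := pmin(umis_A, umis_B) / (umis_A + umis_B)]
  rec2[, is_collision := minority_fraction > 0.1]
  est <- estimate_doublets(rec2, proportions = c(0.5, 0.5))
  expect_equal(est$n_cross_collisions, 50L)
  expect_equal(est$estimated_total_doublets, 100)
  expect_gte(est$estimated_total_doublets, est$n_cross_collisions)

  one_sided <- data.table::data.table(
    cell_barcode = "b1", umis_A = 100, umis_B = 0,
    minority_fraction = 0, is_collision = FALSE)
  expect_warning(est1 <- estimate_doublets(one_sided), "single-species")
  expect_true(is.na(est1$estimated_total_doublets))
})

test_that("simulated cross-species doublets are flagged and recovered", {
  refs <- make_references(60, c(200, 500), seed = 41)
  cfg <- sim_config(n_cells_per_species = 1500L,
                    per_round_retention = c(1, 1, 1),
                    doublet_rate = 0.08, ambient_fraction = 0.02,
                    reads_per_cell_mean = 300, seed = 42L)
  truth <- simulate_cells(refs, cfg)
  cnt <- simulate_counts(truth)
  rec <- barnyard(cnt$matrices[[1]], cnt$matrices[[2]])
  # every balanced true cross-species doublet is flagged
  cross <- truth$cells[grepl("\\+", species)]
  bal <- merge(cross, truth$members[, .(n = sum(n_umis)),
                                    by = .(unit_id, species_id)],
               by = "unit_id")
  bal <- bal[, .(balanced = min(n) / sum(n) > 0.2 & sum(n) > 50),
             by = .(unit_id, cell_barcode)]
  flagged <- rec$cell_barcode[rec$is_collision]
  expect_true(all(bal$cell_barcode[bal$balanced] %in% flagged))
  est <- estimate_doublets(rec)
  expect_lt(abs(est$estimated_doublet_rate - 0.08) / 0.08, 0.35)
})
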