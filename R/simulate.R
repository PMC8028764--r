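#' Simulation configuration for a two-species split-pool experiment
#'
#' Collects every tunable of the synthetic experiment. Defaults emulate the
#' study conditions of a two-planarian barnyard run: three barcoding rounds
#' each retaining ~43% of cells (~8% overall detection of the input pool),
#' a gamma-Poisson (negative binomial) expression model, and low but
#' non-zero rates for the sequencing artifacts the read-curation stage is
#' built to remove.
#'
#' @param n_cells_per_species input cells per species entering round 1.
#' @param per_round_retention per-round cell retention fractions (three
#'   rounds); the default `0.43^3 ~ 0.08` matches the ~8% of input cells
#'   detected after the last barcoding step.
#' @param doublet_rate fraction of barcode-bearing units that are doublets
#'   (two cells fused into one unit); must be < 0.5.
#' @param ambient_fraction fraction of all molecules that are ambient
#'   ("soup") molecules drawn from the pooled expression mixture but
#'   carrying a valid cell barcode.
#' @param reads_per_cell_mean,reads_per_cell_dispersion negative-binomial
#'   mean and size for the number of cDNA molecules (distinct UMIs) per
#'   cell.
#' @param reads_per_umi_mean mean sequenced reads per molecule (>= 1);
#'   duplicates beyond the first are Poisson.
#' @param expression_shape gamma shape of per-gene expression rates; small
#'   values give the skewed per-cell expression profiles typical of
#'   single-cell data.
#' @param error_rate per-base substitution probability in both mates.
#' @param truncation_rate probability that read 2 is truncated to a length
#'   in \[40, 93\] (too short to span the barcodes).
#' @param chimera_rate probability that a read carries an embedded adapter
#'   (read-through chimera).
#' @param adapter1,adapter2 adapter contaminant sequences for mates 1 and 2
#'   (Illumina universal and Nextera by default).
#' @param seed integer seed; the whole simulation is a deterministic
#'   function of the config including the seed.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cells_per_species = 3000L,
                       per_round_retention = c(0.43, 0.43, 0.43),
                       doublet_rate = 0.05,
                       ambient_fraction = 0.02,
                       reads_per_cell_mean = 400,
                       reads_per_cell_dispersion = 2,
                       reads_per_umi_mean = 1,
                       expression_shape = 0.3,
                       error_rate = 0.005,
                       truncation_rate = 0.01,
                       chimera_rate = 0.01,
                       adapter1 = "AGATCGGAAGAG",
                       adapter2 = "CTGTCTCTTATA",
                       seed = 1L) {
  cfg <- list(n_cells_per_species = as.integer(n_cells_per_species),
              per_round_retention = per_round_retention,
              doublet_rate = doublet_rate,
              ambient_fraction = ambient_fraction,
              reads_per_cell_mean = reads_per_cell_mean,
              reads_per_cell_dispersion = reads_per_cell_dispersion,
              reads_per_umi_mean = reads_per_umi_mean,
              expression_shape = expression_shape,
              error_rate = error_rate,
              truncation_rate = truncation_rate,
              chimera_rate = chimera_rate,
              adapter1 = toupper(adapter1),
              adapter2 = toupper(adapter2),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  rates <- c(cfg$doublet_rate, cfg$ambient_fraction, cfg$error_rate,
             cfg$truncation_rate, cfg$chimera_rate, cfg$per_round_retention)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$doublet_rate >= 0.5)
    stop("doublet_rate >= 0.5 is a nonsensical regime")
  if (any(cfg$per_round_retention <= 0))
    stop("per_round_retention must be in (0, 1]")
  if (cfg$n_cells_per_species < 1) stop("n_cells_per_species must be >= 1")
  if (cfg$reads_per_umi_mean < 1) stop("reads_per_umi_mean must be >= 1")
  invisible(TRUE)
}

# Deterministic per-stage seed derived from the global seed and a stage
# name, kept below 2^31 so downstream set.seed() always accepts it.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Simulate the cell pool, barcode assignment and doublet structure
#'
#' Runs the cell-level part of the experiment: per-round binomial cell
#' loss, doublet formation by merging two uniformly sampled surviving
#' cells (cross-species with probability `2*p_A*p_B`), and uniform
#' with-replacement assignment of barcode combinations, so that natural
#' barcode collisions arise at the birthday-problem rate. Per-cell gene
#' expression rates are gamma draws normalized to sum to one; per-cell
#' molecule counts are negative binomial.
#'
#' The number of doublet units D satisfies `D = round(rate * (N - D))`
#' where N is the number of surviving cells, so the realized fraction of
#' barcode-bearing units that are doublets equals `doublet_rate`.
#'
#' @param refs list of two `species_reference` objects.
#' @param config a [sim_config()].
#' @param whitelists optional `splitpool_whitelists`; if supplied, barcode
#'   combinations index into it and each unit gets its sequence-level
#'   `cell_barcode` (bc1..bc2..bc3..sublib-char). Without it, combos index
#'   the default 48 x 96 x 96 x 3 space and barcodes are symbolic.
#' @return a `truth_table` object: list with `cells` (one row per
#'   barcode-bearing unit: unit_id, species, bc1_idx..sublib_idx,
#'   cell_barcode, is_doublet, n_true_umis), `members` (one row per member
#'   cell: unit_id, cell_id, species_id, n_umis), `rates` (per-species
#'   gene-by-cell rate matrices), and the config.
#' @export
simulate_cells <- function(refs, config, whitelists = NULL) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "cells"))
  sp_ids <- vapply(refs, `[[`, character(1), "species_id")

  # per-round binomial thinning of each species' input pool
  survivors <- vapply(sp_ids, function(sp) {
    n <- config$n_cells_per_species
    for (r in config$per_round_retention) n <- stats::rbinom(1L, n, r)
    n
  }, integer(1))
  if (sum(survivors) < 1L) stop("no cells survived the barcoding rounds")

  cell_species <- rep(sp_ids, survivors)
  n_cells <- length(cell_species)
  cell_ids <- sprintf("cell%06d", seq_len(n_cells))

  # doublets: D = round(rate * (N - D))  =>  D = round(N r / (1 + r))
  n_doublets <- round(n_cells * config$doublet_rate / (1 + config$doublet_rate))
  paired <- if (n_doublets > 0) sample(n_cells, 2L * n_doublets) else integer(0)
  unit_of_cell <- integer(n_cells)
  if (n_doublets > 0) {
    unit_of_cell[paired] <- rep(seq_len(n_doublets), each = 2L)
  }
  singles <- which(unit_of_cell == 0L)
  unit_of_cell[singles] <- n_doublets + seq_along(singles)
  n_units <- n_doublets + length(singles)

  members <- data.table::data.table(
    unit_id = sprintf("unit%06d", unit_of_cell),
    cell_id = cell_ids,
    species_id = cell_species)
  data.table::setorder(members, unit_id, cell_id)

  # per-cell molecule counts (negative binomial, gamma-Poisson depth)
  members[, n_umis := stats::rnbinom(.N, mu = config$reads_per_cell_mean,
                                     size = config$reads_per_cell_dispersion)]

  # barcode combinations sampled uniformly WITH replacement
  sizes <- if (is.null(whitelists)) c(48L, 96L, 96L, 3L) else
    c(length(whitelists$round1), length(whitelists$round2),
      length(whitelists$round3), length(whitelists$sublib_tags))
  units <- members[, .(species = paste(sort(unique(species_id)), collapse = "+"),
                       is_doublet = .N > 1L,
                       n_true_umis = sum(n_umis)), by = unit_id]
  units[, bc1_idx := sample.int(sizes[1], .N, replace = TRUE)]
  units[, bc2_idx := sample.int(sizes[2], .N, replace = TRUE)]
  units[, bc3_idx := sample.int(sizes[3], .N, replace = TRUE)]
  units[, sublib_idx := sample.int(sizes[4], .N, replace = TRUE)]
  units[, cell_barcode := compose_barcode(bc1_idx, bc2_idx, bc3_idx,
                                          sublib_idx, whitelists)]
  data.table::setorder(units, unit_id)

  # per-cell expression rate vectors, gamma(shape) normalized per cell
  rates <- lapply(refs, function(r) {
    cells_sp <- members$cell_id[members$species_id == r$species_id]
    g <- length(r$gene_ids)
    m <- matrix(stats::rgamma(g * length(cells_sp), shape = config$expression_shape),
                nrow = g, dimnames = list(r$gene_ids, cells_sp))
    sweep(m, 2L, colSums(m), "/")
  })
  names(rates) <- sp_ids

  stopifnot(n_units == nrow(units),
            abs(n_doublets / n_units - config$doublet_rate) <
              max(0.005, 2 / n_units) || config$doublet_rate == 0)
  structure(list(cells = units, members = members, rates = rates,
                 config = config, species_ids = sp_ids,
                 whitelists = whitelists),
            class = "truth_table")
}

compose_barcode <- function(b1, b2, b3, s, whitelists = NULL) {
  if (is.null(whitelists)) {
    sprintf("B%02d.%02d.%02d.%d", b1, b2, b3, s)
  } else {
    paste0(whitelists$round1[b1], whitelists$round2[b2], whitelists$round3[b3],
           whitelists$sublib_tags[s])
  }
}

#' @export
print.truth_table <- function(x, ...) {
  cat("Simulated experiment:", nrow(x$members), "cells in", nrow(x$cells),
      "barcode-bearing units (", sum(x$cells$is_doublet), "doublets )\n")
  invisible(x)
}

# draw one gene index per molecule for a set of cells sharing a rate matrix
draw_gene_indices <- function(rate_mat, cell_ids, n_per_cell) {
  idx <- vector("list", length(cell_ids))
  for (i in seq_along(cell_ids)) {
    n <- n_per_cell[i]
    idx[[i]] <- if (n > 0)
      sample.int(nrow(rate_mat), n, replace = TRUE, prob = rate_mat[, cell_ids[i]])
    else integer(0)
  }
  idx
}

#' Count-level simulation: per-species digital matrices straight from truth
#'
#' Skips read generation entirely: molecules are drawn per cell from its
#' expression rates (multinomially, given the negative-binomial depth from
#' [simulate_cells()]), ambient molecules from the pooled mixture
#' (allocated to valid barcodes proportionally to unit depth), and
#' counts aggregated per (gene, cell-barcode). Units sharing a barcode
#' (natural collisions) are merged, exactly as sequencing would merge
#' them. Useful for barnyard and doublet-calibration experiments at scales
#' where simulating reads would be wasteful.
#'
#' @param truth a `truth_table` from [simulate_cells()].
#' @return list with `matrices` (named per species, each a sparse
#'   genes-by-barcodes dgCMatrix of molecule counts) and `barcodes` (the
#'   shared column namespace).
#' @export
simulate_counts <- function(truth) {
  config <- truth$config
  set.seed(stage_seed(config$seed, "counts"))
  members <- truth$members
  units <- truth$cells
  bc_of_unit <- stats::setNames(units$cell_barcode, units$unit_id)
  barcodes <- sort(unique(units$cell_barcode))

  mats <- list()
  for (sp in truth$species_ids) {
    rm_ <- truth$rates[[sp]]
    msp <- members[members$species_id == sp]
    gene_idx <- draw_gene_indices(rm_, msp$cell_id, msp$n_umis)
    ii <- unlist(gene_idx, use.names = FALSE)
    jj <- rep(match(bc_of_unit[msp$unit_id], barcodes), msp$n_umis)
    # ambient molecules: pooled mixture, valid barcodes of real units
    n_real_total <- sum(members$n_umis)
    n_amb_sp <- round(config$ambient_fraction / (1 - config$ambient_fraction) *
                        n_real_total * sum(msp$n_umis) / max(1, n_real_total))
    if (n_amb_sp > 0) {
      pool <- rowMeans(rm_)
      amb_gene <- sample.int(nrow(rm_), n_amb_sp, replace = TRUE, prob = pool)
      amb_bc <- sample(match(units$cell_barcode, barcodes), n_amb_sp,
                       replace = TRUE, prob = units$n_true_umis + 1)
      ii <- c(ii, amb_gene); jj <- c(jj, amb_bc)
    }
    mats[[sp]] <- Matrix::sparseMatrix(
      i = ii, j = jj, x = 1,
      dims = c(nrow(rm_), length(barcodes)),
      dimnames = list(rownames(rm_), barcodes))
  }
  list(matrices = mats, barcodes = barcodes)
}

random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# vectorized per-base substitution at a fixed rate; substituted bases are
# drawn from the three alternatives
mutate_seqs <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    pos <- sample.int(lens[i], n_err[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Generate paired reads with per-read ground truth
#'
#' Emits read 1 (a random 60-150 nt fragment of a transcript chosen from
#' the originating cell's expression rates) and read 2 (UMI, the three
#' round barcodes and linker fillers laid out per `layout`, padded to 150
#' nt), then applies the corruption model: per-base substitutions,
#' read-2 truncation below the barcode span, and adapter chimeras.
#' Ambient molecules draw their transcript from the pooled two-species
#' mixture but carry the valid barcode of a real unit (sampled
#' proportionally to unit depth).
#'
#' @param truth a `truth_table` from [simulate_cells()] (built with the
#'   same `whitelists`).
#' @param refs the references used to build `truth`.
#' @param layout a [barcode_layout()].
#' @param whitelists a `splitpool_whitelists`.
#' @param config the [sim_config()] (normally `truth$config`).
#' @param read_len sequenced read length (both mates), default 150.
#' @return list with `reads` (data.table: read_id, sublib, seq1, qual1,
#'   seq2, qual2) and `truth_reads` (data.table: read_id, cell_id
#'   ("AMBIENT" for soup molecules), unit_id, cell_barcode, gene_id, umi).
#' @export
generate_reads <- function(truth, refs, layout, whitelists,
                           config = truth$config, read_len = 150L) {
  if (layout$min_span > read_len) stop("layout min_span exceeds read length")
  set.seed(stage_seed(config$seed, "reads"))
  members <- truth$members
  units <- truth$cells
  sp_of_gene <- do.call(c, unname(lapply(refs, function(r)
    stats::setNames(rep(r$species_id, length(r$gene_ids)), r$gene_ids))))
  all_seqs <- do.call(c, unname(lapply(refs, `[[`, "sequences")))

  # molecules: real cells first
  mol <- list()
  for (sp in truth$species_ids) {
    msp <- members[members$species_id == sp]
    gi <- draw_gene_indices(truth$rates[[sp]], msp$cell_id, msp$n_umis)
    mol[[sp]] <- data.table::data.table(
      cell_id = rep(msp$cell_id, msp$n_umis),
      unit_id = rep(msp$unit_id, msp$n_umis),
      gene_id = rownames(truth$rates[[sp]])[unlist(gi, use.names = FALSE)])
  }
  mol <- data.table::rbindlist(mol)
  # ambient molecules: pooled mixture over both species, barcode of a real unit
  n_amb <- round(config$ambient_fraction / (1 - config$ambient_fraction) *
                   nrow(mol))
  if (n_amb > 0) {
    pool <- do.call(c, unname(lapply(truth$species_ids, function(sp)
      rowMeans(truth$rates[[sp]]) *
        sum(members$n_umis[members$species_id == sp]))))
    amb_units <- units[sample.int(nrow(units), n_amb, replace = TRUE,
                                  prob = units$n_true_umis + 1)]
    mol <- rbind(mol, data.table::data.table(
      cell_id = "AMBIENT",
      unit_id = amb_units$unit_id,
      gene_id = names(pool)[sample.int(length(pool), n_amb, replace = TRUE,
                                       prob = pool)]))
  }
  mol[, umi := random_dna(.N, layout$umi_len)]
  mol <- merge(mol, units[, .(unit_id, cell_barcode, bc1_idx, bc2_idx,
                              bc3_idx, sublib_idx)],
               by = "unit_id", sort = FALSE)

  # reads per molecule (PCR duplicates are plain UMI multiplicity)
  n_reads_per_mol <- if (config$reads_per_umi_mean > 1)
    1L + stats::rpois(nrow(mol), config$reads_per_umi_mean - 1) else
      rep(1L, nrow(mol))
  reads <- mol[rep(seq_len(nrow(mol)), n_reads_per_mol)]
  reads <- reads[sample.int(nrow(reads))]  # shuffle read order
  reads[, read_id := sprintf("read%08d", .I)]

  # read 1: random fragment of the transcript
  tx <- all_seqs[reads$gene_id]
  tx_len <- nchar(tx)
  frag_len <- pmin(tx_len, sample(60:150, nrow(reads), replace = TRUE))
  start <- 1L + floor(stats::runif(nrow(reads)) * (tx_len - frag_len + 1))
  seq1 <- substr(tx, start, start + frag_len - 1L)

  # read 2: layout-ordered UMI + barcodes + linkers, padded to read_len
  segs <- layout$segments[order(layout$segments$offset), ]
  parts <- lapply(seq_len(nrow(segs)), function(i) {
    s <- segs[i, ]
    switch(s$kind,
           UMI = reads$umi,
           BC1 = whitelists$round1[reads$bc1_idx],
           BC2 = whitelists$round2[reads$bc2_idx],
           BC3 = whitelists$round3[reads$bc3_idx],
           LINKER = rep(layout$linkers[s$linker_id], nrow(reads)))
  })
  pad_len <- read_len - layout$min_span
  seq2 <- do.call(paste0, c(parts, list(random_dna(nrow(reads), pad_len))))

  # corruption: substitutions, read-2 truncation, adapter chimeras
  seq1 <- mutate_seqs(seq1, config$error_rate)
  seq2 <- mutate_seqs(seq2, config$error_rate)
  if (config$truncation_rate > 0) {
    tr <- stats::runif(nrow(reads)) < config$truncation_rate
    if (any(tr))
      seq2[tr] <- substr(seq2[tr], 1L, sample(40:93, sum(tr), replace = TRUE))
  }
  if (config$chimera_rate > 0) {
    ch <- which(stats::runif(nrow(reads)) < config$chimera_rate)
    for (i in ch) {
      L <- nchar(seq1[i])
      p <- sample(20:max(20L, L - nchar(config$adapter1)), 1L)
      seq1[i] <- paste0(substr(seq1[i], 1, p), config$adapter1,
                        random_dna(1L, max(0L, L - p - nchar(config$adapter1))))
      seq1[i] <- substr(seq1[i], 1, L)
    }
  }

  out <- data.table::data.table(
    read_id = reads$read_id,
    sublib = whitelists$sublib_tags[reads$sublib_idx],
    seq1 = seq1, qual1 = strrep("I", nchar(seq1)),
    seq2 = seq2, qual2 = strrep("I", nchar(seq2)))
  truth_reads <- reads[, .(read_id, cell_id, unit_id, cell_barcode,
                           gene_id, umi)]
  list(reads = out, truth_reads = truth_reads)
}

#' Simulate a two-cell-type expression matrix (for label-transfer tests)
#'
#' Generates a genes-by-cells count matrix from `n_types` cell types whose
#' mean expression profiles differ on disjoint marker blocks scaled by
#' `effect`, with negative-binomial noise. Larger `effect` separates the
#' types more strongly.
#'
#' @param n_cells cells to draw (types sampled uniformly).
#' @param n_genes total genes; each type gets `n_genes / (2 * n_types)`
#'   markers.
#' @param n_types number of cell types.
#' @param effect fold elevation of a type's marker block.
#' @param depth mean molecules per cell.
#' @param seed integer seed for the cells drawn.
#' @param profile_seed seed fixing the type expression profiles; two
#'   datasets simulated with different `seed` but the same `profile_seed`
#'   contain the same cell types (e.g. a reference atlas and a query).
#' @return list with `counts` (genes x cells matrix) and `labels`
#'   (character vector of type labels per cell).
#' @export
simulate_cell_types <- function(n_cells = 200L, n_genes = 400L, n_types = 2L,
                                effect = 8, depth = 2000, seed = 1L,
                                profile_seed = 1L) {
  set.seed(profile_seed)
  block <- max(1L, floor(n_genes / (2L * n_types)))
  base <- stats::rgamma(n_genes, shape = 1, rate = 1) + 0.1
  type_means <- sapply(seq_len(n_types), function(t) {
    m <- base
    idx <- ((t - 1L) * block + 1L):(t * block)
    m[idx] <- m[idx] * effect
    m / sum(m)
  })
  set.seed(seed)
  labels <- sprintf("type%d", sample.int(n_types, n_cells, replace = TRUE))
  counts <- sapply(seq_len(n_cells), function(i) {
    n <- stats::rnbinom(1L, mu = depth, size = 5) + 50L
    tabulate(sample.int(n_genes, n, replace = TRUE,
                        prob = type_means[, as.integer(sub("type", "", labels[i]))]),
             nbins = n_genes)
  })
  rownames(counts) <- sprintf("g%04d", seq_len(n_genes))
  colnames(counts) <- sprintf("c%04d", seq_len(n_cells))
  list(counts = counts, labels = labels)
}
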