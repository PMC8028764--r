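#' Assemble a full run configuration
#'
#' One serializable object holding every stage parameter of the pipeline,
#' with defaults matching the workflow's printed values: minimum read
#' lengths 60/94, quality cutoff 10, hamming-1 barcode correction, k = 31,
#' matrix-creation floor of 100 genes, cell calling at 125 genes, UMI
#' ceiling 5000, collision threshold 0.10, saturation fractions
#' 0.1/0.25/0.5/0.75/1. A single global seed deterministically derives
#' per-stage seeds, so any stage can be re-run in isolation.
#'
#' @param out_dir output directory of the run.
#' @param sim a [sim_config()] for the simulation stage.
#' @param n_genes genes per species for the synthetic references.
#' @param ... overrides for any parameter below (see Details via
#'   `str(run_config())`).
#' @param seed global seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("splitpool_run"),
                       sim = sim_config(n_cells_per_species = 250L,
                                        per_round_retention = c(1, 1, 1)),
                       n_genes = 80L, ..., seed = 1L) {
  cfg <- list(out_dir = out_dir, sim = sim, n_genes = n_genes,
              length_range = c(200L, 1000L),
              min_len1 = 60L, min_len2 = 94L, qual_cutoff = 10L,
              adapter1 = sim$adapter1, adapter2 = sim$adapter2,
              max_phase_mismatch = 1L, max_hamming = 1L,
              k = 31L, creation_min_genes = 100L,
              min_genes = 125L, max_umi = 5000L, theta = 0.10,
              fractions = c(0.10, 0.25, 0.50, 0.75, 1.00),
              seed = as.integer(seed))
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Validate a run configuration
#'
#' Checks every parameter range and the whitelist/layout consistency,
#' reporting all violations rather than stopping at the first.
#'
#' @param config a [run_config()].
#' @param whitelists optional whitelists to validate alongside.
#' @return character vector of findings; empty means the config is valid.
#' @export
validate_config <- function(config, whitelists = NULL) {
  errs <- character(0)
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(config$theta > 0 && config$theta < 0.5,
      "barnyard collision threshold theta must lie in (0, 0.5)")
  chk(config$min_len1 >= 1, "min_len1 must be positive")
  chk(config$min_len2 >= 1, "min_len2 must be positive")
  chk(config$k %% 2 == 1 && config$k >= 15 && config$k <= 63,
      "k must be odd and within [15, 63]")
  chk(all(config$fractions > 0 & config$fractions <= 1),
      "saturation fractions must lie in (0, 1]")
  chk(config$min_genes >= 1, "cell-calling min_genes must be positive")
  chk(config$max_umi >= 1, "max_umi must be positive")
  chk(config$max_hamming %in% 0:1, "max_hamming must be 0 or 1")
  cfg_ok <- tryCatch({ validate_sim_config(config$sim); TRUE },
                     error = function(e) { errs <<- c(errs, conditionMessage(e)); TRUE })
  if (!is.null(whitelists)) {
    for (r in 1:3) {
      if (anyDuplicated(whitelists[[paste0("round", r)]]))
        errs <- c(errs, paste0("duplicate barcode in whitelist round ", r))
    }
  }
  errs
}

md5_of <- function(paths) tools::md5sum(paths[file.exists(paths)])

#' Run the full pipeline: simulate, curate, demultiplex, quantify, QC
#'
#' Executes every stage in dependency order on a synthetic experiment:
#' reference and whitelist generation, cell/read simulation, per-mate
#' FASTQ writing split by sub-library, read curation with phase checking,
#' barcode tagging per sub-library, unique-k-mer gene assignment, digital
#' expression matrices per species, barnyard/collision QC, cell filtering
#' with the accounting ledger, doublet calibration, and the saturation
#' curve. A failure in any stage aborts with that stage's name; outputs
#' of completed stages are preserved on disk. The manifest (written last
#' as `manifest.yaml`) lists every output file with its md5 checksum and
#' echoes all stage reports.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with all in-memory stage results (`truth`,
#'   `reports`, `matrices`, `barnyard`, `ledgers`, `doublets`,
#'   `saturation`, `manifest`).
#' @export
run_pipeline <- function(config) {
  errs <- validate_config(config)
  if (length(errs) > 0)
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  res <- list()
  tryCatch({
    stage <- "simulate"
    refs <- make_references(config$n_genes, config$length_range,
                            seed = stage_seed(config$seed, "refs"))
    layout <- barcode_layout()
    wl <- generate_whitelists(stage_seed(config$seed, "whitelists"))
    simc <- config$sim
    simc$seed <- stage_seed(config$seed, "sim")
    truth <- simulate_cells(refs, simc, wl)
    sim <- generate_reads(truth, refs, layout, wl, simc)
    sim_dir <- file.path(config$out_dir, "sim")
    write_simulation(sim, truth, wl, sim_dir)
    write_references(refs, sim_dir)
    res$truth <- truth

    stage <- "readproc+demux"
    tagged_all <- list()
    reports <- list()
    for (tag in wl$sublib_tags) {
      sub <- sim$reads[sim$reads$sublib == tag]
      pairs <- data.table::data.table(read_id = sub$read_id,
                                      seq1 = sub$seq1, qual1 = sub$qual1,
                                      seq2 = sub$seq2, qual2 = sub$qual2)
      fl <- trim_and_filter(pairs, config$min_len1, config$min_len2,
                            config$adapter1, config$adapter2,
                            config$qual_cutoff, layout = layout,
                            max_phase_mismatch = config$max_phase_mismatch)
      keep <- retain_paired(fl$pairs$read_id, fl$pairs$read_id)
      dm <- tag_reads(fl$pairs[fl$pairs$read_id %in% keep], layout, wl, tag,
                      config$max_hamming)
      tagged_all[[tag]] <- dm$tagged
      reports[[tag]] <- list(filter = fl$report, demux = dm$report)
    }
    tagged <- data.table::rbindlist(tagged_all)
    res$reports <- reports

    stage <- "quant"
    index <- build_index(refs, config$k)
    tagged[, gene_id := assign_reads(cdna_seq, index)]
    mats <- build_matrix(tagged, index, config$creation_min_genes)
    res$assigned <- tagged[, .(read_id, cell_barcode, umi, gene_id)]
    res$matrices <- mats
    for (sp in names(mats))
      write_matrix_mtx(mats[[sp]], file.path(config$out_dir, paste0("dge_", sp)))

    stage <- "species_qc"
    sps <- names(mats)
    bt <- barnyard(mats[[sps[1]]], mats[[sps[2]]], config$theta)
    data.table::fwrite(bt, file.path(config$out_dir, "barnyard.tsv"),
                       sep = "\t")
    ledgers <- list()
    filtered <- list()
    for (sp in sps) {
      f <- apply_filters(mats[[sp]], bt, config$min_genes, config$max_umi)
      ledgers[[sp]] <- f$ledger
      filtered[[sp]] <- f$matrix
    }
    res$barnyard <- bt
    res$ledgers <- ledgers
    res$filtered <- filtered
    res$doublets <- estimate_doublets(bt)

    stage <- "saturation"
    called <- unique(unlist(lapply(filtered, colnames)))
    res$saturation <- saturation(res$assigned, config$fractions,
                                 fixed_barcodes = called,
                                 seed = stage_seed(config$seed, "sat"))
    data.table::fwrite(res$saturation,
                       file.path(config$out_dir, "saturation.tsv"),
                       sep = "\t")

    stage <- "manifest"
    outputs <- list.files(config$out_dir, recursive = TRUE,
                          full.names = TRUE)
    outputs <- outputs[basename(outputs) != "manifest.yaml"]
    manifest <- list(
      seed = config$seed,
      parameters = unclass(config[setdiff(names(config), c("sim"))]),
      sim = unclass(config$sim),
      checksums = as.list(md5_of(outputs)),
      reports = lapply(reports, function(r) list(
        filter = unclass(r$filter), demux = unclass(r$demux))),
      ledgers = lapply(ledgers, unclass),
      stages_complete = c("simulate", "readproc+demux", "quant",
                          "species_qc", "saturation"))
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
    res$manifest <- manifest
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
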