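library(data.table)

# Shared fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

fx_refs <- function() fx("refs", function()
  make_references(40, c(200, 600), seed = 11))

fx_layout <- function() fx("layout", function() barcode_layout())

fx_whitelists <- function() fx("wl", function() generate_whitelists(7))

# 500-cell two-species experiment with zero corruption (errors, truncation,
# chimeras all off; doublets and ambient RNA at defaults).
fx_clean <- function() fx("clean", function() {
  refs <- fx_refs(); wl <- fx_whitelists(); lay <- fx_layout()
  cfg <- sim_config(n_cells_per_species = 250L,
                    per_round_retention = c(1, 1, 1),
                    reads_per_cell_mean = 200,
                    error_rate = 0, truncation_rate = 0, chimera_rate = 0,
                    seed = 5L)
  truth <- simulate_cells(refs, cfg, wl)
  sim <- generate_reads(truth, refs, lay, wl, cfg)
  list(refs = refs, wl = wl, lay = lay, cfg = cfg, truth = truth, sim = sim)
})

# the clean experiment curated, demultiplexed and gene-assigned;
# `passed_ids` are the reads surviving curation (chance adapter-overlap
# trimming can drop a handful even of clean reads)
fx_clean_quant <- function() fx("clean_quant", function() {
  e <- fx_clean()
  tagged <- list()
  passed <- list()
  for (tag in e$wl$sublib_tags) {
    sub <- e$sim$reads[sublib == tag]
    fl <- trim_and_filter(sub[, .(read_id, seq1, qual1, seq2, qual2)],
                          layout = e$lay)
    passed[[tag]] <- fl$pairs$read_id
    dm <- tag_reads(fl$pairs, e$lay, e$wl, tag)
    tagged[[tag]] <- dm$tagged
  }
  tagged <- data.table::rbindlist(tagged)
  idx <- build_index(e$refs)
  tagged[, gene_id := assign_reads(cdna_seq, idx)]
  c(e, list(tagged = tagged, idx = idx,
            passed_ids = unlist(passed, use.names = FALSE)))
})
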