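# splitpool

Simulation and analysis of **split-pool combinatorially barcoded
single-cell RNA-seq** experiments, built around the two-species
("barnyard") experimental design.

In split-pool barcoding, fixed cells are carried through successive
rounds of splitting into wells, in-well labeling, and re-pooling — here
48 reverse-transcription barcodes, two ligation rounds of 96 barcodes
each, and 3 PCR-indexed sub-libraries, so each cell ends up tagged with
one of 48 × 96 × 96 × 3 = **1,327,104** barcode combinations. Mixing
cells from two species exposes the method's failure modes: a barcode
whose UMIs come from both species is either a cross-species doublet or
two cells that received the same combination. The package provides,
for this design:

* a **ground-truthed read simulator** — two synthetic species
  references, gamma–Poisson expression, per-round cell loss, doublets,
  natural barcode collisions, ambient RNA, substitution errors, read
  truncation and adapter chimeras, emitting paired FASTQ plus truth
  tables;
* **read curation** (`trim_and_filter`): 3′ quality trimming, terminal-N
  stripping, adapter removal, minimum lengths 60 nt (cDNA mate) / 94 nt
  (the minimum read-2 span of all barcodes), and a barcode-phase check
  against the fixed linker offsets;
* **demultiplexing** (`tag_reads`): UMI/barcode extraction and
  whitelist error correction at hamming distance ≤ 1, with ambiguous
  corrections dropped and the sub-library character appended to the
  cell barcode;
* **quantification** (`build_index`, `assign_reads`, `build_matrix`):
  unique-31-mer gene assignment over both species' transcripts, UMI
  collapse at edit distance 1 (greedy count-descending rule), and
  per-species digital expression matrices (MatrixMarket + sidecars);
* **species-mixing QC** (`barnyard`, `apply_filters`,
  `estimate_doublets`): collision calling at a strict >10% minority-UMI
  threshold, cell calling at ≥125 detected genes, exclusion of >5000-UMI
  barcodes, and doublet-load extrapolation
  `n_cross / (2 p_A p_B)` from observed cross-species collisions;
* **saturation analysis** (`saturation`): nested read downsampling at
  10/25/50/75/100% with per-cell UMI/gene medians over the full-depth
  cell set;
* **label transfer** (`label_transfer`): CP10K/log1p normalization,
  high-variance feature selection, and top-k Pearson correlation
  transfer of reference labels with a reference-vs-self margin rule;
* **RNA-integrity inference** (`ribosomal_fraction`, `fit_rin_model`,
  `infer_rin`): the 18S+28S electropherogram area fraction regressed
  against known RIN values — the standard workaround where the
  instrument's vertebrate-trained RIN algorithm fails (e.g. the 28S
  "hidden break" of many invertebrates).

`run_pipeline()` chains simulate → curate → demultiplex → quantify →
QC → saturation under one seeded configuration and writes a manifest
with checksums. A thin command-line front end lives at
`inst/cli/splitpool.R` (`Rscript splitpool.R run|readproc|demux|qc|rin …`).

## Worked example

A small end-to-end run — 150 input cells per species, no cell loss,
default corruption rates (0.5% substitutions, 1% truncation, 1%
chimeras, 5% doublets, 2% ambient):

```r
library(splitpool)
cfg <- run_config(out_dir = "splitpool_demo",
                  sim = sim_config(n_cells_per_species = 150L,
                                   per_round_retention = c(1, 1, 1),
                                   seed = 42),
                  n_genes = 60L, creation_min_genes = 1L, min_genes = 25L,
                  seed = 42)
res <- run_pipeline(cfg)
res$reports$A$filter
#> Read-pair filter report
#>   n_input            42937
#>   n_pass             41387
#>   ...
#>   n_fail_short1      240
#>   n_fail_short2      437
#>   n_fail_phase       873
res$reports$A$demux
#> Demultiplexing report
#>   input 41387, tagged 41313, no-match 74, ambiguous 0, N-UMI 0
#>   corrections per round: 1576 / 1585 / 1558
res$ledgers[[1]]
#> Cell filter ledger: 138 passed >= 25 genes, 8 excluded
#>   (> 5000 UMIs or collision) -> 130 retained
res$doublets
#> Doublet calibration: 9 cross-species collisions, p = (0.510, 0.490)
#>   -> 18.0 total doublets (rate 0.0617)
res$saturation[, 1:3]
#>    fraction median_umis median_genes
#> 1:     0.10        37.0         18.0
#> 2:     0.25        91.0         27.0
#> 3:     0.50       183.0         33.5
#> 4:     0.75       272.0         38.0
#> 5:     1.00       359.5         42.0
```

Reading the output: of 42,937 sub-library-A read pairs, 1,550 are lost
to the length, adapter and phase filters (the simulator planted ~2% of
reads with truncations or chimeras; substitution errors knock a further
~2% of reads out of barcode phase). Demultiplexing resolves 99.8% of
surviving reads, correcting ~1,500 single-base barcode errors per
round. After quantification, 138 barcodes pass the 25-gene calling
threshold used at this toy depth, 8 are excluded as collisions or
aggregates, and the 9 observed cross-species collisions extrapolate to
18 total doublets — the simulation was configured with a 5% doublet
rate over 286 units (14 true doublets). The saturation medians rise
monotonically with sequencing depth and have not plateaued, i.e. this
toy library is not sequenced to saturation.

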