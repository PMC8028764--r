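---
title: "Methods: simulation and analysis of split-pool barnyard experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and analysis of split-pool barnyard experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The experiment being modelled

`splitpool` implements the computational side of a two-species
("barnyard") split-pool combinatorial barcoding experiment. Cells from
two species are mixed, then barcoded through successive rounds of
splitting into wells, in-well labeling, and re-pooling: one
reverse-transcription round over 48 wells, two ligation rounds over 96
wells each, and a final PCR-indexed sub-library round with 3 indices.
Every cell thereby acquires one of

$$48 \times 96 \times 96 \times 3 = 1{,}327{,}104$$

possible barcode combinations; two cells receive the same combination
("natural collision") at the birthday-problem rate. Read 1 of each pair
carries the cDNA fragment; read 2 carries a 10-nt UMI, the three 8-nt
well barcodes, and fixed linker sequences between them. Under the
package's default layout the last barcode ends at offset 94, which is
why 94 nt is the minimum read-2 length that spans all barcodes.

The package covers seven stages: synthetic data generation, read
curation, demultiplexing, quantification, species-mixing QC, saturation
and label transfer, and RNA-integrity inference. `run_pipeline()`
orchestrates them; each is usable on its own.

# The synthetic-data generator

The generator is first-class, tested code: it defines the statistical
conditions every downstream claim is evaluated under.

**Cell pool.** Each species contributes `n_cells_per_species` input
cells; each barcoding round retains a binomial fraction
(`per_round_retention`, default 0.43 per round, i.e. ~8% overall — the
observed cell loss of split-pool protocols, where only a small fraction
of the input pool is detected at the final barcoding step).

**Expression.** Per-cell gene rates are independent gamma draws
(`expression_shape`, default 0.3) normalized to sum to one — the
skewed profile typical of single-cell data. Per-cell molecule counts
are negative binomial (`reads_per_cell_mean` = 400,
`reads_per_cell_dispersion` = 2), so counts are gamma–Poisson at both
levels. No further biological structure (cell types, pathways) is
simulated in the main pipeline; `simulate_cell_types()` provides a
separate typed generator for label-transfer experiments.

**Doublets.** A fraction `doublet_rate` of barcode-bearing units are
fusions of two cells drawn uniformly from the surviving pool; with
species proportions $p_A, p_B$ a doublet is cross-species with
probability $2 p_A p_B$. The realized number of doublets $D$ solves
$D = \mathrm{round}(r \cdot (N - D))$ for $N$ surviving cells, so the
doublet fraction *among units* equals the configured rate exactly.

**Barcodes.** Combinations are sampled uniformly *with* replacement, so
natural collisions occur at the closed-form birthday rate
$1 - (1 - 1/1{,}327{,}104)^{n-1}$ per cell — an asserted property of the
generator. Whitelists are drawn by rejection sampling with a minimum
within-round pairwise hamming distance of 3, which makes radius-1 error
correction provably unambiguous. Real plates carry no such guarantee;
this is a deliberate simulator idealization (set `min_dist = 1` to
disable it).

**Ambient RNA.** A fraction `ambient_fraction` (default 0.02) of
molecules are "soup": their transcript is drawn from the pooled
two-species mixture, but they carry the valid barcode of a real unit,
sampled proportionally to unit depth. Depth-proportional allocation
keeps the per-cell contamination fraction roughly constant, which is
the realistic regime; uniform allocation would give shallow cells
arbitrarily high contamination fractions and turn them into spurious
species-mixing collisions.

**Read corruption.** Per-base substitutions at `error_rate` (default
0.005) on both mates; read-2 truncation to a uniform length in
[40, 93] with probability `truncation_rate`; adapter chimeras embedded
with probability `chimera_rate`. Quality strings are flat Phred 40; the
generator does not model quality-dependent error profiles, indels,
splice structure, or PCR duplicates beyond UMI multiplicity
(`reads_per_umi_mean`). Passing tests therefore demonstrate
correctness of the *algorithms* under a clean generative model, not
robustness to every artifact of real sequencers.

# Read curation

`trim_and_filter()` reproduces the standard curation contract: per
mate, 3' quality trimming at Phred 10 (the maximal low-quality suffix
is dropped), stripping of trailing Ns on read 2, adapter removal — an
exact occurrence anywhere truncates the read at the match, otherwise a
3'-terminal suffix-prefix overlap of at least 6 nt does — then minimum
lengths of 60 nt (read 1) and 94 nt (read 2). Checks run in a fixed
order with first-failure attribution, so the report buckets partition
the input exactly; this identity is asserted on every run.

Two numerical notes. First, overlap-based adapter trimming has an
irreducible false-positive rate: a random 3' hexamer matches the
adapter prefix with probability $4^{-6}$, so roughly $3 \times 10^{-4}$
of perfectly clean reads lose a few terminal bases, and the occasional
short fragment then falls under the 60-nt floor. This is inherent to
every overlap trimmer at this stringency, and the test suite asserts
full recovery *up to* this effect rather than pretending it away.
Second, the phase check (`check_phase()`) verifies that both linkers
sit at their expected offsets with at most one substitution each; any
upstream indel shifts all later segments and fails the check. No
rescue alignment is attempted — out-of-phase reads are rare and are
conservatively discarded, not repaired. Whether the original toolchain
tolerated any linker mismatches is not documented; one substitution
per linker is this package's default and is configurable.

# Demultiplexing

Barcodes are corrected against their round whitelist at hamming
distance ≤ 1: an exact match wins immediately; otherwise the unique
entry at distance 1 is taken; ties are `AMBIGUOUS` and dropped rather
than arbitrarily assigned; N counts as a mismatch. The implementation
precomputes the radius-1 neighborhood of the whitelist into a lookup
table; the test suite checks it against an independent brute-force
hamming scan on thousands of corrupted barcodes. UMIs containing N are
dropped at tagging, because an N corrupts the hamming arithmetic of
UMI deduplication downstream. The sub-library character (A, T or C) is
appended to the 24-nt barcode concatenation, so identical well
combinations from different sub-libraries can never merge.

# Quantification

**Gene assignment.** Splice-aware alignment is out of scope; reads are
assigned by a unique-k-mer vote instead. A k = 31 index over both
species' transcripts keeps exactly the k-mers occurring in one gene
across the concatenated gene set. A read hitting one gene is assigned;
two or more distinct genes is a multimapper (dropped); zero hits is
unassigned. On random synthetic references ≥ 99% of k-mers are
gene-unique, so this assigner is essentially exact there — it is the
package's single intentional departure from an alignment-based
toolchain, adequate because the synthetic references are
transcript-level and intron-free.

**UMI collapse.** Within each (gene, barcode), UMIs are deduplicated
at edit distance 1 with the greedy count-descending rule standard in
digital-expression tools: sort by descending read count (ties
lexicographic), absorb any UMI within hamming distance 1 of an already
accepted UMI. Whether the original tooling used greedy or
connected-components collapse is not documented; both are implemented
(`method = "components"`), greedy is the default. All tie-breaks in
the package are lexicographic, so matrices are bit-reproducible and
invariant to read order — an asserted property.

**Matrix creation.** Barcodes detecting fewer than 100 genes are
dropped at matrix creation (`creation_min_genes`), mirroring the
matrix-builder floor; this is distinct from the later cell-calling
threshold of 125 genes.

# Species-mixing QC and doublet calibration

`barnyard()` tabulates each barcode's UMIs per species and flags a
**collision** when the minority species holds strictly more than
θ = 10% of its UMIs. The boundary is exclusive by design (a 90/10
barcode is not a collision); θ is configurable. `apply_filters()` then
keeps barcodes with ≥ 125 detected genes and excludes, from those,
barcodes with > 5000 total UMIs (aggregates) or a collision flag,
maintaining the accounting identity
`retained = passed − excluded` that the ledger asserts on every run.

**Doublet calibration.** Cross-species collisions are directly
observable; the total doublet load is extrapolated as

$$\widehat{D} = \frac{n_{\text{cross}}}{2\,p_A\,p_B},$$

with species proportions taken from majority-species assignment and a
binomial 95% interval propagated from $n_{\text{cross}}$. Two known
biases, both conservative (upward) and both small at the scales used
here, are worth stating. Natural barcode collisions between cells of
different species are indistinguishable from cross-species doublets
and inflate the numerator by about $\binom{n}{2}/1{,}327{,}104 \times
2 p_A p_B$ — at 20,000 units this is ~75 barcodes against ~500 true
cross doublets. Conversely, very unbalanced doublets (one member
contributing < θ of the UMIs) are missed; under the default
negative-binomial depth model the contribution split is approximately
Beta(2, 2), so ~6% of cross doublets escape the 10% threshold. The
net effect is a mild overestimate, inside the ±20% band the recovery
experiment checks, and the estimator is applied to unfiltered barnyard
records: gene-count filtering before estimation would preferentially
retain (deeper) doublets and bias the rate upward much more strongly.

# Saturation analysis

`saturation()` downsamples the read-assignment table (not the raw
FASTQ — equivalent, since every retained read appears exactly once in
the table) at fractions 10/25/50/75/100%, re-collapses UMIs, and
reports median UMIs and genes per cell over the *fixed* barcode set
called at full depth. A single permutation under the run seed makes
the subsamples nested, so per-cell counts are non-decreasing in the
fraction read-by-read; the suite asserts this cell-by-cell. (With
edit-distance collapse the subset property is not a mathematical
certainty — removing an absorbing UMI could in principle split its
absorbed neighbors — but with 10-nt UMIs the configurations that break
it have probability ~$10^{-5}$ per pair and do not occur at these
scales.)

# Label transfer

`label_transfer()` implements correlation-based transfer from an
annotated reference: counts-per-10,000 + log1p normalization on both
matrices, features = the reference's `n_features` most variable genes
intersected with the query, Pearson correlation of every query cell
against all reference cells and all other query cells, and top-k means
(k = 20 by default, the reference neighborhood size). The label is the
majority among the top-k reference neighbors; a cell is *assigned*
when its reference score exceeds its self score by more than `margin`.

The transfer rule this mirrors states its acceptance cutoff as an
"absolute difference > 1", which cannot literally apply to
correlations bounded by 1; the intended scale is not recoverable from
the text. The margin is therefore an explicit parameter with default
0 (reference strictly better than self), and no guess is hard-coded.
The normalization applied before correlation is likewise unstated in
the source workflow; CP10K + log1p is fixed here as the field's
default. One behavioural consequence of the top-k rule worth knowing:
with many more reference than query cells, the top-k mean over the
larger pool is slightly favoured, so a pure-noise query assigns a
small nonzero fraction at margin 0; a modest positive margin removes
this.

# RNA-integrity inference

For invertebrate samples the instrument's Bayesian RIN algorithm
(trained on vertebrate traces) often fails, and the 28S "hidden break"
— natural scission of 28S into two 18S-sized fragments — deflates RIN
without true degradation. The package implements the fraction-based
workaround: `ribosomal_fraction()` computes the trapezoidal area of
the annotated 18S + 28S windows over the total trace area excluding
the lower-marker window, after subtracting a flat baseline equal to
the global minimum fluorescence. Band windows are caller-supplied
intervals, not auto-detected peaks — peak modelling is proprietary to
the instrument and out of scope. In hidden-break mode both annotated
28S fragment windows count toward the ribosomal area, which is the
point of the statistic: it is robust to the break. `fit_rin_model()`
is ordinary least squares of known RIN on fraction (≥ 3 calibration
points, non-degenerate design); `infer_rin()` clamps predictions to
the instrument scale [1, 10]. The exact calibration pairs behind the
original regression are not published, so calibration is validated by
property (parameter recovery, monotonicity along a degradation
ladder), not by numeric reproduction.

# Problem sizes and determinism

The test and acceptance experiments use desk-scale versions of the
study conditions, chosen once: a 500-cell (250 per species,
retention 1) zero-corruption run of ~100k reads for end-to-end
identity and saturation; ten replicates of 20,000 barcode-bearing
units (10,500 input cells per species) at doublet rate 0.05 for the
calibration recovery, run at count level via `simulate_counts()` —
generating FASTQ for 200,000 cells would add nothing to the estimator
under test; 10,000 corrupted barcodes and 1,000 UMI multisets for the
oracle-equivalence checks; and 20-point calibrations over ten seeds
for the RIN regression. Every stochastic stage derives its seed
deterministically from one global seed via stage-name hashing, so any
stage can be re-run in isolation and identical configurations are
byte-identical, an asserted invariant.

# Known limitations

* The read-2 segment offsets are a plausible reconstruction
  constrained by the 94-nt minimum span; the true oligo coordinates
  come from plate documentation that is not reproduced here. The
  layout object is fully configurable.
* The k-mer assigner is exact only to the extent that k-mers are
  gene-unique; on real genomes with paralogs and repeats it would
  multimap far more than on random references.
* No within-species doublet *removal* is performed — only the
  expected load is estimated, matching the ground-truthing role the
  collision count plays in the original workflow.
* Dataset-level figures of the original study (collision counts,
  per-cell UMI medians on the deposited data) depend on the deposited
  sequencing runs and are out of desk-scale scope; the package's
  claims are the property-based recoveries its tests compute.
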