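# genomewaves

Brief social interactions leave a molecular trace in the brain: waves of
transcription that rise and fall over minutes to hours, coordinated by
transcription factors and accompanied by rapid changes in chromatin
accessibility. **genomewaves** is an R package for analyzing exactly this
kind of experiment — a two-group (control vs socially challenged)
time-course design with bulk RNA-seq in one or more brain regions and
H3K27Ac ChIP-seq as an accessibility readout — and for validating every
analysis stage against synthetic data with planted ground truth.

It is aimed at behavioral and neuro-genomics groups who need the full
chain from count matrices to an integrated picture, with each statistical
step testable in isolation.

## What it computes

**Differential expression over time.** Counts are filtered (CPM ≥ 1 in
≥ 2 samples), TMM-normalized, and fitted per brain region with a
negative-binomial GLM under the nested interaction model
`~ time + treatment:time`, so the treatment coefficient within each time
level is the log2 fold change at that time. Dispersion is estimated as
common → trended → tagwise via Cox–Reid adjusted profile likelihood.
Per-time 1-df and joint 3-df likelihood-ratio tests are FDR-adjusted
together (Benjamini–Hochberg over all contrasts of a region at once);
genes whose *trajectory* is altered by the treatment (interaction
q < 0.1) form the DEGx set.

**Temporal-profile clustering.** DEGx log2 fold-change profiles are
clustered by Ward agglomeration ("ward.D" on Euclidean distances), cut
by `k` or height, and summarized into verbal response patterns such as
`"no change, down, up"`.

**Regulatory network inference.** TF → target edges require (1) mutual
information between TF and target expression significant at
P ≤ 1e-6 against a pooled permutation null with a gamma tail, and
(2) the target to be quantitatively predictable from its selected TFs —
forward-selection regression with 5-fold cross-validation — with
out-of-fold RMSD below 0.33 of the target's expression sd. Hub TFs are
the top-degree regulators (> 30 targets).

**Chromatin accessibility.** From peak tag tables: baseline-accessible
peaks (≥ 4-fold over input, exact binomial p < 1e-4) and differentially
accessible peaks (DAPs: fold > 2 between experimental and control in
either direction, p < 1e-4). Each gene gets a chromatin domain — the
union over its transcripts of ±20 kb windows truncated at any other
gene's transcripts — and peaks link to genes by any-overlap with the
domain.

**Integration.** Hypergeometric enrichment of TF targets in clusters
(TFs with ≥ 3 targets, BH-adjusted at 0.05), the DEGx ∩ DAP-gene overlap
test (DAPDEGx), and detection of genes regulated in *opposite*
directions in two brain regions at the same time point ("discordant
genes").

**Synthetic data.** `simulate_genome()`, `simulate_expression()` and
`simulate_chip()` plant temporal clusters, linear TF → target programs
and accessibility changes with full determinism given a seed, emitting
truth tables that score every downstream stage.

## Worked example

```r
library(genomewaves)

sim   <- sim_de_scenario(seed = 1, n_genes = 500)   # 10% planted, |log2FC| = 2
fit   <- fit_nested_glm(sim$cm)                     # TMM + dispersions + GLM
calls <- call_degs(fit, alpha = 0.1)
calls
#> deg_calls (diencephalon): 59 DEGx at q < 0.1; per-time DEGs: 32/30/42

precision_recall(calls$degx, sim$truth$degx)
#> precision    recall        tp        fp        fn
#>     0.847     1.000    50.000     9.000     0.000

summ <- summarize_clusters(cut_tree(ward_cluster(calls$profiles), k = 4),
                           calls$profiles)
summ$pattern
#>                     1                     2                     3                     4
#> "down, no change, up"   "up, no change, up" "down, down, no change" "no change, up, down"
```

All 50 planted trajectory-responsive genes are recovered (recall 1.0)
with 9 false calls among 59 — a realized FDR of 0.15, matching the 0.1
nominal level up to small-scenario noise — and the four cluster patterns
read back the planted response profiles.

The full chain, from simulation through the integration statistics, runs
from a single configuration:

```r
cfg <- pipeline_config(seed = 1, outdir = "gw_out")
res <- run_pipeline(cfg, "all")   # simulate, de, cluster, trn, chromatin, integrate
```

or from a shell via `inst/scripts/run_pipeline.R`. Outputs are TSV/BED/
GTF/Newick files plus a JSON manifest (config echo, seed, checksums);
reruns with the same seed are bit-identical.

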