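# rbpregulon

Post-transcriptional regulatory networks link RNA-binding proteins (RBPs)
to the transcripts they bind. A central question about such networks is
whether an RBP's own expression tracks the expression of its target
transcripts across tissues — evidence that the RBP coordinates its targets
post-transcriptionally. `rbpregulon` is an R package for that analysis:

1. **Network construction** — map CLIP-seq binding peaks into ±300 bp
   windows around exon boundaries; a transcript with ≥1 overlapping peak is
   a target of that RBP (`map_targets()`).
2. **Co-expression classification** — for each RBP, compare the Spearman
   correlations ρ(RBP, target) against ρ(RBP, non-target) across tissues
   with a two-sample Wilcoxon rank-sum test, at the transcript level (the
   RBP's highest-expressed protein-coding transcript) and the protein level
   (its protein profile over the shared tissues). Each RBP is labelled
   **SC** (significantly congruent: target correlations higher, p < 0.05),
   **SIC** (significantly incongruent: lower), or **NSC** (no significant
   change), with 100 matched-control resamples reported next to the
   full-control comparison (`run_level()`).
3. **Feature modelling** — explain the observed correlations with
   multivariate OLS, backward stepwise elimination and cross-validated
   elastic net, on an RBP-centric table (response: median target ρ; nine
   predictors) and a transcript-centric table (response: per-pair ρ; five
   predictors) (`fit_multivariate()`, `fit_stepwise()`,
   `fit_elastic_net()`, `per_rbp_transcript_models()`).
4. **Network centrality** — compare closeness and betweenness in a
   protein-interaction network between "sync" RBPs (same SC/SIC label at
   both expression levels) and the rest (`sync_partition()`,
   `centralities()`, `compare_groups()`).

A synthetic-data module (`synth_config()`, `generate_dataset()`,
`write_synthetic_dataset()`) generates exon-structured annotation, peaks,
expression matrices with planted rank correlations, a PPI graph and domain
counts, with all planted facts recorded in a truth object — so the whole
pipeline is testable end to end without any external downloads. The
`analysis/` directory holds the numbered workflow drivers
(`01_simulate.R` … `05_centrality.R`) that run these stages over the
package and write their tables under `results/`.

Intended users: computational biologists studying post-transcriptional
regulation who have per-RBP binding intervals (BED), a transcript
annotation (GTF), and transcript × tissue / protein × tissue expression
matrices.

## Worked example

The synthetic default cohort — 60 RBPs, 16 tissues (9 with protein data),
50–80 targets each, planted Spearman effect 0.7, labels split 20/20/20
into SC/SIC/NSC — exercises every stage:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_build_network.R
Rscript analysis/03_classify.R
Rscript analysis/04_feature_models.R
Rscript analysis/05_centrality.R
```

which prints (seed 1):

```
cohort: 60 RBPs, 5123 transcripts, 16 tissues (9 with protein)
planted labels (RNA): NSC 20, SC 20, SIC 20
planted targets: 3817 pairs, union of 3817 unique transcripts

network: 60 RBPs, 3817 edges, 3817 unique targets
target counts per RBP: 50-80 (median 64)
planted target sets recovered exactly: TRUE

transcript level: SC 21 / SIC 20 / NSC 19 -> 68.33% significant; planted-label accuracy 98.3%
protein level: SC 20 / SIC 20 / NSC 20 -> 66.67% significant; planted-label accuracy 95.0%

sync RBPs: 12; non-sync: 48
closeness: median sync 0.3242 vs non-sync 0.2533, p = 4.75e-07 (sync higher)
betweenness: median sync 990.6 vs non-sync 190.1, p = 2.3e-06 (sync higher)
```

Reading the numbers: peak-to-window mapping recovers the planted network
exactly (peaks were planted inside boundary windows, decoys beyond twice
the flank). The classifier recalls 59/60 planted RNA-level labels and
57/60 protein-level labels — the protein level is noisier because only 9
tissues support each correlation. The 12 RBPs planted with concordant
labels are recovered as the sync set, and their planted attachment to the
dense PPI core shows up as significantly higher closeness and betweenness.
The feature-selection stage finds per-feature significance fractions near
the 0.05 type-I level, as it should: this cohort plants correlation
structure, not feature effects (see `vignettes/methods.Rmd`).

The same stages run over real data by replacing the files under
`results/synthetic_inputs/` (GTF, per-RBP BED files, expression TSVs, PPI
edge list, domain counts) — or in one call with
`run_pipeline(input_dir, out_dir)`, which also writes a run manifest with
config and file hashes.

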