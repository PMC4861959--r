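---
title: "Methods: RBP-target co-expression classification and its models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RBP-target co-expression classification and its models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

RNA-binding proteins (RBPs) regulate the fate of their target transcripts
post-transcriptionally. If an RBP stabilizes (or degrades) the transcripts
it binds, its own expression should co-vary positively (or negatively) with
its targets' expression across tissues, more strongly than with transcripts
it does not bind. `rbpregulon` implements that test genome-wide: it builds
an RBP-to-target network from CLIP-seq binding sites, classifies each RBP
by the tissue co-expression of its targets relative to non-targets, models
which features explain the observed correlations, and asks whether RBPs
with concordant behaviour across expression levels occupy more central
positions in the protein-interaction network.

# Target-network construction

All intervals are held internally as 0-based half-open coordinates (the BED
convention); GTF input (1-based inclusive) is converted once at the reading
boundary, so the window arithmetic below lives in a single convention.

A transcript is a **target** of an RBP if at least one of the RBP's peaks
shares at least one base with a window of `flank` bp (default **300**, the
distance scale at which RBP binding concentrates around splice sites)
around any exonic start or end coordinate of the transcript. For an exon
`[s, e)` the two windows are `[max(0, s - flank), s + flank + 1)` and
`[max(0, e - 1 - flank), e + flank)` — symmetric around the first and last
exonic base. Design choices made where the procedure was genuinely open:

* *Symmetric windows.* Descriptions of this rule oscillate between
  "flanking" and "downstream" regions; the symmetric +/-300 bp window is
  the union of those readings and the most permissive consistent one.
  `flank` is a parameter, so stricter variants are recoverable.
* *Overlap, not containment.* One shared base suffices; no
  minimum-overlap fraction is imposed.
* *Strand is ignored by default.* CLIP peak strand annotation is often
  absent (`.`); `respect_strand = TRUE` restores strand matching.
* *Self-targets are kept.* An RBP binding its own transcripts stays in its
  target set; `exclude_self = TRUE` removes them for sensitivity analysis.

The implementation rides on `GenomicRanges::findOverlaps`; its correctness
contract is exact equality with a brute-force all-pairs overlap check,
enforced in the test suite on random instances.

# SC / SIC / NSC classification

For each RBP at the **transcript level**, the RBP profile is its gene's
protein-coding transcript with the highest mean expression across all
tissues (ties broken lexicographically — deterministic). At the **protein
level** the profile is the RBP's row of the protein matrix (per-tissue
maximum when isoform rows exist), and target/control profiles come from
the RNA matrix restricted to the tissues shared by both matrices; RBPs
without a protein row are skipped and reported.

Spearman correlations (average ranks for ties) are computed between the
RBP profile and every expressed target (the *target* set), every expressed
non-target (*control-all*), and `n_reps = 100` random non-target samples of
target-set size (*control-matched*). The target and control rho
distributions are compared with a **two-sample Wilcoxon rank-sum test**
(normal approximation with tie correction, two-sided). The compared vectors
are unpaired and of unequal length, so the rank-sum variant — not the
signed-rank one — is the only applicable reading of "Wilcoxon test".

Labels at threshold `alpha = 0.05` (raw, no multiple-testing correction;
a Benjamini-Hochberg column is emitted alongside for users):

* **SC** (significantly congruent): `p < alpha` and median target rho
  above the control median;
* **SIC** (significantly incongruent): `p < alpha` and median below;
* **NSC** otherwise.

The final label is decided against *control-all*; the 100 matched-control
p-values are summarized by their median and by the fraction of matched
comparisons agreeing with the final label. This precedence is a documented
configuration choice: the matched resamples guard against control-set-size
artefacts but each has less power than the full control set.

Reproducibility: one master seed governs all matched sampling, and each
RBP's stream is derived deterministically from `(seed, rbp_id)`, so results
do not depend on the order in which RBPs are processed.

Transcripts absent from the expression matrix are dropped from every
category before any statistic; rows with fewer than 3 complete tissue pairs
or constant profiles are excluded and counted.

# Feature modelling

Two feature tables explain the observed correlations:

* **RBP-centric** — one row per RBP; response = median target rho;
  predictors: number of targets, median binding p-value of supporting
  peaks ("CLIP signal"), number of RNA-binding domains, PPI degree, number
  of protein-coding and of all annotated transcripts of the RBP gene,
  length of the selected transcript, median distance from peak start to the
  closest transcript end, and the RBP's mRNA-protein Spearman correlation
  over shared tissues.
* **Transcript-centric** — one row per RBP-target pair; response = the
  pair's rho; predictors: binding p-value, distances of the peak start
  from the 5' and 3' transcript ends (strand-aware, genomic-span
  coordinates), transcript length and biotype. When several peaks support
  one pair, the one with the smallest p-value is used.

Distances use the genomic span of the transcript rather than spliced
(mRNA) coordinates: "either end of the transcript" does not disambiguate
the two, and the genomic reading requires no exon projection; it is the
documented default. Missing domain/PPI/protein entries become 0 with a
provenance flag rather than NA — this keeps the design full-rank and the
imputation auditable.

Three procedures are applied:

1. **Multivariate OLS** (`lm`), with two-sided t-test p-values. A
   categorical feature's significance is the minimum of its BH-adjusted
   indicator-contrast p-values, giving one p per feature.
2. **Backward stepwise elimination**: iteratively drop the feature with the
   largest marginal p-value (single-term F test) while it is at or above
   `alpha_stay = 0.05`; ties break alphabetically, so the path is
   deterministic and invariant to column order. This mirrors
   p-value-threshold stepwise selection rather than AIC-based `step()`.
3. **Elastic net** (`glmnet`): predictors standardized, response centered;
   the mixing parameter (grid `0, 0.25, 0.5, 0.75, 1`) and penalty are
   chosen by 10-fold cross-validated MSE with seed-fixed folds. "Selected"
   means a nonzero coefficient; penalized fits carry no p-values, so
   selection is reported in a separate column. The grids and CV scheme are
   package defaults — the procedure they tune was described without them.

Per-RBP transcript-centric models need at least `p + 2` pairs; smaller
RBPs are skipped and reported. Biotype levels observed once within an RBP
are merged into `"other"` so contrasts stay estimable.

# PPI centrality of sync RBPs

An RBP is **sync** when it earns the same significant label at both levels
(SC/SC or SIC/SIC). Closeness centrality uses the classical definition with
the Wasserman-Faust component scaling,
`closeness(v) = (k / sum d(v,u)) * (k / (n - 1))` over the `k` reachable
nodes — well-defined on the disconnected graphs real PPI data produce
(isolated nodes score 0); a harmonic variant is available by flag.
Betweenness is the standard shortest-path count, reported unnormalized with
a normalized column alongside. Both are checked for exact equality against
an all-pairs BFS oracle. Group comparison is the same two-sided rank-sum
test as the classifier.

# The synthetic-data generator

The generator emulates the *shape* of the real inputs so every stage is
testable without downloads: an exon-structured GTF (1-10 exons, 100-500 bp,
loci separated by >= 3 kb so windows of different loci never interact),
per-RBP BED peaks, a transcript-by-16-tissue TPM-like matrix, a
gene-by-9-tissue protein matrix (the 9 tissues are a subset of the 16), a
PPI edge list and domain counts. Default conditions: **60 RBPs**, 50-80
planted targets each (disjoint across RBPs so every planted correlation is
unambiguous), planted effect **0.7**, labels split evenly into SC/SIC/NSC
at the RNA level with 6 SC/SC and 6 SIC/SIC RBPs kept in sync at the
protein level (12 sync RBPs; the remaining significant RBPs flip
direction). Peaks supporting planted pairs are placed inside a boundary
window; decoys go to inter-locus gaps, more than `2 * flank` from every
boundary, so the planted network is recovered exactly by construction.

Correlation is planted on ranks: targets couple to a latent factor through
a Gaussian copula with latent Pearson `2*sin(pi*rho/6)`, making the
population Spearman equal the requested `effect_rho` directly (the
statistic the pipeline uses); the monotone `exp()` map to positive
TPM-like units leaves Spearman untouched. The shared factor equals the
RBP's own profile (signed by the RNA-level label) for significant RBPs;
the protein profile couples to the same factor with the protein-label
sign, which lets the two levels disagree. Doubly-NSC RBPs get mutually
independent targets — a shared factor would shift all their correlations
by its chance correlation with the RBP and inflate false positives.

What the generator does **not** emulate: tissue-specific expression
programs, shared targets between RBPs, peak-strength biology (binding
p-values are decorative log-uniform draws), library-size or
zero-inflation artefacts of real RNA-seq, and any planted relationship
between the feature-table predictors and the response. Passing tests
therefore demonstrate the statistical machinery is correct and calibrated,
not that real data meet its assumptions; on the default cohort the feature
models should and do find per-feature significance fractions near the
type-I level.

With the PPI core planted (`plant_ppi_core = TRUE`), sync RBPs attach to a
dense 8-hub core, elevating their closeness by construction; with planting
off, group comparisons are null.

# Numerical choices and degenerate inputs

* Identical rho multisets give rank-sum p = 1 (NSC); vectors shorter than
  2 yield NSC with an `insufficient_data` flag.
* A constant response pins all regression p-values at 1 (the t statistics
  are 0/0 there).
* Rank-deficient designs are an error naming the collinear columns, never
  a silent drop.
* The elastic net at `lambda -> 0` must match OLS on standardized data
  within 1e-6 and at large `lambda` shrink every coefficient to zero;
  both limits are asserted in tests.
* A 1-bp exon yields two near-identical windows; windows are clipped at
  the chromosome origin.
* Matched sampling with a control pool smaller than the target set is an
  error; a pool exactly as large means every sample is the full pool.

# Problem sizes used in the checks

The test suite and the acceptance script run on sizes chosen to make the
statistical assertions meaningful while staying desk-scale: the default
60-RBP cohort (about 5,100 transcripts) for label recovery; a 200-RBP
all-NSC cohort (about 6,400 transcripts, 20-30 targets each) for type-I
calibration, where the tolerance is 3 binomial standard deviations around
`alpha`; 100 random instances for the interval-overlap oracle; graphs of
up to 50 nodes for the centrality oracle; and 100 seeded replicates for
the stepwise retention rates. Matched-control resamples are reduced from
100 to 2-10 in checks whose measured quantity does not depend on them (the
final label uses the control-all comparison).

# Known limitations

* The SC/SIC/NSC label treats co-expression as evidence of regulation;
  it cannot distinguish direct regulation from shared upstream drivers.
* Protein-level classification rests on 9 tissues; single-RBP calls at
  that sample size are noisy even with a strong planted effect, and the
  per-RBP Spearman estimates have sd around 0.3.
* Distances to transcript ends use genomic span, not spliced coordinates
  (see above); both are defensible and differ for multi-exon transcripts.
* No multiple-testing correction is applied to the headline labels, by
  design parity with the procedure being reproduced; the BH column is the
  conservative alternative.
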