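---
title: "Methods: scoring transcriptome masculinization across a morph continuum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring transcriptome masculinization across a morph continuum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimorphix)
```

This vignette is the package's own account of its statistical machinery: the
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical choices that a maintainer would otherwise have to
reverse-engineer from the code.

## The scientific question and the measurement problem

The design compares three sexual morphs — females, subordinate males and
dominant males — in a strongly dimorphic tissue (gonad) and a weakly
dimorphic one (spleen). If sex-biased expression encodes dimorphic
phenotypes, the intermediate male phenotype should be intermediate in
transcription: male-biased genes expressed below the dominant-male level
(demasculinization) and female-biased genes above it (feminization).

The central measurement hazard is that RNA-seq is *relative*: every FPKM
value is a share of a finite read total. If one morph genuinely
down-regulates a large class of genes (say, male-biased genes in
subordinates), every other gene's relative expression in that morph rises
mechanically. An apparent feminization can therefore be an arithmetic shadow
of a real demasculinization. Two of the three controls in this package exist
for exactly this reason.

## Expression processing

* **Expression filter** (`filter_expressed`): a gene is kept when, in at
  least one morph (within a tissue), at least half of that morph's samples
  reach 4 reads per million mappable reads. The group-wise form (rather than
  "half of all samples") deliberately keeps morph-limited genes, which the
  presence analysis needs. Both the threshold (reads per million) and the
  group fraction are arguments.
* **FPKM** (`compute_fpkm`): `count × 10⁹ / (library_size × exonic_length)`.
  The library size is the *total mappable reads* from the sample sheet, not
  the column sum of the (already filtered) matrix; the column sum is only a
  fallback when no totals are supplied. Log expression is
  `log2(FPKM + 1)` by default, so a zero count maps to 0; the pseudocount is
  an argument (units: FPKM).
* **Morph means** (`morph_means`): per-gene arithmetic means of log2
  expression over exactly the samples of each morph and tissue. All
  downstream morph comparisons are across *genes* on these per-gene means.

Tissues are processed independently throughout; nothing is normalized across
tissues.

## The negative-binomial test

`nb_test` reimplements the classic conditioned exact test for two groups of
count libraries:

1. **Size factors**: median over genes (restricted to genes positive in
   every sample) of the ratio of a sample's count to the gene's geometric
   mean; upper-quartile ratios are a fallback (with a warning) when no gene
   is everywhere-positive.
2. **Dispersion**: per-gene method of moments on pooled within-group
   variance of normalized counts (shot noise subtracted), then a parametric
   trend `α(μ) = a0 + a1/μ` fitted by a Gamma GLM with one
   outlier-trimmed refit. When the mean range spans less than a decade the
   `1/μ` term is unidentifiable and the trend collapses to a winsorized mean
   (95th percentile cap) — isolated high-dispersion genes must not drag the
   trend.  Three sharing modes are exposed: `"trend"` (fit-only, default),
   `"max"` (larger of gene-wise and trend; conservative), `"gene"`.
   The default is fit-only because, in replicated designs, it holds the
   empirical type-I error at the nominal level (the conservative `"max"`
   rule under-rejects at small n, and raw gene-wise estimates over-reject;
   the acceptance suite pins the default's calibration to 0.03–0.07 at
   α = 0.05). With no replicates anywhere, variance is pooled across all
   samples ("blind").
3. **Test**: given the total `kS = kA + kB`, the two group sums are modelled
   as negative binomial with a common per-gene mean (pooled normalized mean
   scaled by each group's size-factor totals) and the estimated dispersion;
   the two-sided p sums the probabilities of all splits no more likely than
   the observed one. For totals above `exact_total_limit` (default `1e4`) a
   Gaussian conditioning approximation on `kA | kS` with continuity
   correction is used; its error on p is well under the decision thresholds
   used anywhere in the pipeline (~1% relative at the default limit).
   All-zero genes get p = 1 by definition.

## Classification and quartiles

`classify_sex_bias` calls a gene male-biased when it is at least
`fc_threshold`-fold higher in the male reference than in females with
Benjamini–Hochberg adjusted p < α, and symmetrically for female-biased.
Defaults: two-fold, α = 0.05, dominant males as reference (subordinate or
pooled males are options, used to show the conclusions do not depend on how
bias is defined). Adjustment and thresholding run separately for autosomes
and Z: incomplete avian dosage compensation gives Z-linked genes a baseline
male shift, so pooling the two classes would misstate both.

The reported `log2fc` is computed from group-mean normalized counts with a
0.5-count pseudocount — finite even for morph-limited genes — and is oriented
male-positive.

`quartile_bins` ranks *all* significant genes (fold-change criterion
dropped — restricting quartiles to two-fold genes would discard exactly the
moderately biased genes whose gradient is of interest) by |log2fc| within
direction and chromosome class; quartile 4 is most biased; ties break
lexicographically by gene id so binning is deterministic.

## Morph scoring

* `demasc_fem_test`: two-sided Wilcoxon on per-gene (subordinate −
  dominant) means for the selected set. The signed-rank (paired) form is the
  default because the gene set is identical in both morphs — pairing by gene
  is the natural structure; an unpaired rank-sum option exists. Direction
  labels require both p < 0.05 and the correct sign.
* `decoupling_regression`: OLS of (dominant − subordinate) on the signed
  female-oriented bias degree over all sex-biased genes; reports slope, r²
  and the slope's p. A degenerate all-zero response returns slope 0, r² 0.
* `slope_compare`: the same regression per chromosome class restricted to
  male-biased genes, with 95% t-intervals and an overlap flag — the test of
  whether the Z chromosome contributes disproportionately.
* `spearman_morph_matrix` + `fisher_rz`: rank correlations between morph
  mean vectors; contrasts compared by `z = Δ atanh(ρ) / √(1/(n₁−3) +
  1/(n₂−3))`.
* `presence_venn`: "expressed to some degree" defaults to ≥ 1 read in at
  least half a morph's samples; rule parameters are exposed. The partition
  can also be built directly from printed region counts
  (`venn_partition`). `shared_gene_ztest` uses the pooled-variance
  two-proportion z; the candidate pools default to the expressed-gene
  universe of each comparison, since nothing in the design fixes a narrower
  denominator.

## Controls

**Renormalization** (`renormalize_without_malebiased`) removes male-biased
genes' counts from every sample, recomputes library sizes as the remaining
totals, and re-derives FPKM. This approximates re-mapping the read pool
without those genes: at gene-level counting, removing rows and shrinking the
totals is exact up to multimapping redistribution, which is negligible here
and out of scope. Non-male-biased counts are conserved bit-exactly, and the
new totals equal the originals minus the male-biased column sums — both are
tested invariants. If feminization survives this control it is not a
compositional artifact.

**Resampling null** (`rtm_randomization`) guards against regression toward
the mean: genes selected as extreme on a subset of samples will look less
extreme on held-out samples even under the null. Each iteration defines bias
on a random trio of dominant males and trio of females, then tests (a)
defining vs held-out samples of the same morph — a pure
regression-toward-the-mean read-out — and (b) subordinates vs held-out
dominants, on each newly defined gene set. Both raw and per-iteration
Bonferroni-adjusted p-values are recorded: the Bonferroni column is what the
original design reports, while raw rates are what a calibration claim about
a single null contrast refers to (any multiplicity factor pushes a true
null's adjusted rate far below its nominal level, so "≈ α under the null"
is only meaningful raw). One caution worth stating: because the subordinate
group is identical across iterations, iteration outcomes are positively
correlated; calibration statements should pool iterations across independent
datasets, not lean on many iterations of one dataset.

**Motif proximity** (`annotate_motifs`, `motif_bias_tests`): binding sites
are reduced to midpoints; a gene is flagged for window *w* when the nearest
strictly-upstream midpoint (5′ of the TSS on the gene's strand) lies within
(TSS − w, TSS). Flags are monotone across the 2/5/10 kb windows by
construction. The enrichment test is a one-sample two-sided proportion z
against the genome-wide male-biased fraction (the two-proportion variant
differs negligibly at these set sizes and the one-sample form matches a
fixed published baseline); the expression test is a permutation p for the
flagged set's mean subordinate-vs-dominant fold change against equal-sized
uniform gene sets, two-sided around the overall mean with add-one
correction, so p ∈ [1/(B+1), 1].

## Category-level dN/dS

Per-gene ratios explode when a gene has no synonymous substitutions; summing
first avoids that while weighting genes by alignment length:
`dN = Σ(N·dn)/ΣN`, `dS = Σ(S·ds)/ΣS`, ratio `dN/dS` of the sums. Records are
pre-filtered: dS > 2 (mutational saturation), gapless length < 100 bp
(boundary inclusive: exactly 100 bp is kept), in-frame stops,
retrotransposons. Confidence intervals are nonparametric gene-level
bootstrap percentile intervals (1000 replicates by default) — the interval
method for such aggregates is not canonical, so the point estimate and the
bootstrap interval are reported side by side and labelled. Degenerate
resamples with zero synonymous mass are skipped and counted. A minimal
parser for codeml branch-table output is included, but the documented TSV is
the canonical input.

## Structure summaries

Hierarchical clustering uses Euclidean distance with complete linkage on
morph mean-expression vectors (or samples, given a full expression matrix).
Node support is the plain bootstrap proportion: genes resampled with
replacement, trees rebuilt, and each original clade scored by the percentage
of replicates containing the same leaf set. Multiscale/AU corrections are
out of scope. Trees export to Newick with support as internal node labels.

Factor analysis treats samples as variables and genes as observations —
diagnostics (inter-sample correlations, Bartlett sphericity on the sample
correlation matrix, KMO from anti-image partial correlations; pseudo-inverse
with a flag if the correlation matrix is singular) and the sample loadings
plot both refer to samples, and with genes as observations the
maximum-likelihood fit (`factanal`) is well-posed. The factor count defaults
to the smallest number reaching 95% cumulative eigenvalue share, capped by
the degrees-of-freedom limit; rotation is off by default (varimax optional).

## The synthetic-data generator

`simulation_config()` defaults define the study conditions the analysis
assumes:

| parameter | default | rationale |
|---|---|---|
| `n_genes_autosome`, `n_genes_z` | 10 000, 360 | expressed-gene counts of a strongly dimorphic gonad transcriptome on a ZW genome |
| `frac_male_biased`, `frac_female_biased` | 0.22, 0.29 | realized gonad bias fractions at two-fold, adj. p < 0.05 |
| `effect_min_log2`, `effect_scale_log2` | 1.2, 0.8 | biased genes sit clear of the two-fold call threshold with an exponential tail (mean ≈ 4-fold) |
| `demasc_d`, `fem_f` | 0.4, 0.4 | moderate subordinate displacement on the log2 continuum |
| `dispersion` | 0.1 | typical biological CV (~32%) for outbred vertebrate RNA-seq |
| `depth`, `depth_cv` | 26 × 10⁶, 0.2 | mappable read pairs per library and lane-to-lane spread |
| `n_per_morph` | 6 | a realistic per-morph cohort; the design itself does not fix one |
| `z_dosage_offset_log2` | 0.5 | incomplete avian dosage compensation (~1.4-fold male excess) |
| `tissue_bias_scale` | 0.3 | somatic bias is a fraction of gonadal bias |
| `baseline_log2_mean/sd` | 4, 2 | log-normal baseline expression; heavy right tail on the natural scale |

Two design decisions matter most:

* **Bias is created by reducing the opposite sex.** A male-biased gene keeps
  the shared baseline in males and is *reduced* in females (`−e` log2), and
  vice versa — matching the observation that increasing sex-bias is driven
  mainly by reduced expression in the unbiased sex rather than elevated
  expression in the biased one. This also keeps the morphs' total
  transcriptional mass nearly equal, so compositional shifts are present but
  realistic in size.
* **Counts are compositional.** Expected counts are `library size ×
  (expression × length share)`: sequencing depth is fixed per sample
  regardless of the underlying absolute transcription, exactly as in real
  RNA-seq. This is what makes the renormalization control demonstrable: with
  pure demasculinization (`d > 0, f = 0`) the female-biased set shows a
  significant apparent up-shift in subordinates that vanishes after
  male-biased reads are removed. The sample sheet's `library_size` is the
  drawn depth, not the realized column sum: real totals are spread over far
  more genes than a desk-scale simulation carries, so per-gene noise in a
  real total is negligible, and normalizing by the realized sum of a few
  hundred simulated genes would inject a shared large-gene noise term that
  full-scale data does not have.

The subordinate mean follows
`log2 μ_sub = log2 μ_dom − d·(log2 μ_dom − log2 μ_fem)` (displacement on the
log scale, so the `d = 1` endpoint lands exactly on the female mean);
`quartile_coupling = TRUE` optionally scales `d` with the gene's effect rank
to produce a monotone quartile gradient — off by default, since constant
displacement and rank-coupled displacement are separate mechanisms and the
default should not conflate them. Z-linked genes add the dosage offset to
both male morphs. Binding sites are placed upstream of a configurable
fraction of male-biased (35%) and other (10%) genes at uniform distances
within 10 kb; genes sit 50 kb apart on per-class pseudo-chromosomes so
windows never straddle neighbours. Divergence records draw per-category
gamma-distributed rates (male-biased fastest), with small planted fractions
of saturated, stop-containing, retrotransposon and short alignments for the
filters to catch.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: no on/off (truly morph-limited) genes, so
presence partitions are only exercised on shallow or hand-made data; no
gene–gene correlation, GC/length biases, batch effects or isoform structure;
dispersion is constant rather than mean-dependent (a trend option exists);
and motif placement is independent of expression, so motif tests are
calibrated under their null rather than under a planted regulatory signal.

`recover_continuum` estimates `d` as the median over classified male-biased
genes of `(dom − sub)/(dom − fem)` on morph means (female-biased genes give
`f`), using only genes with a dominant–female gap above 0.5 log2 units —
smaller gaps make the ratio numerically unstable — and clipping per-gene
ratios to [−0.5, 1.5] (clip fraction reported). Because FPKM is relative,
the morph-specific total-mass constants bias this estimator slightly
downward (≈ −0.04 under default conditions); the acceptance tolerance of
±0.1 absorbs this known, documented bias rather than hiding it by
normalizing the simulation unrealistically.

## Problem sizes used by the test suite

Checks run at sizes chosen so each statistical claim is testable at desk
scale: full 10 360-gene transcriptomes for displacement recovery (10 seeds);
2 000 null genes × 10 seeds for type-I calibration; a 450-gene transcriptome
for the renormalization control, where the pre-control artifact (~0.19 log2)
is detected with certainty while post-control residuals — the small
regression-toward-the-mean and missed-gene remainders that any finite-power
classification leaves — sit below the paired test's detection threshold; and
30 (null) / 10 (displaced) independent datasets × 5 iterations for the
resampling control, pooled across datasets because iterations within one
dataset share samples and are therefore correlated.

## Known limitations

* The NB test covers pairwise contrasts only; multi-factor GLM designs are
  out of scope by design.
* Library-size semantics matter: passing filtered column sums as mappable
  totals will modestly inflate FPKM; supply true mapped-read totals.
* Bootstrap CIs for dN/dS are percentile intervals; no BCa correction.
* The permutation null for motif tests matches set size only (no
  expression- or length-matching).
* `parse_codeml` handles the branch-table layout only and leaves gapless
  length `NA`; length filtering must then rely on upstream information.
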