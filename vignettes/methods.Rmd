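---
title: "Methods: co-expression modules, motif scanning, regulatory networks and Ks epoch dating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression modules, motif scanning, regulatory networks and Ks epoch dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`coexreg`, the assumptions behind them, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## The scientific setting

Plant TCP transcription factors — a family defined by a non-canonical
basic helix-loop-helix DNA-binding domain — divide into two classes with
distinct GC-rich binding preferences; class II proteins favour the
consensus GTGGNCCC. Under abiotic stress (cold, heat, salt, drought),
some family members are strongly induced in specific tissues, and a
natural analysis couples three strands of evidence: (i) co-expression
modules correlated with stress conditions, (ii) promoter scanning for
the binding consensus among a focal factor's co-expression partners, and
(iii) the duplication history of the family, dated by synonymous
divergence (Ks) of collinear duplicate pairs. `coexreg` implements that
workflow as reusable, testable components driven by a truth-annotated
simulator.

## Co-expression modules

### Model

Expression is analysed on the `log2(TPM + 1)` scale (the pseudocount
guards against zeros; a pure `log2` transform is available when inputs
are strictly positive). For genes `i, j` with Pearson correlation
`r_ij` over all samples, the unsigned adjacency is `a_ij = |r_ij|^beta`.
The topological overlap

    TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)

(`k_i` the connectivity `sum_{j != i} a_ij`) measures shared
neighbourhood; genes are clustered by average linkage (UPGMA) on
`1 - TOM`. Correlations are computed across all samples jointly (tissues
pooled), mirroring a single network over all conditions; a sample subset
can be passed instead.

### Soft threshold

`beta` is chosen from the grid 1–20 as the smallest value whose
scale-free topology fit reaches R² ≥ 0.8; if none does, the argmax. The
fit regresses `log10 p(k)` on `log10 k` over 10 equal-width connectivity
bins. With a few hundred genes this R² curve is noisy, so the first
crossing can land anywhere in roughly 4–20 on simulated data; the chosen
value and the full diagnostic table are stored in the fit object so the
selection is always reproducible after the fact, and `beta` can be fixed
by hand.

### Module detection

Candidate modules are branches of the dendrogram below a static cut at
`cut_height_frac` (default **0.90**) of the maximum merge height;
branches smaller than `min_module_size` (default **10**) are left
unassigned. The fraction-of-tree-top form, rather than a quantile of the
merge heights, is deliberate: TOM dissimilarity between unrelated genes
concentrates within a percent or two of the tree top (chance-level
attachments sit near 0.98 of it in our simulations, while within-module
merges finish below ~0.8), so a cut at 0.90 excludes chance attachments,
and — crucially — under a null dataset with no planted structure *all*
merge heights sit above the cut, so every gene is left unassigned
instead of being absorbed into one spurious giant module. A cut defined
as a high quantile of the merge heights cannot achieve this: under the
null, any quantile is itself a near-1 height and everything clusters.

Surviving modules are then merged bottom-up while the eigengene
dissimilarity `1 - cor(ME_a, ME_b)` of the closest pair is below
`merge_cut_height` (default **0.2**, i.e. eigengene correlation > 0.8),
recomputing eigengenes after every merge. We read the conventional
"cut height 0.2" parameter as this eigengene merge height — its
canonical role in the field's reference implementation — rather than as
a dendrogram cut height; both readings are representable since the
dendrogram cut is exposed separately.

### Eigengenes and traits

A module eigengene is the first right singular vector of the
gene-standardised (zero mean, unit variance per gene) module submatrix,
unit-norm, with its sign fixed so the mean correlation with member genes
is nonnegative. This makes outputs bit-reproducible given input order;
all remaining ties (cluster labelling, merges) break on the lowest gene
index. Module–trait association is the Pearson correlation of each
eigengene with each binary condition indicator (one per observed
tissue × stress × timepoint combination), with the two-sided p from
`t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.

## Promoters and motif scanning

Promoters are the `window` bases (default **1000**) immediately upstream
of the translation initiation site, read 5'→3' on the coding strand,
excluding the TIS base itself: `[tis - window, tis - 1]` on `+`, the
reverse complement of `[tis + 1, tis + window]` on `−` (1-based,
inclusive, as in GFF3). Promoters running off a chromosome end are
truncated and flagged, never padded — the conservative reading of a
"1-kb upstream" window. The TIS comes from annotation coordinates, not
from ATG scanning.

The scanner matches an IUPAC consensus (default **GTGGNCCC**) with a
mismatch budget (default **1**). Degenerate codes are true wildcards for
their nucleotide set and never consume the budget; an `N` in the
*sequence* at a constrained position counts as a mismatch
(conservative). Both strands are scanned by default — binding sites are
conventionally counted on either strand, and the choice is switchable —
and overlapping occurrences are all counted, since "at least two sites"
is a count of matches and no merging rule is natural. At budget 1 the
default consensus accepts 88 of the 65,536 possible 8-mers (4 exact
instances × the N position, plus 7 constrained positions × 3 substitutes
× 4), a count the test suite re-derives by exhaustive enumeration.

## Regulatory network

Co-expression partners of the focal gene satisfy the strict inequalities
`|r| > 0.7` and `p < 1e-4` (defaults), over all samples by default;
whether control samples belong in the correlation panel is
study-specific, so the sample subset is an argument. Genes constant over
the selected samples cannot be tested and are skipped (counted in the
result's attributes); a constant focal gene is an error. Targets are
partners with ≥ `min_sites` (default **2**) promoter sites; a curated
whitelist of stress-relevant genes qualifies with a single site. Edges
are directed focal → target, signed by the correlation (activating /
repressing); no attempt is made to distinguish direct from indirect
regulation. The run report carries the member count, the motif-positive
count and fraction, and the ≥ 2-site count.

## Ks estimation and epoch dating

Synonymous divergence is estimated by Nei–Gojobori (1986) counting:
per-codon synonymous site fractions are the fraction of
single-nucleotide neighbours preserving the amino acid (mutations to
stop codons count as nonsynonymous), averaged over the two sequences;
differences between codons differing at k positions are averaged over
all k! substitution orderings, excluding orderings that pass through a
stop codon (if all are blocked, the average is taken without the
exclusion); `pS = Sd/S` is corrected by Jukes–Cantor,
`Ks = -(3/4) ln(1 - 4 pS / 3)`, with a saturation flag when `pS ≥ 3/4`.
NG86 is used instead of the kappa-aware YN estimator because it is fully
specified, exactly testable against a brute-force pathway enumerator,
and adequate for epoch *binning*; a codon-model ML estimator is a
non-goal.

Epoch bins are configuration, not inference: published Ks ranges for the
*Populus* duplication waves (recent WGD ~0.17–0.31; ancient ~3.43–4.66)
are observed ranges, not boundaries, so the defaults are generous
half-open intervals containing them — rWGD [0.10, 0.50), γ-WGT
[0.90, 2.20), ancient [3.00, 5.00) — and saturated or out-of-interval
pairs are reported as unassigned. Note that true Ks near 4 sits at the
edge of what JC-corrected NG86 can resolve: a substantial fraction of
such pairs saturates (`pS` near 3/4), which the pipeline reports
honestly rather than extrapolating.

## DEG consensus and qPCR

A gene is a DEG when at least `min_methods` (default **2**) of the
supplied per-method tables report adjusted p < 0.05 (strict) and
|log2 fold change| ≥ 1 (the universal reading of "fold change ≥ 2"), and
the supporting methods agree in sign. The direction-agreement
requirement is our addition — a "DEG" with conflicting signs across
methods is uninterpretable — and can be switched off. Benjamini–Hochberg
adjustment is exposed for tables that arrive with raw p-values.

Relative qPCR quantification follows 2^−ΔΔCt: per biological replicate,
ΔCt is the target Ct minus the *mean* Ct of the reference genes
(arithmetic mean of Ct ≡ geometric mean on the expression scale — the
standard convention when several reference genes are listed without an
aggregation rule), and ΔΔCt centres on the mean ΔCt of the control
group rather than a single calibrator sample. Group comparisons use
Student's pooled t by default (Welch available); a noise-free group
cannot be tested and reports NA rather than an infinite t.

## The synthetic-data generator

The generator defines the study conditions; its defaults are fixed, not
tuned per run.

* **Design**: 3 tissues (leaf, stem, root) × {control, cold, heat,
  salt} × 24 h × 2 replicates = 24 samples. Drought and a 7 d timepoint
  — present in the emulated study — are expressible through the `design`
  argument but kept out of the default to keep the default sample count
  at the 24 used throughout the validation suite.
* **Modules**: three planted modules (30, 25, 20 genes) following the
  indicators leaf-cold, root-salt and stem-heat, with per-gene loadings
  in (0.8, 1], amplitude 3 log2 units (≈ 8-fold — a realistic strong
  stress induction), residual noise sd 0.25 on the log2 scale, baselines
  uniform in log2 [3, 8]. Expression is built on the log2 scale and
  exponentiated, which makes the planted correlation structure
  analytically controllable; at zero noise, member correlations are
  exactly 1 on the log2 scale.
* **Promoter sites**: background sequence is i.i.d. uniform ACGT with
  rejection-resampling of any window matching the consensus within the
  budget on either strand (including windows spanning junctions), so the
  emitted site truth table is exact. Planted sites are concrete
  consensus instances, optionally with exactly one mismatch at a
  constrained position, placed non-overlapping on the configured strand
  and re-verified by a full two-strand scan. Genes 2–13 of the first
  module carry 2 sites each (the planted network targets), 14–19 carry
  one, and five background genes carry one — so the end-to-end network
  test has true targets, near-misses and decoys.
* **Codon pairs**: an ancestral stop-free codon sequence (300 codons by
  default) evolves along two branches by uniform single-nucleotide
  substitutions with stop rejection until each branch accrues half the
  target number of synonymous changes per (ancestral) synonymous site.
  No transition/transversion bias is modelled, deliberately: the uniform
  process matches the Jukes–Cantor correction downstream, so recovery
  tests probe the counting machinery rather than a mutation-model
  mismatch. The default pair set mirrors the three duplication waves:
  14 pairs at true Ks 0.25, 7 at 1.5, 9 at 4.0. Realized substitution
  counts are stored as truth.
* **Ct tables**: Ct = per-gene baseline − log2(relative abundance) +
  N(0, σ_ct), σ_ct = 0.2, three biological replicates, four
  condition-invariant reference genes, planted fold changes of 4, 2, 0.5
  and 1 across two targets and two stress groups.

All four generators are byte-deterministic given the configuration seed;
each derives its own sub-stream so stages can be regenerated
independently.

**What the simulator does not emulate** — and hence what passing tests
do not show about real data: read-level RNA-seq artefacts (the matrix is
drawn at the TPM level), realistic genome composition (background is
uniform, so motif false-positive rates are optimistic relative to GC-
and repeat-structured promoters), indels and alignment error in duplicate
pairs (pairs arrive aligned and gap-free), correlated noise between
samples (library or batch effects), and mean–variance relationships of
count data. Module recovery and network Jaccard results on these data
are therefore upper bounds on what identically parameterised real data
would give.

## Validation scales

The test suite and `scripts/acceptance.R` validate at scales chosen to
finish in minutes on one CPU while keeping the statistics meaningful:
scanner–oracle agreement on 1,000 random 200-bp sequences plus
exhaustive 8-mer enumeration; NG86 against the pathway-enumeration
oracle on 200 random pairs of ≤ 50 codons (tolerance 1e−12) and
parameter recovery within 15% at true Ks ∈ {0.05, 0.2, 0.5} with 50
replicate pairs of 300 codons; TOM against a triple-loop oracle on
20–50-gene matrices; module recovery (adjusted Rand index ≥ 0.8 in ≥ 90%
of 20 seeds) and network recovery (exact at zero noise, Jaccard ≥ 0.8 at
noise 0.25 over 20 seeds) on the default 200-gene configuration.

## Known limitations

* The static-cut/size-filter/eigengene-merge module detector is a fully
  specified, deterministic stand-in for adaptive dendrogram-shape
  methods; on real data with nested or weak modules an adaptive cut will
  recover structure this one misses.
* NG86 with Jukes–Cantor correction underestimates divergence when
  substitution is transition-biased and saturates above Ks ≈ 3; epoch
  assignments for the oldest duplication wave should be read as
  "ancient or saturated".
* p-values for module–trait and partner correlations assume independent
  samples; replicated designs violate this mildly, and the strict
  p < 1e−4 partner threshold is the guard.
* The scale-free fit, and hence automatic β selection, is noisy below a
  few hundred genes; fix `beta` explicitly when comparing runs.
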