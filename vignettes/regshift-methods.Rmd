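---
title: "Methods: regulatory-shift analysis on synthetic multiome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulatory-shift analysis on synthetic multiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regshift)
```

# Scope and model

`regshift` implements the downstream computational layer that links a
transcription factor (the running example is FOSL2/FRA-2, an AP-1 family
member binding TGAGTCA) to cell state in diseased versus healthy tissue:

1. **Footprinting on contribution tracks.** Base-resolution attribution
   scores of an accessibility model are treated as a signed per-base signal.
   Motif instances are located by scanning the genome (exact IUPAC consensus
   match by default, PWM log-odds optionally), per-base profiles over the
   motif ±30 bp are extracted per condition, clustered with k-means, and
   clusters are scored for condition-differential contribution.
2. **Motif deviation z-scores.** Per cell and motif, the deviation of
   observed accessibility in motif-bearing peaks from a depth-proportional
   expectation, standardized against background peak sets matched on GC and
   mean accessibility. Group comparison uses the two-sided Wilcoxon rank-sum
   test with Bonferroni adjustment.
3. **eRegulon scoring.** A regulon (TF with target regions/genes) is scored
   per cell by the area under the recovery curve at the top 5% of the
   feature ranking; regulons are filtered by the Pearson correlation between
   TF expression and region enrichment across 5-cell pseudo-bulks
   (|r| > 0.5; the sign classifies activators and repressors), and ranked by
   the regulon specificity score (1 − Jensen–Shannon distance to a label
   indicator).
4. **GRN perturbation.** Candidate TF→gene edges (motif hit with score ≥ 10
   in a peak linked to the gene) are fitted per condition by Bayesian ridge
   regression on log-normalized expression; edges are kept at posterior
   p < 0.001, capped at the top 2,000 by |weight|. In-silico knockout sets a
   TF to 0, overexpression to 1.5× its maximum; the delta propagates three
   steps through the signed weight matrix and each cell is scored by the
   cosine of its delta with the direction toward the other condition's
   centroid.
5. **Overlap statistics.** Wilcoxon DE with Bonferroni and the thresholds
   p_adj < 0.05, |log2FC| > 0.1/0.25/0.32; cross-namespace symbol mapping
   (table first, Title-case ↔ UPPER-case fallback); hypergeometric overlap
   computed in log space; Monte-Carlo multi-set overlap with the add-one
   estimator.

Everything runs end to end on a seeded synthetic generator with planted
ground truth, so each stage's recovery behavior is measurable.

# Synthetic-data generator

The generator emulates the *structure* of a single-cell multiome study, not
any particular dataset:

* **Genome**: i.i.d. bases at GC 0.41 (human-like; this controls the decoy
  motif-match rate), with exactly `n_plant_per_motif` non-overlapping
  consensus instances planted at random positions and strands and recorded
  in a truth manifest. Planted instances are always rediscoverable by
  exact-match scanning.
* **Contribution tracks**: Gaussian noise (sd 0.1 by default — attribution
  scores are real-valued, so noise is Gaussian rather than count-based)
  plus a positive plateau at every planted seqlet; a chosen fraction of
  seqlets is additionally multiplied by δ in the disease condition only.
* **Peak universe**: planted-seqlet neighborhoods plus motif-free decoy
  intervals at a 3:1 decoy-to-motif ratio by default. Motif-bearing peaks
  must be a minority of the universe — exactly as in real peak sets —
  because the deviation statistic standardizes against backgrounds matched
  on GC and mean accessibility; if motif peaks dominate their bins, the
  matched backgrounds absorb the very signal being tested.
* **Accessibility**: Poisson counts with per-cell depths (log-normal around
  the configured mean) and gamma peak weights; `group_effect` multiplies
  motif-bearing peak weights in the disease group, and weights are
  renormalized per group so each cell's expected total equals its drawn
  depth — the group effect is therefore a composition shift, which is what
  the deviation statistic responds to.
* **Expression**: latent log2 expression propagated through a planted
  acyclic TF→target network (linear structural equations in topological
  order), negative-binomial counts (dispersion 0.1, a typical single-cell
  overdispersion scale) around `2^latent` with a per-cell size factor.
  Exogenous regulators vary cell-to-cell with sd 1 (log2) — driver TFs in
  real single-cell data are highly variable genes — while targets carry
  intrinsic noise sd 0.3. The designated driver is shifted up in the
  disease group, so each gene's planted log2 effect is its summed path
  weight times the shift. A second, Title-case ("mouse-like") namespace is
  emitted with an ortholog table.
* **Regulon fixture** (`simulate_regulon_truth`): one activator whose
  latent activity drives 15 regions with loadings graded over 0.3–1.5
  against unit noise. The grading matters: with uniform strong loadings the
  top-5% recovery AUC saturates and its correlation with TF expression
  collapses; graded loadings make the AUC respond smoothly, which is the
  regime the pseudo-bulk correlation filter assumes (and yields r ≈ 0.9
  for the planted activator by construction).

What the generator does **not** emulate: read-level data (FASTQ/BAM),
doublets, batch effects, ambient RNA, genomic sequence composition beyond
GC content, or peak-calling noise. Passing tests therefore demonstrate the
correctness and calibration of the statistics under their own model
assumptions, not robustness to those artifacts.

All randomness flows from one integer seed; each output derives a labeled
sub-seed, so any stage can be reproduced in isolation and full runs are
byte-deterministic.

# Numerical and design choices

* **Coordinates** are `GRanges` (1-based closed) internally — the
  Bioconductor convention — converted to/from 0-based half-open only at
  BED/bedGraph boundaries. bedGraph values are written with 17 significant
  digits so write∘read round-trips doubles exactly.
* **Peak calling on attribution tracks** replaces count-based callers with
  a threshold/run-length scanner: maximal runs of ≥ `min_run` bases with
  |score| above a threshold (default the 95th percentile of |score| within
  the prior peak set), merged across gaps ≤ `merge_gap`. Count-model
  callers are ill-defined for signed real-valued attributions.
* **k-means** uses k-means++ seeding, best of `n_init = 10` restarts by
  within-cluster sum of squares, deterministic given the seed; clusters are
  relabeled in decreasing size order. `k = 4` by default (configurable; the
  number of profile archetypes is a judgment call, and the differential
  cluster is then identified by the Δ statistic rather than visually).
  Profiles are strand-oriented by default so asymmetric flanks align.
* **Differential cluster statistic**: Δ = mean contribution over the motif
  span, condition A − condition B, averaged over member seqlets; the
  permutation null flips condition labels within rows, p uses the add-one
  estimator, so the smallest attainable p is 1/(n_perm+1).
* **Deviation backgrounds**: 10×10 quantile bins on GC × mean
  accessibility, 50 background sets by default; each background peak is
  drawn from the bin of the peak it replaces. Background deviations reuse
  the original matrix's cell totals and pooled peak fractions. When a
  background SD is zero the z is defined as 0 with a warning. Depth
  invariance holds exactly at the deviation (expectation) level; the
  z-standardization inherits it up to the scaled cell's influence on
  pooled fractions.
* **AUC normalization** divides by `X · min(|set|, X)` with
  `X = ceiling(top_frac · n)`, so a small, fully recovered set scores
  exactly 1. The brute-force recovery-curve oracle in the test suite pins
  this definition.
* **Bayesian ridge edges**: conjugate Gaussian ridge with fixed prior
  precision λ (default 1), residual variance plugged in with an effective
  degrees-of-freedom correction, posterior covariance σ²(XᵀX+λI)⁻¹, and
  edge p the two-sided posterior tail at 0. This realizes "edge strength as
  a distribution" without naming a frequentist test; the null calibration
  test verifies pure-noise regulators pass p ≥ 0.001 in ≥95% of replicates.
  The top-2,000 cap is applied per condition GRN overall (not per sign).
* **Perturbation propagation** adds wave-by-wave increments `Wˢ·delta0`
  for s = 1..3 with the perturbed TF clamped (it receives no incoming
  updates); genes unreachable from the TF keep delta 0, and deltas are
  linear in the initial perturbation. Transition scores live in expression
  space; the 2-D embedding projection is for visualization only.
* **Region→gene links** are distance-based (nearest gene start within
  100 kb): co-accessibility models are out of scope, and the synthetic
  truth uses the same rule, so edge recovery is well-posed.
* **QC thresholds** are applied literally as specified, globally across
  cells, including the removal of cells with RNA reads ≥ 50,000 (a doublet
  proxy) and TSS enrichment ≤ 1.
* **Overlap universes** default to the intersection of detected-gene sets
  of the compared datasets. Published overlap p-values are generally not
  recomputable without the original universe; the statistics here are
  validated against enumeration and analytic oracles instead.

# Problem sizes

The bundled demo and the test suite run at desk scale, chosen so the full
suite completes in a few minutes on one core while every statistic is still
well-resolved: genomes of 2 × 12–60 kb, 30–200 planted seqlets, 50–100
cells per group for deviation analyses, 500 cells per condition for GRN
recovery, 999 permutations, 10⁵ Monte-Carlo iterations for the two-set
overlap cross-check, and 20–100 seeded replicates for calibration and
retention rates.

# Known limitations

* Consensus-exact scanning misses degenerate motif instances; PWM mode
  exists but the synthetic truth plants exact consensus sequences.
* The deviation z-scores inherit chromVAR's composition sensitivity: a
  strong accessibility shift in motif peaks necessarily perturbs all other
  peaks' relative fractions, so decoy motifs can show (weaker) group
  differences.
* The Monte-Carlo multi-set overlap loops over iterations in R; at the
  default B = 10⁵ and desk-scale universes this is seconds, but very large
  universes would warrant a compiled path.
* Ridge edge p-values are conditional on the fixed prior precision; they
  are calibrated for edge screening (as verified), not posterior
  probabilities of a causal effect.
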