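---
title: "Scoring and ranking candidate pathway genes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and ranking candidate pathway genes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgcprior)
```

## The problem and the model

Plant specialized-metabolite pathways leave three footprints that can be
read without any wet-lab work. First, pathway genes are co-regulated: their
expression profiles across tissues correlate strongly with a *bait* — an
already characterized pathway gene such as the oxidosqualene cyclase
catalyzing the first committed step of triterpene saponin biosynthesis.
Second, the pathway runs somewhere: in soapbark-type saponin biosynthesis
the young leaf primordia, so absolute transcript abundance there is
informative. Third, plant genomes frequently organize such pathways into
biosynthetic gene clusters (BGCs), and a putative cluster that already
contains a characterized pathway gene is strong circumstantial evidence for
its other members.

`bgcprior` encodes each footprint as a bounded sub-score and sums them:

* **Coexpression.** Pearson correlation `r` of a gene's TPM vector with the
  bait's, across all samples. Sub-score 0 at or below `r = 0.8`, 1 at or
  above `r = 0.9`, linear between.
* **Abundance.** Arithmetic mean TPM over the replicates of the target
  tissue. Sub-score 0 at or below 1,000 TPM, 1 at or above 3,000 TPM,
  linear between.
* **Cluster membership.** 1 for membership in a putative BGC containing a
  characterized gene, 0.5 for any other putative BGC, 0 otherwise.

The composite is the exact sum, at most 3.0; no weighting is applied. These
knots and bonuses were calibrated on the behaviour of already characterized
saponin pathway genes and are the package defaults
(`scoring_config()`); every one is overridable.

The model's assumptions are worth stating plainly: it assumes one dominant
co-regulated module (a single bait anchors the search), that length- and
depth-normalized abundance (TPM) is comparable across the samples, and
that genomic proximity of signature enzyme classes is meaningful evidence.
It makes no claim of statistical significance — the composite is a
prioritization device for choosing genes to test experimentally, not a
test statistic.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `pcc_lo`, `pcc_hi` | 0.8, 0.9 | PCC | ramp knots; characterized pathway genes sit at PCC ≥ 0.9 |
| `tpm_lo`, `tpm_hi` | 1,000, 3,000 | TPM | ramp knots for target-tissue abundance |
| `bgc_char_bonus`, `bgc_other_bonus` | 1, 0.5 | score | characterized-cluster membership is the stronger evidence |
| `abundance_tissue` | `"primordia"` | label | tissue of peak pathway activity |
| `top_n` | 68 | genes | candidate-list length for downstream screening |
| `max_gap_bp` | 20,000 | bp | max intergenic gap when chaining signature genes |
| `min_classes` | 2 | classes | a cluster must mix ≥ 2 enzyme families |

## Cluster calling

The internal caller is a deliberately transparent stand-in for dedicated
cluster-detection software: on each scaffold, genes whose `enzyme_class`
belongs to a configurable signature catalogue are sorted by start and
chained while the intergenic gap (`next.start − prev.end − 1`; overlaps
count as 0) stays within `max_gap_bp`; a chain with at least two signature
genes spanning at least `min_classes` distinct classes becomes a putative
cluster, and *every* gene inside its span is a member. The defaults
(20 kb, 2 classes) approximate the "two or more enzyme families in
proximity" behaviour of plantiSMASH-style tools without their pHMM
machinery, which is out of scope here. Because no heuristic reproduces a
specific tool's calls exactly, `load_external_clusters()` ingests real tool
output (a `cluster_id` / `scaffold` / `member_id` TSV) and recomputes spans
and characterized flags from the annotation, after which scoring is
identical by construction. A gene belonging to several clusters takes the
maximum bonus — the only choice that keeps the sub-score monotone in
evidence.

## What the synthetic generator emulates

`simulate_genome()` + `simulate_counts()` produce the structure the score
assumes, with known ground truth:

* a planted pathway module (default 12 genes, bait included) sharing one
  latent tissue profile: primordia at `primordium_mean_tpm` (default
  8,000 TPM), each other tissue at a tissue-specific 1–10% of that;
  per-gene lognormal scaling (sdlog 0.25) keeps genes distinct;
* most pathway genes laid out in tight genomic clusters (default 4 + 4 + 3,
  leaving one unclustered member), each cluster holding ≥ 2 enzyme classes
  and ≥ 1 characterized gene, with intra-cluster gaps ≤ `cluster_gap_bp`
  (10 kb) and ≥ 5 × `cluster_gap_bp` of insulation from neighbours;
* *coexpression decoys* (default 4) sharing the latent profile but placed
  far from any planted cluster, and *cluster decoys* (default 4) sitting
  inside planted clusters with background expression — the two failure
  modes a purely correlational or purely positional method would fall for;
* background genes with independent lognormal tissue means
  (`meanlog` 5.0, `sdlog` 1.5 — median ≈ 150 TPM, heavy right tail, so
  2,000 genes sum near the 10^6 TPM budget), 10% of them carrying random
  signature classes so that accidental proximity clusters occur;
* counts drawn negative-binomial with mean proportional to target TPM ×
  gene length at equal library sizes (default 5 × 10^6 fragments), so
  recomputed TPM matches the target profile in expectation and the
  1,000/3,000 thresholds keep their meaning.

One calibration deserves its own paragraph. The NB dispersion default is
`nb_dispersion = 0.02` (variance `m + 0.02 m²`, ~14% extra-Poisson CV).
With 8 tissues × 3 replicates and the profile above, the between-replicate
noise at a dispersion of 0.1 would cap the expected bait correlation of a
true pathway gene near 0.89 — below the 0.9 ramp knot, and far from the
near-perfect coexpression (PCC > 0.98) that motivates the coexpression
channel in the first place. A dispersion of 0.02, typical for highly
expressed genes across biological replicates, reproduces that regime
(median planted-gene PCC ≈ 0.99) and is therefore the default; the
parameter is exposed for anyone wanting noisier conditions.

What the generator does **not** emulate: mapping ambiguity and length
biases of real quantification, correlated background modules (every
background gene is independent), isoforms, unbalanced library sizes, and
genuinely plantiSMASH-like cluster boundaries. Passing the recovery tests
therefore shows the pipeline is correct and well-conditioned under its own
assumptions — not that any particular real genome will rank as cleanly.

## Numerical and design choices

* **Correlation input.** PCC is computed on raw TPM across all individual
  samples. Tissue means (`tissue_means`) and `log1p` transforms are
  config switches, not defaults: raw-TPM/all-samples is the simplest
  reproducible convention, and with a spiked profile the choice moves
  PCC values only slightly. Missing values are rejected, not
  pairwise-deleted — count matrices are dense.
* **Undefined correlations.** Zero-variance genes (or a zero-variance
  bait) get an undefined PCC, flagged explicitly, and map to a
  coexpression sub-score of 0.
* **Knot inclusivity.** The ramps are continuous: exactly 0 at the lower
  knot and exactly 1 at the upper knot ("0.9 or greater" scores 1; the
  value at 0.8 is 0 by continuity).
* **Ties.** Ranking breaks composite ties by PCC descending, then target-
  tissue TPM descending, then gene id ascending — deterministic output for
  a deterministic input.
* **Rounding.** Machine outputs keep full precision; only
  `format_candidate_report()` rounds (scores to 2 decimals, so a
  full-evidence gene prints `3.00`).
* **Whitelist timing.** The enzyme-class whitelist (e.g. reductases, acyl
  transferases, glycosyl transferases when hunting tailoring steps) is
  applied after genome-wide ranking and before top-N truncation by
  default, mirroring the narrowing of an already ranked list; applying it
  before ranks are assigned is available via `whitelist_timing =
  "before_ranking"`.
* **Degenerate inputs.** All-zero sample columns give all-zero TPM with a
  warning; an all-zero gene gets undefined PCC and sub-scores of 0; both
  are warnings, never aborts.
* **Reproducibility.** One user-facing seed per run; stages derive their
  own sub-seeds deterministically, so identical configs give byte-identical
  GFF3, TSV and manifest outputs (the run manifest stores paths relative
  to the run directory for this reason).
* **Bait handling.** The bait is scored and ranked like any other gene; by
  construction it tops the list, a useful sanity check.

## Problem sizes used in validation

The test suite validates the stages against independent oracles (a
sum-formula Pearson implementation at 10-sample vectors, tolerance 1e-12;
a brute-force pairwise-gap chaining oracle on 1,000 random scaffolds of up
to 25 genes; hand-computed TPM examples) and the whole pipeline by planted-
module recovery at the default conditions (2,000 genes, 24 samples, seed
1): all 12 planted genes must rank inside the top 20, at least 90% of them
with composite ≥ 2.5, coexpression decoys must never reach the
characterized-cluster bonus and cluster decoys never a saturated
coexpression sub-score. The full suite runs in well under a minute.

## Known limitations

* Cluster-call fidelity to any specific external tool is not claimable;
  for faithful BGC evidence, feed the tool's calls in via
  `load_external_clusters()`.
* A single bait anchors the search; pathways with decoupled sub-modules
  would need multiple runs with different baits.
* TPM's compositional closure induces a small negative background
  correlation with a strongly expressed bait module (the module occupies
  a share of each sample's fixed TPM budget); at the default conditions
  the effect is ≈ −0.02 mean background PCC and irrelevant to the 0.8
  ramp, but it grows if the module dominates a small transcriptome.
* The equal-weight sum is the published calibration, not an optimum; no
  attempt is made to learn weights.
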