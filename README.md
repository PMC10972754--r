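# bgcprior

Prioritize candidate genes for the missing steps of a plant
specialized-metabolite pathway.

When part of a biosynthetic pathway is already characterized — say, the
enzymes building a triterpene saponin scaffold — the remaining tailoring
genes (reductases, acyl transferases, glycosyl transferases, …) can often be
found from genomic and transcriptomic signatures alone. Pathway genes tend
to be:

1. **tightly coexpressed** with a known pathway gene (the *bait*, e.g. a
   β-amyrin synthase catalyzing the first committed step),
2. **highly expressed** in the tissue where the pathway runs (e.g. leaf
   primordia), and
3. sometimes **physically clustered** in the genome as biosynthetic gene
   clusters (BGCs), often together with already characterized pathway
   genes.

`bgcprior` turns these three signals into a transparent composite score and
a ranked genome-wide candidate list.

## The score

For each gene *g* with bait Pearson correlation `r_g`, target-tissue mean
abundance `a_g` (TPM), and BGC status `b_g`:

```
c_coexpr(g) = 0                          if r_g ≤ 0.8 (or undefined)
              (r_g − 0.8) / (0.9 − 0.8)  if 0.8 < r_g < 0.9
              1                          if r_g ≥ 0.9

c_abund(g)  = 0                          if a_g ≤ 1000 TPM
              (a_g − 1000) / 2000        if 1000 < a_g < 3000
              1                          if a_g ≥ 3000 TPM

c_bgc(g)    = 1    if g lies in a putative BGC containing an already
                   characterized pathway gene
              0.5  if g lies in any other putative BGC
              0    otherwise

S(g) = c_coexpr(g) + c_abund(g) + c_bgc(g)        (maximum 3.0)
```

Candidates are ranked by `S` (ties broken by PCC, then TPM, then gene id),
optionally filtered to an enzyme-class whitelist, and truncated to a top-N
list. Putative BGCs are called with a documented proximity heuristic
(signature enzyme-class genes chained at ≤ 20 kb intergenic gaps, ≥ 2
distinct classes), or ingested from an external cluster-detection tool such
as plantiSMASH.

A synthetic-data module simulates a genome annotation and a multi-tissue
negative-binomial count matrix with a planted, primordium-enriched,
partially genome-clustered pathway module plus decoys, so the whole
pipeline is testable end to end without any downloads.

## Worked example

```r
library(bgcprior)
res <- run_pipeline(list(simulate = list(), seed = 1), outdir = "qs_run")
head(res$candidates[, c("rank", "gene_id", "enzyme_class", "pcc",
                        "primordium_tpm", "bgc_status", "composite")], 8)
#>   rank   gene_id          enzyme_class    pcc primordium_tpm               bgc_status composite
#> 1    1 gene00114 oxidosqualene-cyclase 1.0000         6125.6 in_characterized_cluster         3
#> 2    2 gene00395 oxidosqualene-cyclase 0.9957         5592.1 in_characterized_cluster         3
#> 3    3 gene00399  BAHD-acyltransferase 0.9957         7721.4 in_characterized_cluster         3
#> 4    4 gene00608   glycosyltransferase 0.9957         4665.5 in_characterized_cluster         3
#> 5    5 gene00396                   CYP 0.9940         6469.4 in_characterized_cluster         3
#> 6    6 gene00607                   CYP 0.9935         7450.4 in_characterized_cluster         3
#> 7    7 gene00397   glycosyltransferase 0.9825         7435.5 in_characterized_cluster         3
#> 8    8 gene00606 oxidosqualene-cyclase 0.9764         6839.8 in_characterized_cluster         3
```

This simulates the default synthetic dataset (2,000 genes, 8 tissues × 3
replicates, a 12-gene planted pathway, 4 + 4 decoys), normalizes counts to
TPM, correlates every gene with the bait (`gene00114`, the planted
oxidosqualene cyclase, PCC 1 with itself), calls clusters, and ranks. The
top rows are planted pathway genes with saturated evidence on all three
channels (composite 3.00); all 12 planted genes land in the top 20 of the
genome-wide ranking. Full-precision per-stage outputs (`tpm.tsv`,
`pcc.tsv`, `clusters.tsv`, `ranked_all.tsv`, `candidates_top.tsv`, a run
manifest and log) are written to `outdir`.

The same pipeline runs on real data by replacing the `simulate` block with
an `inputs` block naming a GFF3 annotation (attributes `enzyme_class`,
`characterized`) and counts/lengths/samples TSVs, plus a `bait_id`. A thin
command-line front end with `simulate`, `score` and `run` subcommands is
installed under `exec/bgcprior`.

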