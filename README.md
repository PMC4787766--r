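# pip3tc

Differential expression, gene-set logic, cluster stability and motif
activities for PI3K/PIP3 perturbation time courses.

## What this package is for

Class I PI3Ks produce the lipid second messenger PIP3; PTEN degrades it.
Breast-cancer-relevant lesions on this axis — biallelic PTEN deletion, or
the activating PIK3CA H1047R mutation in p110α — chronically rewire cells,
while EGF stimulation and the p110α-selective inhibitor A66 perturb the
pathway acutely.  Disentangling which mRNA changes are direct consequences
of PIP3 signalling from the genome-wide ripple of a chronic mutation (the
"butterfly effect") takes a combination of analyses, and this package
implements that combination as a tested, reusable pipeline for bulk
RNA-seq time courses over the five conditions `WT`, `A66`, `A66_noEGF`,
`PTEN_KO` and `PIK3CA_H1047R` (EGF time points 0/15/40/90/180/300 min in
triplicate; 75 libraries):

* **Differential expression** — negative-binomial GLM likelihood-ratio
  tests, `y_gs ~ NB(μ_gs, α_g)` with `log μ_gs = x_sᵀβ_g + log s_s`,
  over pairwise, time-course and condition×time interaction designs;
  median-of-ratios size factors `s_s`; Cox–Reid adjusted per-gene
  dispersion combined with a fitted mean–dispersion trend
  `α(μ) = a/μ + b`; Benjamini–Hochberg adjusted p-values at 0.05
  (pairwise) and 0.01 (time-course) defaults.
* **Set logic** — exact Venn-region partitions of the comparison outcomes
  into the basal/EGF-induced PI3K sets (sets 1–4), the mutant chronic ×
  EGF-dependence sets (A–H), and a direction-coherence filter that keeps
  only genes moving up in both activating mutants and down under the
  inhibitor (or the mirror image) in all six comparisons.
* **Cluster stability** — k-medoids (PAM) on z-scored profiles with
  bootstrap Jaccard stability: a cluster is stable when its median
  similarity over 100 resamples is ≥ 0.75 with SD ≤ 10% of the mean; the
  optimal k is the largest k of the first contiguous all-stable run.
* **Motif activities** — a ridge regression of centered promoter
  log-expression on motif site counts,
  `A = (NᵀN + λI)⁻¹ NᵀE` per sample, with per-motif significance
  `z_m = sqrt(mean_s (A_ms/se_ms)²)`; per-promoter target scores `S_pm`
  (misfit increase when a motif's sites are removed, activities fixed),
  per-gene scores `S_m` by the max-over-promoters rule, and the
  `S_m > 20`, `z ≥ 2` strong-target table.
* **Distribution comparisons and enrichment** — two-sample
  Kolmogorov–Smirnov and Mann–Whitney tests on `S_m` distributions
  between gene sets (sorted by D), hypergeometric term enrichment,
  correlation/PCA sample QC.
* **A seeded synthetic-data generator** that emulates the full design with
  planted chronic, EGF-impulse, PI3K-dependent, coherent and motif-driven
  structure, so every stage is testable end to end without any download.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` for the main result types.

## Worked example

```r
library(pip3tc)

res <- run_pipeline(pipeline_config(seed = 1), out_dir = "pip3_run")
```

The run simulates the 4000-gene default study, executes all seven standard
comparisons and downstream stages, and logs:

```
[simulate] 4000 genes x 75 samples
[de] basal_pi3k: 171 significant
[de] induced_pi3k: 123 significant
[de] egf_dep_wt: 540 significant
[de] chronic_pten: 715 significant
[de] chronic_pik3ca: 624 significant
[de] induced_pten: 810 significant
[de] induced_pik3ca: 725 significant
[sets] set1 2 set2 115 set3 54 set4 54 A 0 B 192 C 3 D 429 E 5 F 518
       G 9 H 179 coherent_up 27 coherent_down 18
[motifs] lambda = 3.16, 4 motifs with z >= 2, 670 strong targets
```

Reading these numbers: the two chronic mutant baselines change 715 and
624 genes while acute A66 inhibition changes 123 — the design-matched
chronic-over-acute ratio is

```r
res$butterfly
#> [1] 6.24
```

the "butterfly" asymmetry between genetic and pharmacological
perturbation.  The coherence filter narrows thousands of changed genes to
45 (27 up + 18 down) whose directions follow PIP3 logic in all six
comparisons.  The motif stage recovers exactly the 4 transcriptionally
active motifs planted by the generator at `z ≥ 2` (top z = 29.1), and the
score comparison ranks the motif coupled to the chronic-both gene set
first by KS D.

Per-stage tables land in `pip3_run/` (`de_*.tsv`, `genesets.tsv`,
`clusters.tsv`, `stability.tsv`, `activities.tsv`, `sm_scores.tsv`,
`strong_targets.tsv`, `comparison.tsv`, `enrichment.tsv`, `corr.tsv`,
`pca.tsv`, `summary.tsv`) together with a checksum `MANIFEST.tsv`;
re-running the same configuration reproduces every file byte for byte.

Individual stages are plain functions:

```r
sim <- generate_dataset(generator_config(n_genes = 2000, seed = 7))
de  <- run_comparison(sim$dataset,
                      comparison_spec("pairwise", condition_a = "WT",
                                      condition_b = "PTEN_KO",
                                      time_a = 0, time_b = 0))
glance(de)       # one-row summary: genes, samples, significant count
tidy(de)         # per-gene log2fc, LRT stat, p, padj
autoplot(de)     # volcano plot
```

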