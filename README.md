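# cgsc — core glioma stem cells and their immune-evasive phenotype

`cgsc` is an R package for identifying **core glioma stem cells (c-GSCs)**
— glioblastoma cells that concurrently express the embryonic pluripotency
factors **OCT4, SOX2 and NANOG** at high levels — in single-cell expression
data, and for characterizing their immune-evasive phenotype by integrating
bulk RNA-seq and EPIC-style DNA-methylation profiles of patient-derived
cells (GBM-DC) versus reprogrammed induced c-GSC (ic-GSC) lines.

It is aimed at computational biologists studying stemness and antigen
presentation in glioblastoma, and at anyone who needs the individual
building blocks: marker-combination quantile classification, rank-based
differential expression, pathway-agreement statistics, or
methylation-interval genomics.

## The method in brief

**Single-cell identification.** After removing genes unexpressed in more
than 95% of cells, each marker g ∈ {OCT4, SOX2, NANOG} gets a threshold
Q3(g), its upper quartile over all pooled cells. A marker is *high* in a
cell iff expression > Q3(g) (strictly; ties are low), and a cell is a
c-GSC iff all three markers are high. The eight O±S±N± combinations define
the populations over which the HLA-A/-B/-C expression gradient is
computed. c-GSC vs tumor-bulk differential expression uses a two-sided
Wilcoxon rank-sum test with BH-FDR; a gene is a DEG iff q < 0.05 and
|log2 FC| > 0.5.

**Bulk transcriptome.** Counts are TPM-converted and normalized by
median-of-ratios size factors. DEGs between GBM-DC and ic-GSC groups
require q < 1e-10 (negative-binomial Wald p-values, BH-adjusted) and an
absolute log2 median-of-ratios fold change > 1.5. A c-GSC centroid
(mean over c-GSC cells on the DEG genes) is embedded with the bulk samples
by an exact t-SNE. Pathway-level concordance between the c-GSC and ic-GSC
enrichment results is quantified over a shared pathway universe by
Cohen's kappa κ = (po − pe)/(1 − pe), the odds ratio ad/bc of the 2×2
agreement table, and a Fisher exact p-value.

**Methylome.** Beta values are standardized by each sample's mean beta
(columns then average exactly 1). A probe is a differentially methylated
site (DMS) iff the standardized group difference satisfies |Δ| > 1 with a
Wilcoxon p ≤ 0.1 — exact p-values at these group sizes, where the minimum
attainable two-sided p at 3 vs 3 is 0.1 (complete rank separation).
Promoter methylation aggregates probes within ±1.5 kb of a TSS; consensus
OCT4/SOX2/NANOG binding sites are the triple interval intersection of the
three ChIP peak sets; metaprofiles average methylation in 200-bp bins over
±10 kb around binding-site midpoints; and a starburst table classifies
genes by the sign pair of expression change and promoter methylation
change.

**Synthetic data.** `simulate_bundle()` writes a complete input bundle
(MTX single-cell counts, bulk count/design/length TSVs, beta matrix, probe
annotation, peak BEDs, TSS table, GMT gene sets) with planted ground truth:
a ~4% triple-high subpopulation with HLA suppression, 50 bulk DEGs at
|log2| = 4 (stemness up, antigen presentation down), promoter
hypermethylation at HLA genes and hypomethylation at consensus binding
sites. See the methods vignette (`vignettes/cgsc-methods.Rmd`) for the
full model and the reasoning behind every default.

## Worked example

```r
library(cgsc)

cfg <- synthetic_config(seed = 7)       # 8,000 cells, 28 patients, 4% planted
sim <- simulate_sc_cohort(cfg)
m   <- filter_genes(sim$counts, 0.95)
th  <- marker_thresholds(m, cfg$markers)
lab <- classify_osn(m, th)
cohort_summary(lab, sim$patient_of)
```

```
c-GSC cohort summary: 4.41% pooled (353/8000 cells)
  28/28 patients with >=1 c-GSC (100.0%)
  per-patient: 4.41% +/- 0.11 (SEM; SD 0.57)
```

The classifier calls 4.41% of cells triple-high: the planted 4% plus a
small background of coincidental triple-highs, present in every patient.
The HLA gradient over the marker categories shows the planted
immune-evasion signal — triple-negative cells express the HLA genes about
three-fold higher than c-GSCs:

```r
grad <- hla_gradient(m, lab, cfg$hla_genes)
subset(grad, category %in% c("O-S-N-", "O+S+N+"))
```

```
   category  gene mean_expr rescaled
1    O-S-N- HLA-A     20.05     3.50
8    O+S+N+ HLA-A      5.73     1.00
9    O-S-N- HLA-B     20.06     3.31
16   O+S+N+ HLA-B      6.06     1.00
17   O-S-N- HLA-C     19.81     3.15
24   O+S+N+ HLA-C      6.29     1.00
```

The agreement statistic on a hand-checkable 2×2 table (5 pathways enriched
in both analyses, 2 and 3 in exactly one, 90 in neither):

```r
u <- paste0("path", 1:100)
pathway_agreement(u[1:7], u[c(1:5, 8:10)], u)
```

```
pathway agreement over 100 sets: a=5 b=2 c=3 d=90
  kappa = 0.640, OR = 75.00, Fisher p = 1.48e-05
```

The full pipeline runs over a bundle directory and writes per-stage TSVs
plus a `summary.json` (c-GSC percentages, DEG/DMS counts, κ/OR, config
hash); a shell entry point is included at `inst/cli/cgsc`
(`cgsc simulate|run|validate`).

```r
paths <- simulate_bundle(cfg, "bundle")
summary <- run_pipeline(pipeline_config(paths, seed = 7), "run")
```

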