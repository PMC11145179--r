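# spatialTME

Spatial tumor-microenvironment analysis for imaging mass cytometry (IMC) and
other multiplexed single-cell tissue imaging.

Multi-region tumor studies image 1.5 mm tissue-microarray cores at 1 um/px
and segment them into single cells with marker intensities and coordinates.
spatialTME turns such per-cell tables into the quantities spatial
tumor-immunology studies report, for bioinformaticians and computational
pathologists working with NSCLC-style cohorts:

* **Phenotyping** — per-marker positivity from a two-component mixture on
  log intensities, major lineages from marker-set scoring, subtypes from a
  rule table (e.g. neutrophils = CD11b+MPO+ negative for CD14/CD68/CD163/
  CD206), plus pathology-mask relabeling (perivascular, alveolar, tumor).
* **Compartment densities** — cells/mm^2 per (class, tumor-nest/stroma)
  with robust z-scores, z = (x - median) / MAD.
* **TME classification** — consensus clustering (1,000 iterations, 75%
  subsamples, Chebyshev distance, Ward linkage) of immune densities into
  four classes — *TS:TIL+MP high*, *T:TIL+MP excluded*, *TS:Immune low*,
  *TS:Neutrophil high* — converted into explicit per-class criteria with
  cutoffs at the sensitivity/specificity intersection of a logistic fit;
  cores failing their cluster's criteria are *undefined*.
* **Cellular communities** — windows of each cell plus its 9 nearest
  neighbors, summarized as composition fractions and clustered by k-means
  (k = 10), with elbow-based k selection, subsampling concordance and
  mixed-model enrichment tests.
* **Barrier score** — on a 5-nearest-neighbor cell graph, the mean over CD8
  T cells of the fraction of BFS shortest paths to the nearest tumor cells
  (in DBSCAN clusters >= 2,000 um^2) that pass through a tumor-adjacent
  aSMA+ fibroblast.
* **Interaction testing** — per-image permutation tests of mean neighbor
  counts within 5 um (+ cell radii), p = (1 + #{perm >= obs}) / (n_perm + 1),
  with GLMM aggregation across cores and Benjamini-Hochberg adjustment.
* **Heterogeneity** — spatial ITH scores (cohort-mean within-tumor SD of
  z-scored densities), bootstrap probabilities that all sampled regions of a
  tumor share a TME class, nearest-type distances, TAN high/low calls
  (tTAN/sTAN cutoffs 2%/3% and 1%/2% in LUAD/LUSC), TMB status (high at
  >= 10 muts/Mb) and recent-subclonal-expansion scores (max leaf-clone CCF).
* **Synthetic tissue generator** — 1.5 mm cores with irregular tumor nests,
  per-class target densities, two-component log-normal markers, planted
  communities, planted fibroblast barriers and planted TME classes, with
  full ground truth; every stage above is validated against it.

## Worked example

Generate a small synthetic cohort with a planted fibroblast barrier, score
it, and classify its microenvironments:

```r
library(spatialTME)

cfg <- synthetic_config(barrier = list(coverage = 0.5, thickness_um = 10))
core <- generate_core(cfg, seed = 1)
b <- barrier_score(core$cells)
round(b$score, 3)
#> [1] 0.25
b$n_cd8
#> [1] 505
```

A quarter of the CD8 T cells are separated from their nearest tumor cells by
a tumor-adjacent aSMA+ fibroblast when half of each nest boundary carries a
planted barrier. Baseline stromal fibroblasts produce a small organic score
even at `coverage = 0`, and the score increases strictly with coverage (the
test suite checks the 0 -> 0.5 -> 1 sweep).

The canonical worked example is a hand-built graph: one CD8 T cell with
three nearest tumor cells, all six hops away, and tumor-adjacent
fibroblasts on two of the three shortest paths:

```r
# chain_fixture() as in scripts/acceptance.R
fx <- chain_fixture(3, 1:2)
barrier_score(fx$cells, fx$graph, fx$clusters)$score
#> [1] 0.6666667
```

TME classification on a cohort with planted classes:

```r
cfg <- synthetic_config(n_patients = 29, cores_per_patient = c(3, 3),
                        emit_markers = FALSE)
planted <- as.list(rep(tme_class_names(), c(8, 6, 3, 12)))
coh <- generate_cohort(cfg, seed = 1, planted_classes = planted)
rd <- compute_densities(coh$cells, coh$truth$cores)
model <- tme_model(rd, k = 4, seed = 1)
round(model$consensus$delta_auc, 3)
#>     2     3     4     5     6
#>    NA 0.087 0.115 0.060 0.035
table(model$labels, coh$truth$cores$planted_tme)
```

The consensus-CDF area gain (`delta_auc`) peaks at k = 4 and flattens
beyond it, and the per-core labels recover all 87 planted class labels
(recovery 1.0, no `undefined` cores at this seed).

The whole pipeline — simulate, phenotype, densities, TME, communities,
barrier, interactions, heterogeneity — runs as one call and writes CSV/JSON
artifacts stamped with a config hash:

```r
run_pipeline(pipeline_config(out_dir = "tme_out", seed = 1))
```

A thin CLI covering simulate / barrier / run-all is installed at
`inst/cli/spatialtme.R`.

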