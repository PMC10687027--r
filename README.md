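# orcnet

Ollivier-Ricci curvature analysis of gene interaction networks, for
integrating a protein-protein interactome with per-patient omics profiles
and relating the resulting network geometry to clinical outcome.

## The problem and who this is for

Molecular subtypes of cancers such as multiple myeloma are usually defined
from expression or copy-number profiles gene by gene. `orcnet` instead asks
how each patient's profile reshapes the *geometry* of a fixed
protein-interaction network: for every interaction edge and every sample it
computes the Ollivier-Ricci curvature

    kappa(i, j) = 1 - W1(mu_i, mu_j) / d(i, j)

where the node values r (log2(TPM+1) for RNA-seq, or copy number) define
transition probabilities p_ij = r_j / Σ_{k∈N(i)} r_k, edge weights
w_ij = (p_ij + p_ji)/2 and lengths 1/√w_ij; mu_i spreads unit mass over the
neighbors of i in proportion to r; W1 is the exact Wasserstein-1 (earth
mover's) transport cost; and d is the weighted shortest-path distance.
Positively curved edges sit in redundant, well-connected neighborhoods
(robust interactions); negatively curved edges are bottlenecks (fragile,
bridge-like interactions). The edges-x-samples curvature matrix then feeds
a standard outcome pipeline: hierarchical clustering with silhouette model
selection, high/low-risk group formation, Kaplan-Meier / log-rank / Cox
survival analysis, negative-binomial differential expression with the
strict q < 0.05 and |log2FC| > 3.5 gene filter, hypergeometric gene-set
over-representation, and hub/bridge/singleton network topology reports.

The package is aimed at computational biologists who want a reusable,
tested implementation of this analysis for their own cohorts (edge-list +
TPM/counts/CNA/clinical TSV inputs), plus a fully self-contained synthetic
cohort generator for method evaluation.

## A worked example

```r
library(orcnet)

# a synthetic cohort with known ground truth: 300-gene scale-free
# interactome, 200 samples, 3 subtypes (the third at hazard ratio 3),
# planted expression modules and a planted 8-gene prognostic signature
cfg    <- sim_config(seed = 1)
net    <- simulate_interactome(cfg)
sim    <- simulate_cohort(net, cfg)
cohort <- harmonize(sim$network, list(sim$tpm, sim$counts, sim$cna),
                    sim$clinical)

curv <- curvature_matrix(cohort, kind = "rna")
curv
#> curvature_matrix [rna]: 1184 edges x 200 samples

X   <- feature_matrix(curv, standardize = TRUE)
sel <- select_k_silhouette(X, 2:12)
sel$k
#> [1] 3
asg <- hierarchical_cluster(X, sel$k)
mclust::adjustedRandIndex(asg$labels, sim$ground_truth$subtype)
#> [1] 1

lr <- logrank_test(times  = cohort$clinical$pfs_time,
                   events = cohort$clinical$event,
                   labels = asg$labels[cohort$clinical$sample])
lr$p
#> [1] 9.899741e-06

risk <- assign_risk_groups(asg, cohort$clinical, mode = "auto")
de   <- nb_two_group_test(cohort$matrices$counts, risk)
sig  <- select_significant(de, q_max = 0.05, lfc_min = 3.5)
nrow(sig)
#> [1] 56
```

The silhouette score recovers the three planted subtypes exactly
(adjusted Rand index 1); the clusters separate progression-free survival
(log-rank p ≈ 1e-5); and the risk-group contrast recovers the planted
extreme-fold-change genes (56 genes passing the strict filter, against 60
planted in the two contrasted modules). `cox_fit()` on z-scored
log2(TPM+1) recovers all 8 planted signature genes at BH q < 0.05.

The same analysis runs from a single YAML configuration with
`run_pipeline("pipeline.yaml")`, which writes every stage's outputs
(curvature TSV, cluster labels, risk groups, log-rank and Cox tables, DE
tables, topology JSON) plus a checksummed run manifest, and resumes from
cached stage outputs.

## Layout

- `R/` — network/omics I/O and harmonization, per-sample graph weighting,
  the curvature engine and its brute-force oracles, clustering and risk
  groups, survival statistics, differential expression and enrichment,
  topology reports, the synthetic-data generator, the pipeline driver
- `src/` — exact earth-mover (min-cost-flow) solver and batched per-sample
  curvature kernel (Rcpp)
- `vignettes/orc-network-analysis.Rmd` — the model, its assumptions, the
  generator's design, numerical choices, and limitations
- `tests/testthat/` — unit, property and acceptance tests
- `scripts/acceptance.R` — end-to-end reproduction script
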