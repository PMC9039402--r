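# cernet

miRNA-mediated regulatory-network analysis with survival validation, for
tumor/normal expression studies.

Competing endogenous RNA (ceRNA) regulation is the crosstalk by which
lncRNAs and mRNAs influence each other's abundance through shared miRNA
binding: two transcripts repressed by the same miRNA rise and fall
together as they compete for it. `cernet` turns this analysis — as
practised on cohorts such as TCGA rectal cancer — into a tested, reusable
R pipeline for bioinformaticians who have miRNA/lncRNA/mRNA count
matrices, clinical follow-up, and (optionally) interaction tables,
sequences, motifs and genomic intervals.

The pipeline:

- **Differential expression** on counts with an exact negative-binomial
  test (common method-of-moments dispersion, total-count normalisation)
  and the `|FC| > 2`, `p < 0.05` rule.
- **miRNA–target networks**: curated edges mapped to DE endpoints
  (mRNA side) and canonical seed matching — 8mer / 7mer-m8 / 7mer-A1 /
  6mer sites (lncRNA side) — then retention of negatively
  expression-correlated pairs (Pearson).
- **Topology**: degree, clustering coefficient, average path length and
  a power-law degree-distribution fit (R²), with empirical p-values
  against 1,000 degree-preserving double-edge-swap randomisations.
- **Modules**: an MCODE reimplementation (vertex weight = k-core density
  of the closed neighborhood; seed-and-expand; haircut; module
  score = density × size, reported above 5).
- **ceRNA network**: lncRNA–mRNA pairs sharing ≥ 1 miRNA with
  expression PCC > 0.9, plus lncRNA–miRNA–mRNA triplets and an
  upper-tail hypergeometric sharing test.
- **TF–lncRNA crosstalk**: hypergeometric shared-miRNA pairing
  (p < 0.05) and a PWM scanner with exact dynamic-programming p-values
  over ±2 kb promoter windows and assigned enhancers.
- **Survival**: per-feature univariate Cox coefficients β_i (Breslow
  ties), the risk score `RiskScore(s) = Σ_i β_i · Exp_i(s)`,
  stratification at the mean score, Kaplan–Meier curves with the
  log-rank test, and rank-based ROC-AUC.
- **Associations**: lncRNA–immune-infiltration correlation and generic
  gene-set over-representation (hypergeometric + BH).
- **Synthetic studies**: `generate_study()` draws a fully
  self-consistent study — counts, interactions, sequences, motifs,
  clinical, infiltration — with planted ground truth, so every stage can
  be validated by recovery and calibration simulations.

## Worked example

```r
library(cernet)

study <- generate_study(synth_config(n_tumor = 40, n_normal = 10,
                                     n_mirna = 40, n_lncrna = 25, n_mrna = 80,
                                     frac_de = 0.4, edge_effect = 0.9,
                                     n_triplets = 5, seed = 7))
study
#> Synthetic regulatory study
#>   samples: 40 tumor + 10 normal
#>   features: 40 miRNA, 25 lncRNA, 80 mRNA (frac DE 0.40)
#>   planted: 42 true edges, 5 triplets, 5 prognostic features

de_mir  <- select_de(de_test(study$expr$miRNA, study$groups))
de_mrna <- select_de(de_test(study$expr$mRNA, study$groups))

log2e <- lapply(study$expr, log2_standardize)
cand  <- map_de_edges(subset(study$interactions, target_class == "mRNA"),
                      de_mir, de_mrna)
edges <- correlation_filter(cand, log2e$miRNA, log2e$mRNA)

net <- build_network(edges,
  c(setNames(rep("miRNA", 40), rownames(study$expr$miRNA)),
    setNames(rep("mRNA", 80),  rownames(study$expr$mRNA))))
tp <- topology(net)
sprintf("network: %d nodes, %d edges, power-law R2 = %.2f",
        tp$n_nodes, tp$n_edges, tp$powerlaw_r2)
#> [1] "network: 49 nodes, 38 edges, power-law R2 = 0.98"

frm   <- fit_risk_model(log2e$mRNA[, study$clinical$sample_id],
                        study$clinical, head(de_mrna, 10))
strat <- risk_score(frm$model, log2e$mRNA[, study$clinical$sample_id])
km    <- km_logrank(study$clinical, strat$group)
sprintf("log-rank chi2 = %.2f, p = %.4f", km$logrank_chi2, km$logrank_p)
#> [1] "log-rank chi2 = 8.12, p = 0.0044"
```

The retained edges are miRNA→target pairs that are both differentially
expressed and negatively co-expressed — the signature of active miRNA
repression. The risk model weights the top DE genes' log2 expression by
their univariate Cox log-hazard ratios; the log-rank p-value (here
0.0044) says the mean-score split separates the two synthetic risk
groups' survival, as it should given the planted prognostic effects.

The whole pipeline, driven by one YAML config, writes TSV/GraphML
outputs and a machine-readable run summary:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "cernet"),
             "results_demo")
```

A thin CLI over the same entry point lives at `inst/cli/cernet.R`
(verbs: `simulate`, `de`, `network`, `modules`, `cerna`, `tf`,
`survival`, `run-all`).

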