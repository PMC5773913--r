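# scpranker

Ranks candidate essential proteins in a protein–protein interaction (PPI)
network by fusing two biological signals, for computational biologists who
want to prioritize knockout or validation experiments.

Essential proteins are indispensable for survival, but identifying them
experimentally is slow and costly. Network rankers exploit the tendency of
essential proteins to be highly connected, yet degree alone is a weak,
noisy predictor. `scpranker` implements the SCP score, which augments the
network with two further evidence layers:

* **MPR** — a modified PageRank over the PPI network whose edges are
  weighted by subcellular co-localization. Each compartment `C` has
  importance `ISC(C) = 1/N_C` (small compartments are more informative);
  an edge gets the maximum ISC over the compartments its endpoints share,
  or the minimum ISC over the union of their compartments if they share
  none. Each protein's prior `IPSC(P) = Σ_j W(P, P_j)` (its incident
  weight sum) becomes the PageRank reset distribution, and the score is
  the dominant eigenvector of `α·M̂₁ + (1−α)·M̂₂` (walk matrix plus
  rank-one reset, `α = 0.85`), computed by power iteration.
* **IPCC** — the per-protein sum of Pearson correlations of gene-expression
  profiles over its interactions: `IPCC(P) = Σ_j PCC(X_P, X_{P_j})`.

The channels are min–max normalized (NIS) and fused as

```
SCP = λ · NIS(MPR) + (1 − λ) · NIS(IPCC),    λ = 0.5 by default.
```

The package also ships the full evaluation battery used in this literature
(truncated ROC/AUC, precision–recall, jackknife curves, top-percentage
essential counts, link-proportion analysis of top-ranked subnetworks), a
degree-centrality baseline, readers for the standard input formats
(edge lists, BioGRID-style tables, localization TSVs, expression matrices,
essential-gene lists) and a seeded synthetic-data generator so the whole
pipeline can be exercised offline.

## Worked example

```r
library(scpranker)

# a seeded synthetic dataset with planted essential-protein structure
ds <- generate_dataset(synthetic_config(n_proteins = 300, seed = 1))
ds
#> scp_synthetic_dataset: 300 proteins, 1342 interactions, 60 essential;
#>   38 compartments; 36 time points (seed 1)

# channel 1: compartment-weighted modified PageRank
wg  <- weight_network(ds$network, ds$annotation)
fit <- mpr(build_transition_model(wg, compute_ipsc(wg)))
fit
#> scp_rank: 300 proteins; 59 iterations; converged (residual 9.18e-11)

# channel 2: summed expression correlation, then the fusion
ipcc <- compute_ipcc(ds$network, ds$expression)
scp  <- scp_score(fit$scores, ipcc, lambda = 0.5)
head(rank_scores(scp))
#>   rank protein     score
#> 1    1  P00150 0.9024786
#> 2    2  P00014 0.6907841
#> 3    3  P00040 0.6761311
#> 4    4  P00104 0.6718141
#> 5    5  P00160 0.6440305
#> 6    6  P00039 0.6343959
```

Proteins are ranked by SCP in descending order; a higher score means the
protein is predicted more likely to be essential. Evaluating against the
planted truth:

```r
roc_curve(scp, ds$essential)$auc                          # 0.8422
roc_curve(degree_centrality(ds$network), ds$essential)$auc # 0.7271

top_percent_counts(scp, ds$essential)
#>  1%  5% 10% 15% 20% 25%
#>   3  13  25  35  40  45

link_proportions(ds$network, rank_scores(scp)$protein, ds$essential, 50)
#>   top_k n_edges   ess_ess ess_noness noness_noness
#> 1    50     267 0.6067416   0.329588    0.06367041
```

The fused ranking recovers planted essentials far better than degree
centrality (AUC 0.84 vs 0.73 here), and the subnetwork induced by its top
50 proteins is dominated by essential–essential links — the qualitative
signatures this family of methods is judged by.

The same workflow runs from files: `cmd_simulate()` writes a dataset
directory, `cmd_score()` turns the four input files into per-channel score
files, a fused ranking and a JSON run manifest, and `cmd_evaluate()` writes
the metric tables. `inst/scripts/scp-cli.R` exposes the three as
`simulate` / `score` / `evaluate` shell subcommands.

See `vignettes/scp-methods.Rmd` for the model, its assumptions, every
tunable parameter, and the design of the synthetic benchmark.

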