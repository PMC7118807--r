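# dmsearch

Network-assisted dense module search for genome-wide association studies.

Most GWAS hits for complex traits fall short of genome-wide significance,
yet genes with moderate signal often cluster in interacting groups.
`dmsearch` finds those groups by superimposing gene-level association
scores onto a protein-protein interaction (PPI) network and greedily
growing *dense modules* — connected subgraphs whose aggregate score

    Z_m = sum(z_i) / sqrt(k),    z_i = Phi^-1(1 - p_i)

is locally maximal: starting from every scored gene as a seed, the
neighbor (within distance `d = 2`) giving the best new score is recruited
while `Z_{m+1} > Z_m (1 + r)` with `r = 0.1`. Modules are standardized
across the run (`Z_n`) and the top modules merged into a candidate
subnetwork. It is aimed at statistical geneticists integrating GWAS,
interactome and expression data.

On top of the core search the package provides:

* **SNP-to-gene scoring** — gene-body ± 50 kb mapping, Sidak-minimum or
  Fisher combination, inverse-normal transform, and capping of extreme
  gene p-values that would otherwise dominate every module;
* **dual-dataset consistency** — modules discovered in one GWAS dataset
  are re-scored with a second dataset and kept only when significant in
  both (discovery/evaluation design);
* **edge-weighted search** — per-interaction differential co-expression
  weights from the Fisher z-test comparing case and control Pearson
  correlations, a combined score `s = lambda z_node + (1 - lambda) z_edge`,
  and permutation significance against size-matched random connected
  subgraphs;
* **enrichment** — hypergeometric over-representation against GMT
  collections (set sizes 10–500, Bonferroni over tested sets) with
  affinity-propagation redundancy reduction;
* **a synthetic study generator** — scale-free networks, paired gene-score
  datasets sharing a planted connected module, and case/control expression
  with a planted correlation shift, so the whole pipeline is testable
  without access-controlled data.

## Worked example

A synthetic 300-gene interactome with a planted 6-gene module whose genes
draw `z ~ N(3, 1)` in two independent datasets:

```r
library(dmsearch)

net <- generate_network(300, seed = 42)
gw  <- generate_dual_gwas(net, plant_size = 6, node_effect = 3, seed = 43)
ms  <- normalize_scores(dense_module_search(net, gw$discovery, d = 2, r = 0.1))
ms
#> module_set: 300 modules (d = 2, r = 0.1)
#>   size 6-12, mean 8.15
#>   Z_n range -2.46 to 1.99

top <- top_k_subnetwork(ms, net, gw$discovery, k = 10)
sum(gw$truth$planted_genes %in% top$genes$gene)  # 6 of 6 planted genes
top$frac_nominal                                 # 0.75 of subnetwork genes at p < 0.05

dual <- evaluate_modules(ms, gw$evaluation)
score_correlation(dual)                          # 0.465
```

Every one of the 300 seeds produced a module of 6–12 genes; the union of
the ten best modules recovers all six planted genes, and 75% of the
merged-subnetwork genes are nominally associated (`p < 0.05`) — the planted
signal plus the background genes the modules recruited around it. The
positive correlation between discovery and evaluation module scores
supports running the one-directional consistency selection,
`select_consistent(dual)`.

For real data, load a tab-delimited edge list with `load_network()`,
gene-level p-values with `read_gene_scores()` (or SNP-level results via
`read_snp_associations()` + `map_snps_to_genes()` + `combine_snp_pvalues()`),
and expression with `read_expression()`; `run_pipeline()` orchestrates the
stages from a `pipeline_config()` and writes TSV/SIF/GraphML outputs plus a
manifest with input checksums.

See `vignettes/dense-module-search.Rmd` for the model, parameter and
design-choice documentation.

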