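---
title: "Network-assisted dense module search: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-assisted dense module search: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmsearch)
```

## The problem

Genome-wide association signals for complex traits are mostly weak and
scattered: few genes clear genome-wide significance, yet many genes with
moderate signal may act together in pathways. `dmsearch` implements the
network-assisted strategy of superimposing gene-level association scores
onto a protein-protein interaction (PPI) network and searching for *dense
modules* — connected subgraphs whose aggregate score is locally maximal
under a greedy expansion rule. Two searches are provided: a node-weighted
search driven purely by GWAS scores, and an edge-weighted variant that adds
case/control differential co-expression so that modules must carry both
association and transcriptional signal.

## Node weights

SNP p-values are mapped to a gene when they fall in the gene body or within
a 50 kb flank on either side (symmetric in genomic coordinates, so strand is
irrelevant). Mapped p-values are combined per gene by either the
Sidak-corrected minimum, `1 - (1 - min p)^m`, or Fisher's method. Both
combiners ignore linkage disequilibrium; when gene-level p-values from an
LD-aware tool are available they should be supplied directly through
`gene_score_table()`, which is the preferred path. The gene-level p is
transformed to the node weight by the inverse normal distribution function,
`z = qnorm(1 - p)`; p-values are clipped to `[1e-300, 1 - 1e-16]` first so z
stays finite.

A handful of genes with extraordinarily small p-values can dominate every
module that can reach them. `cap_extreme_genes()` therefore floors all
p-values below a threshold — by default the gene-level Bonferroni bound
`0.05 / n_genes` — to the smallest p-value among the remaining genes,
recomputing z and flagging the rows. A `drop` strategy removes them instead.

## The greedy search

Every scored network gene seeds one module. At each step all genes within
shortest-path distance `d` (default 2) of the current members are candidate
recruits; each is tentatively scored by the singleton rule

    Z_{m+1} = module_score(members + candidate),
    module_score(z_1..z_k) = sum(z_i) / sqrt(k)

and the best candidate (lexicographic tie-break on the symbol) is accepted
only if `Z_{m+1} > Z_m * (1 + r)` with `r = 0.1` by default. Growth stops
when no candidate passes: that stopping rule *is* the local-maximality
certificate, which `check_local_maximality()` re-verifies post hoc by an
exhaustive, cache-free neighbor scan.

Three numerical choices deserve note:

* **Non-positive scores.** The multiplicative acceptance rule is ill-posed
  when `Z_m <= 0`, so the rule becomes `Z_{m+1} > Z_m + |Z_m| * r`, which
  coincides with the standard rule for positive scores and still demands
  strict improvement at zero.
* **Connectivity linkers.** With `d = 2` the best candidate may be two hops
  from the module. The candidate is evaluated by its singleton score exactly
  as above, but on acceptance one linker gene — a common neighbor of the
  candidate and the module, highest z first, then lexicographic — is
  recruited with it, so module gene sets always induce connected subgraphs.
  The module score is then recomputed over the full member set. This is the
  package's resolution of the tension between one-gene-at-a-time recruitment
  and connectedness of the final module; the test suite's independent
  step-by-step oracle implements the identical documented rule.
* **Termination guards.** `max_iter` (default 1000) bounds expansion steps
  and warns, never silently truncates.

Raw scores are standardized across all modules of a run,
`Z_n = (Z_m - mean) / sd` with the population (divide-by-n) sd, and the top
k modules by `Z_n` (default 50, ties broken by seed symbol) are merged into
the reported subnetwork.

## Discovery/evaluation consistency

With two GWAS datasets, modules are generated on the discovery dataset and
re-scored with the evaluation dataset's z-scores over the same gene sets;
the evaluation normalization uses the distribution of those evaluation
scores across the discovery modules, not a fresh evaluation-side search.
Modules are kept when the discovery `Z_n` sits in the top `1 -
disc_quantile` share (default top 1%) *and* the evaluation `Z_n` clears
`eval_threshold` (default 1.64, the one-sided normal 5% point). Neither cut
is a published constant; both are explicit parameters and are recorded in
the pipeline manifest. The design is one-directional (discovery →
evaluation) because module scores need not correlate in both directions;
`score_correlation()` reports the Pearson correlation between raw discovery
and evaluation scores as a sanity check for the chosen direction.

## Edge weights and the edge-weighted search

For each interaction the within-case and within-control Pearson
correlations of the two genes' expression are compared with the Fisher
z-transform difference statistic

    z_raw = (atanh(r_case) - atanh(r_control)) /
            sqrt(1/(n_case - 3) + 1/(n_control - 3)),

the standard two-correlation test. Correlations are clipped to
±0.999999 before `atanh`, so the statistic is always finite; genes with zero
variance within a condition drop their edges with a warning. The weight fed
to the search is `|z_raw|` standardized across edges and shifted so the
minimum is zero — non-negative, so co-expression change in either direction
is rewarded. At least four samples per condition are required (the
statistic needs `n - 3 > 0`), and with small sample sizes the edge weights
are noisy; this is a property of the data design, not of the estimator.

The edge-weighted module score is `s = lambda * z_node + (1 - lambda) *
z_edge`, with `z_edge = sum(w_j)/sqrt(m)` over the m member edges, mirroring
the node formula. Seeds are edges, so modules have at least two genes;
`max_size` (default 10) caps growth because the combination of non-negative
weights and the square-root normalization lets z_edge grow with size.
`lambda` defaults to 0.5; `lambda = "auto"` equalizes the spread of the two
components (`lambda * sd(z) = (1 - lambda) * sd(w)`) and reports the value
chosen. Duplicate gene sets from different seed edges are collapsed,
keeping the best score.

## Permutation significance

Each module's combined score is compared against `n_perm` (default 1000)
random connected subgraphs of the same size — a uniform random edge followed
by uniform random connected growth — scored with the observed weight tables,
giving `p_perm = (1 + #{null >= s}) / (n_perm + 1)`. The null is
deterministic given a seed and conditions on module size only. Note a
deliberate asymmetry: observed modules are greedily *optimized* while the
null subgraphs are not, so the null is conservative about module membership
but liberal about the scores of optimized modules — grown modules will pass
the filter much more readily than seed-stuck ones. Interpretation should
lean on the module contents and on relative ranking, not on the absolute
p_perm of heavily optimized modules.

## Enrichment

Module genes are tested for over-representation against GMT collections by
the one-sided hypergeometric tail. Sets are restricted to the background
universe (by default the intersection of the scored-gene list and the
collection's genes), sets with fewer than 10 or more than 500 universe
members are excluded *before* testing, and the Bonferroni correction runs
over the number of sets actually tested. Redundant significant sets are
clustered by affinity propagation on Jaccard similarity (damping 0.9,
preference at the median similarity, 1000-iteration cap with a greedy
best-p-first fallback at Jaccard ≥ 0.5). Two conventions make the
clustering well-behaved on gene-set data: a deterministic sub-1e-9 jitter
breaks the exact symmetry of identical sets, and an item with zero Jaccard
overlap with its assigned exemplar becomes its own singleton cluster.

## The synthetic study generator

Real inputs of this kind (trio GWAS p-values, normalized case/control
expression) are controlled-access, so the package ships a generator that
emulates their statistical shape end to end:

* **Network** — preferential attachment: a clique on `attach + 1` nodes
  (default 4), then each new node attaches to `attach = 3` distinct existing
  nodes with probability proportional to degree. Connected, heavy-tailed,
  `choose(attach+1, 2) + attach*(n - attach - 1)` edges.
* **Dual GWAS** — one connected *planted* module is chosen by random walk;
  in both datasets planted genes draw `z ~ N(node_effect, noise_sd)`
  independently and background genes `N(0, 1)`, emulating two ancestries
  that share causal genes but not noise. `p = 1 - pnorm(z)`.
* **Expression** — 7 cases and 6 controls by default (the case/control
  design of the dental-pulp expression data this emulates), planted genes
  equicorrelated at `r_case` (default 0.8) in cases and `r_control`
  (default 0) in controls, background independent, all on a baseline of 7
  log2 units, with an optional `de_shift` on planted case means. A probe
  wrapper splits genes into 1–3 probes with `N(0, 0.1)` offsets to exercise
  probe collapsing.

What the generator does *not* emulate: linkage disequilibrium and gene
length effects on SNP-level scores, interaction false positives/negatives,
expression batch effects, and realistic pathway structure. Passing
recovery tests on this generator therefore demonstrates that the search
machinery finds planted signal of the stated strength under clean noise —
not that any particular real dataset would yield stable modules.

## Problem sizes and default conditions used in validation

The package's own validation (test suite and the acceptance script) uses
networks of 300–500 genes with an 8-gene planted module, node effects of
3.5 (node-only recovery) or 2 (edge-weighted comparison), correlation shift
0.8 vs 0, search defaults `d = 2`, `r = 0.1`, `top_k` 10–50, and 500–1000
permutations — sizes chosen so that a full end-to-end run completes in
minutes on one CPU while leaving the planted-module recovery problem
non-trivial (the planted module is under 2% of the network). The oracle
cross-check runs on ~200 random graphs of 8–25 nodes, where exhaustive
step-by-step simulation is cheap.

## Known limitations

Two behaviours of the greedy machinery deserve explicit warning because they
shape what downstream filters can and cannot do:

* **Module convergence.** When the planted (or real) signal is strong
  relative to the network's diameter — e.g. an 8-gene module at z ≈ 3.5 in a
  dense 500-gene graph searched at `d = 2` — expansions from nearly every
  seed converge onto the same high-signal region. Module gene sets then
  barely vary, raw scores compress, and *standardized* scores (`Z_n`, and
  especially the evaluation-side `z_n_eval`) degrade toward exchangeable
  noise, which can leave a strict dual-dataset selection (top-1% discovery
  AND evaluation `Z_n` ≥ 1.64) empty even though every module carries the
  true signal. On large sparse interactomes modules vary more and the
  selection behaves as intended; on small dense networks, widen the
  discovery quantile or inspect the raw `z_m_eval` values.
* **Permutation saturation.** Because observed modules are greedily
  optimized and null subgraphs are not (see above), grown modules
  essentially always clear `p_perm < 0.05`; the filter discriminates mainly
  among seed-stuck, unoptimized modules. Differences between analyses
  should be read from module composition and ranking, not from the
  significant/non-significant split.

Other limitations:

* The SNP combiners ignore LD; gene scores from LD-aware tools are the
  recommended input where available.
* The permutation null does not correct for greedy optimization bias (see
  above); absolute p_perm values for grown modules are anti-conservative.
* Affinity propagation parameters are fixed conventions, not fitted; with
  few significant sets the greedy fallback dominates.
* The discovery/evaluation cuts are explicit parameters with package
  defaults; reported module counts depend on them directly.
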