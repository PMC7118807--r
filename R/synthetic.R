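# Synthetic study generator.
#
# Emulates the ingredients of a network-assisted GWAS integration study
# without any controlled-access data: a scale-free-like interactome, two
# gene-score datasets (discovery/evaluation) sharing one planted connected
# high-signal module with independent per-dataset noise, and case/control
# expression in which the planted module's pairwise correlation shifts
# between conditions. All generators are deterministic given their seed, and
# the returned truth object records every parameter needed to regenerate the
# data.

#' Generate a preferential-attachment interactome
#'
#' Construction: a complete graph on `attach + 1` seed nodes, then each new
#' node connects to `attach` distinct existing nodes chosen with probability
#' proportional to current degree. The result is connected with
#' `choose(attach + 1, 2) + attach * (n - attach - 1)` edges and a
#' heavy-tailed degree distribution. Nodes are named `G0001`, `G0002`, ...
#'
#' @param n number of genes (>= attach + 1).
#' @param attach edges added per new node (default 3).
#' @param seed integer RNG seed.
#' @return igraph PPI network.
#' @export
generate_network <- function(n, attach = 3L, seed = 1L) {
  if (n < attach + 1L) stop("need n >= attach + 1", call. = FALSE)
  set.seed(seed)
  names_all <- sprintf("G%04d", seq_len(n))
  m0 <- attach + 1L
  init <- t(combn(m0, 2L))
  edges <- matrix(0L, nrow = nrow(init) + attach * (n - m0), ncol = 2L)
  edges[seq_len(nrow(init)), ] <- init
  deg <- integer(n)
  deg[seq_len(m0)] <- m0 - 1L
  row <- nrow(init)
  for (v in seq.int(m0 + 1L, length.out = n - m0)) {
    existing <- seq_len(v - 1L)
    targets <- sample(existing, attach, prob = deg[existing])
    for (t in targets) {
      row <- row + 1L
      edges[row, ] <- c(v, t)
      deg[t] <- deg[t] + 1L
    }
    deg[v] <- attach
  }
  ppi_network(cbind(names_all[edges[, 1]], names_all[edges[, 2]]))
}

# connected planted gene set chosen by random walk from a random start
plant_module <- function(net, size) {
  nodes <- igraph::V(net)$name
  if (size > length(nodes)) stop("plant_size exceeds network size", call. = FALSE)
  if (size < 2L) stop("plant_size must be >= 2", call. = FALSE)
  planted <- sample(nodes, 1L)
  current <- planted
  while (length(planted) < size) {
    nb <- igraph::neighbors(net, current)$name
    current <- nb[sample.int(length(nb), 1L)]
    planted <- union(planted, current)
  }
  sort(planted)
}

#' Generate paired discovery/evaluation gene scores with a planted module
#'
#' A connected planted gene set is chosen by random walk. In both datasets,
#' planted genes draw `z ~ N(node_effect, noise_sd)` independently (two
#' noisy views of the same causal module, as two ancestries would give) and
#' background genes draw `z ~ N(0, 1)`; `p = 1 - pnorm(z)`.
#'
#' @param net igraph network.
#' @param plant_size number of planted genes (>= 2).
#' @param node_effect mean planted z-score.
#' @param noise_sd sd of the planted z draws (default 1).
#' @param seed integer RNG seed.
#' @return list with `discovery` and `evaluation` gene score tables and
#'   `truth` (class `synthetic_truth`).
#' @export
generate_dual_gwas <- function(net, plant_size, node_effect, noise_sd = 1,
                               seed = 1L) {
  set.seed(seed)
  genes <- igraph::V(net)$name
  planted <- plant_module(net, plant_size)
  draw <- function() {
    z <- rnorm(length(genes))
    z[match(planted, genes)] <- rnorm(length(planted), node_effect, noise_sd)
    tab <- gene_score_table(genes, clip_p(pnorm(z, lower.tail = FALSE)), 1L)
    tab
  }
  disc <- draw()
  eval <- draw()
  truth <- structure(list(planted_genes = planted, node_effect = node_effect,
                          noise_sd = noise_sd, seed = seed,
                          n_genes = length(genes)),
                     class = "synthetic_truth")
  list(discovery = disc, evaluation = eval, truth = truth)
}

# equicorrelated multivariate normal draws: n obs x k dims with pairwise
# correlation r, via a shared-factor construction (requires 0 <= r < 1; for
# small negative r falls back to Cholesky)
requicorr <- function(n, k, r) {
  if (r <= -1 / (k - 1) || r >= 1) {
    stop("equicorrelation ", r, " is not positive definite for k = ", k,
         call. = FALSE)
  }
  if (r >= 0) {
    shared <- rnorm(n)
    sqrt(r) * matrix(shared, n, k) + sqrt(1 - r) * matrix(rnorm(n * k), n, k)
  } else {
    sigma <- matrix(r, k, k)
    diag(sigma) <- 1
    matrix(rnorm(n * k), n, k) %*% chol(sigma)
  }
}

#' Generate case/control expression with a planted co-expression shift
#'
#' Planted genes are drawn from an equicorrelated multivariate normal with
#' pairwise correlation `r_case` in cases and `r_control` in controls;
#' background genes are independent `N(0, 1)`. All values sit on a baseline
#' of 7 log2 units (typical normalized array intensity); planted case means
#' are additionally shifted by `de_shift` log2 units.
#'
#' @param net igraph network (defines the gene list).
#' @param truth `synthetic_truth` naming the planted genes.
#' @param n_case,n_control sample counts (defaults 7 and 6, both >= 4).
#' @param r_case,r_control planted pairwise correlations (defaults 0.8, 0).
#' @param de_shift planted case-mean shift in log2 units (default 0).
#' @param seed integer RNG seed.
#' @return `expression_set` over all network genes.
#' @export
generate_expression <- function(net, truth, n_case = 7L, n_control = 6L,
                                r_case = 0.8, r_control = 0, de_shift = 0,
                                seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_case < 4L || n_control < 4L) {
    stop("need >= 4 samples per condition", call. = FALSE)
  }
  set.seed(seed)
  genes <- igraph::V(net)$name
  planted <- truth$planted_genes
  stop_if_missing_genes(planted, genes)
  k <- length(planted)
  n <- n_case + n_control
  values <- matrix(rnorm(length(genes) * n, mean = 7), length(genes), n,
                   dimnames = list(genes,
                                   c(sprintf("CASE%02d", seq_len(n_case)),
                                     sprintf("CTRL%02d", seq_len(n_control)))))
  values[planted, seq_len(n_case)] <-
    7 + de_shift + t(requicorr(n_case, k, r_case))
  values[planted, n_case + seq_len(n_control)] <-
    7 + t(requicorr(n_control, k, r_control))
  expression_set(values,
                 c(rep("case", n_case), rep("control", n_control)),
                 check_scale = FALSE)
}

#' Split gene-level expression into probe-level values
#'
#' Thin wrapper to exercise probe collapsing: each gene is split into 1-3
#' probes whose values are the gene value plus a `N(0, 0.1)` probe offset.
#'
#' @param es gene-level `expression_set`.
#' @param seed integer RNG seed.
#' @return list with `values` (probe x sample matrix) and `probe_map`
#'   (probe id to gene).
#' @export
generate_probe_expression <- function(es, seed = 1L) {
  set.seed(seed)
  genes <- rownames(es$values)
  n_probes <- sample(1:3, length(genes), replace = TRUE)
  probe_gene <- rep(genes, n_probes)
  probe_id <- paste0(probe_gene, "_at", sequence(n_probes))
  offsets <- rnorm(length(probe_id), 0, 0.1)
  values <- es$values[probe_gene, , drop = FALSE] + offsets
  rownames(values) <- probe_id
  probe_map <- probe_gene
  names(probe_map) <- probe_id
  list(values = values, probe_map = probe_map)
}

#' Write a complete synthetic study to disk
#'
#' Generates a network, dual gene scores, expression with conditions, gene
#' annotations with SNP-level p-values (round-trippable through the score
#' stage), and a truth JSON, all under `dir` in the standard pipeline input
#' formats.
#'
#' @param dir output directory (created if needed).
#' @param n network size.
#' @param plant_size,node_effect,noise_sd planted-module parameters.
#' @param r_case,r_control,de_shift expression parameters.
#' @param seed master seed; per-component seeds are derived with
#'   [derive_seed()].
#' @return invisible named vector of written file paths.
#' @export
simulate_study <- function(dir, n = 500L, plant_size = 8L, node_effect = 3.5,
                           noise_sd = 1, r_case = 0.8, r_control = 0,
                           de_shift = 0, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- generate_network(n, seed = derive_seed(seed, "network"))
  gw <- generate_dual_gwas(net, plant_size, node_effect, noise_sd,
                           seed = derive_seed(seed, "gwas"))
  es <- generate_expression(net, gw$truth, r_case = r_case,
                            r_control = r_control, de_shift = de_shift,
                            seed = derive_seed(seed, "expression"))
  snps <- synthesize_snps(gw$discovery, seed = derive_seed(seed, "snps"))
  paths <- c(
    network = file.path(dir, "network.tsv"),
    scores_disc = file.path(dir, "scores_discovery.tsv"),
    scores_eval = file.path(dir, "scores_evaluation.tsv"),
    expression = file.path(dir, "expression.tsv"),
    conditions = file.path(dir, "conditions.tsv"),
    snps = file.path(dir, "snps.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_network(net, paths["network"], format = "edge_list")
  write_gene_scores(gw$discovery, paths["scores_disc"])
  write_gene_scores(gw$evaluation, paths["scores_eval"])
  expr_df <- data.frame(gene = rownames(es$values), es$values,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write.table(expr_df, paths["expression"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = colnames(es$values),
                         condition = es$condition),
              paths["conditions"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(snps$snps, paths["snps"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(snps$annotations, paths["annotations"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(planted_genes = gw$truth$planted_genes,
         node_effect = node_effect, noise_sd = noise_sd,
         r_case = r_case, r_control = r_control, de_shift = de_shift,
         n = n, plant_size = plant_size, seed = seed),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# SNP-level p-values consistent with a gene score table: one locus per gene
# on a synthetic chromosome, 1-3 SNPs per gene, the gene's p assigned to its
# top SNP and the rest uniform
synthesize_snps <- function(scores, gene_span = 20000L, spacing = 200000L,
                            seed = 1L) {
  set.seed(seed)
  n <- nrow(scores)
  start <- spacing * seq_len(n)
  annot <- data.frame(gene = scores$gene, chrom = "chr1", start = start,
                      end = start + gene_span, strand = "+",
                      stringsAsFactors = FALSE)
  n_snps <- sample(1:3, n, replace = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    pos <- sort(sample(seq(start[i], start[i] + gene_span), n_snps[i]))
    p <- runif(n_snps[i])
    p[sample.int(n_snps[i], 1L)] <- scores$p[i]
    data.frame(snp = sprintf("rs%d_%d", i, seq_len(n_snps[i])),
               chrom = "chr1", pos = pos, p = p, stringsAsFactors = FALSE)
  })
  list(snps = do.call(rbind, rows), annotations = annot)
}
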