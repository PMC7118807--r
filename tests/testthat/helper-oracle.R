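# Independent step-by-step simulator of the greedy expansion rule.
#
# Coded from the documented rule only, with its own adjacency-list BFS and
# from-scratch rescoring at every step; no code shared with the package's
# search. Used to cross-check dense_module_search (single-gene start) and
# the edge-weighted search in its node-only limit (two-gene start).

oracle_adjacency <- function(edges) {
  edges <- as.matrix(edges)
  nodes <- sort(unique(c(edges[, 1], edges[, 2])))
  adj <- lapply(nodes, function(v) {
    sort(unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])))
  })
  names(adj) <- nodes
  adj
}

# all nodes within BFS distance <= d of the set, excluding the set
oracle_within <- function(adj, genes, d) {
  frontier <- genes
  seen <- genes
  for (step in seq_len(d)) {
    frontier <- setdiff(unique(unlist(adj[frontier])), seen)
    if (length(frontier) == 0L) break
    seen <- c(seen, frontier)
  }
  sort(setdiff(seen, genes))
}

oracle_greedy <- function(adj, z, genes, d, r, max_iter = 1000L) {
  for (iter in seq_len(max_iter)) {
    cands <- oracle_within(adj, genes, d)
    if (length(cands) == 0L) break
    zm <- sum(z[genes]) / sqrt(length(genes))
    news <- vapply(cands, function(g) {
      sum(z[c(genes, g)]) / sqrt(length(genes) + 1)
    }, 0)
    ord <- order(-news, cands)
    best <- cands[ord[1L]]
    thr <- if (zm > 0) zm * (1 + r) else zm + abs(zm) * r
    if (!(news[ord[1L]] > thr)) break
    if (any(adj[[best]] %in% genes)) {
      genes <- c(genes, best)
    } else {
      nb_mod <- unique(c(genes, unlist(adj[genes])))
      common <- setdiff(intersect(adj[[best]], nb_mod), c(genes, best))
      linker <- common[order(-z[common], common)][1L]
      genes <- c(genes, linker, best)
    }
  }
  genes
}

# random test instance: preferential-attachment graph + N(0,1)-ish z-scores
# with a few elevated genes so module growth actually happens
random_instance <- function(n, seed, attach = 2L) {
  net <- generate_network(n, attach = attach, seed = seed)
  set.seed(seed + 7L)
  z <- rnorm(n)
  hot <- sample.int(n, max(1L, n %/% 6L))
  z[hot] <- z[hot] + 2.5
  genes <- igraph::V(net)$name
  names(z) <- genes
  list(net = net, z = z,
       scores = gene_score_table(genes, pnorm(z, lower.tail = FALSE)),
       adj = oracle_adjacency(igraph::as_edgelist(net)))
}
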