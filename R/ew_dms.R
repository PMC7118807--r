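# Edge-weighted dense module search.
#
# The search runs on a network carrying both node weights (gene z-scores)
# and edge weights (differential co-expression statistics). A module's score
# is s = lambda * z_node + (1 - lambda) * z_edge, where z_node is the usual
# sum(z)/sqrt(k) over member genes and z_edge mirrors it over member edge
# weights, sum(w)/sqrt(m). Seeds are edges, so every module has at least two
# genes and one edge; expansion follows the same greedy acceptance rule as
# the node-weighted search, applied to s.

#' Combined node/edge module score
#'
#' `s = lam * z_node + (1 - lam) * z_edge` with the mixing parameter
#' `lam` in \[0, 1\]; `lam = 1` ignores edges, `lam = 0` ignores nodes.
#'
#' @param z_node node-score component.
#' @param z_edge edge-score component.
#' @param lam mixing proportion in \[0, 1\].
#' @return the combined score.
#' @export
combined_score <- function(z_node, z_edge, lam) {
  if (!is.finite(lam) || lam < 0 || lam > 1) {
    stop("lam must lie in [0, 1]", call. = FALSE)
  }
  lam * z_node + (1 - lam) * z_edge
}

# weighted search substrate: nodes with scores, edges with weights; returns
# the igraph plus per-node neighbor-weight lists
build_ew_substrate <- function(net, scores, ew) {
  z <- scores$z
  names(z) <- scores$gene
  keep <- ew$gene_a %in% names(z) & ew$gene_b %in% names(z)
  ew <- ew[keep, , drop = FALSE]
  if (nrow(ew) == 0L) {
    stop("no edge has both a weight and scored endpoints", call. = FALSE)
  }
  known <- igraph::V(net)$name
  stop_if_missing_genes(unique(c(ew$gene_a, ew$gene_b)), known)
  snet <- igraph::graph_from_edgelist(as.matrix(ew[, c("gene_a", "gene_b")]),
                                      directed = FALSE)
  igraph::E(snet)$weight <- ew$w
  nbrw <- lapply(igraph::V(snet)$name, function(g) {
    inc <- igraph::incident(snet, g)
    ends <- igraph::ends(snet, inc)
    other <- ifelse(ends[, 1] == g, ends[, 2], ends[, 1])
    w <- inc$weight
    names(w) <- other
    w
  })
  names(nbrw) <- igraph::V(snet)$name
  list(net = snet, z = z, nbrw = nbrw, ew = ew)
}

# sum of member-edge weights and member-edge count for a gene set
module_edge_stats <- function(genes, nbrw) {
  sw <- 0
  m <- 0L
  for (i in seq_along(genes)) {
    wi <- nbrw[[genes[i]]]
    hit <- names(wi) %in% genes
    sw <- sw + sum(wi[hit])
    m <- m + sum(hit)
  }
  list(sum_w = sw / 2, m = m %/% 2L)
}

#' Edge-weighted dense module search
#'
#' One greedy search per seed edge, maximizing the combined score under the
#' acceptance rule `s_new > s * (1 + r)` (with the same non-positive-score
#' handling as [dense_module_search()]). Modules are capped at `max_size`
#' genes and deduplicated by exact gene-set equality, keeping the seed with
#' the highest score.
#'
#' @param net igraph PPI network.
#' @param scores gene score table (node weights).
#' @param ew edge weight table from [edge_weight()].
#' @param lam mixing parameter in \[0, 1\], or `"auto"` to equalize the
#'   spread of node and edge contributions (`lam = sd(w) / (sd(z) + sd(w))`,
#'   reported via message).
#' @param d neighborhood distance (default 2).
#' @param r expansion increment threshold (default 0.1).
#' @param max_size maximum module size (default 10).
#' @param max_iter cap on expansion steps per module.
#' @return object of class `ew_module_set`: list of modules each with
#'   `seed_edge`, `genes`, `z_node`, `z_edge`, `s`, plus `params`.
#' @export
ew_dense_module_search <- function(net, scores, ew, lam = 0.5, d = 2L,
                                   r = 0.1, max_size = 10L, max_iter = 1000L) {
  stopifnot(d >= 1L, r >= 0, max_size >= 2L)
  sub <- build_ew_substrate(net, scores, ew)
  if (identical(lam, "auto")) {
    szd <- sd(sub$z[igraph::V(sub$net)$name])
    swd <- sd(sub$ew$w)
    lam <- if (szd + swd == 0) 0.5 else swd / (szd + swd)
    message(sprintf("auto lambda = %.4f", lam))
  }
  if (!is.finite(lam) || lam < 0 || lam > 1) {
    stop("lam must lie in [0, 1]", call. = FALSE)
  }
  z <- sub$z
  nbrw <- sub$nbrw
  score_fn <- function(genes) {
    st <- module_edge_stats(genes, nbrw)
    combined_score(module_score(z[genes]),
                   if (st$m > 0L) st$sum_w / sqrt(st$m) else 0, lam)
  }
  make_tent_fn <- function() {
    function(genes, cands) {
      sum_z <- sum(z[genes])
      st <- module_edge_stats(genes, nbrw)
      k1 <- sqrt(length(genes) + 1)
      vapply(cands, function(g) {
        wi <- nbrw[[g]]
        hit <- names(wi) %in% genes
        m_new <- st$m + sum(hit)
        ze <- if (m_new > 0L) (st$sum_w + sum(wi[hit])) / sqrt(m_new) else 0
        combined_score((sum_z + z[g]) / k1, ze, lam)
      }, 0)
    }
  }
  tent_fn <- make_tent_fn()
  el <- igraph::as_edgelist(sub$net)
  ord <- order(el[, 1], el[, 2])
  el <- el[ord, , drop = FALSE]
  modules <- lapply(seq_len(nrow(el)), function(i) {
    seed <- c(el[i, 1], el[i, 2])
    res <- expand_greedy(sub$net, seed, z, tent_fn, score_fn, d, r,
                         max_size = max_size, max_iter = max_iter)
    st <- module_edge_stats(res$genes, nbrw)
    list(seed_edge = seed, genes = res$genes,
         z_node = module_score(z[res$genes]),
         z_edge = if (st$m > 0L) st$sum_w / sqrt(st$m) else 0,
         s = res$score)
  })
  # deduplicate identical gene sets, keeping the best score
  key <- vapply(modules, function(m) paste(sort(m$genes), collapse = ","), "")
  s_all <- vapply(modules, `[[`, 0, "s")
  keep <- !duplicated(key[order(-s_all, key)])[order(order(-s_all, key))]
  modules <- modules[keep]
  structure(list(modules = modules,
                 params = list(lam = lam, d = d, r = r, max_size = max_size)),
            class = "ew_module_set")
}

#' @export
print.ew_module_set <- function(x, ...) {
  sizes <- vapply(x$modules, function(m) length(m$genes), 0L)
  cat(sprintf("ew_module_set: %d modules (lambda = %.3f, d = %s, r = %s)\n",
              length(x$modules), x$params$lam, x$params$d, x$params$r))
  cat(sprintf("  size %d-%d\n", min(sizes), max(sizes)))
  invisible(x)
}

#' @export
as.data.frame.ew_module_set <- function(x, ...) {
  data.frame(
    seed_edge = vapply(x$modules, function(m) paste(m$seed_edge, collapse = "-"), ""),
    size = vapply(x$modules, function(m) length(m$genes), 0L),
    z_node = vapply(x$modules, `[[`, 0, "z_node"),
    z_edge = vapply(x$modules, `[[`, 0, "z_edge"),
    s = vapply(x$modules, `[[`, 0, "s"),
    p_perm = if (!is.null(x$modules[[1L]]$p_perm))
      vapply(x$modules, `[[`, 0, "p_perm") else NA_real_,
    genes = vapply(x$modules, function(m) paste(m$genes, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
}

# one uniform random connected subgraph of k genes: random edge seed, then
# repeated uniform choice among neighbors of the current set
random_connected_subgraph <- function(snet, k, nbrw, max_restart = 100L) {
  el <- igraph::as_edgelist(snet)
  for (attempt in seq_len(max_restart)) {
    e <- el[sample.int(nrow(el), 1L), ]
    genes <- c(e[1], e[2])
    while (length(genes) < k) {
      nb <- setdiff(unique(unlist(lapply(genes, function(g) names(nbrw[[g]])))),
                    genes)
      if (length(nb) == 0L) break
      genes <- c(genes, nb[sample.int(length(nb), 1L)])
    }
    if (length(genes) == k) return(genes)
  }
  stop("could not sample a connected subgraph of size ", k, call. = FALSE)
}

#' Permutation significance of edge-weighted modules
#'
#' For each distinct module size k, a null distribution of the combined
#' score is built from `n_perm` random connected subgraphs of size k (random
#' edge seed, uniform random connected growth) scored with the observed node
#' and edge weights; `p_perm = (1 + #\{null >= s\}) / (n_perm + 1)`.
#' Deterministic given `seed`.
#'
#' @param modules `ew_module_set`.
#' @param net,scores,ew,lam the search inputs (weights are reused, not
#'   refit). `lam = NULL` reuses the lambda recorded in `modules`.
#' @param n_perm number of null draws per size (>= 100).
#' @param seed integer RNG seed.
#' @return the module set with `p_perm` added per module.
#' @export
permutation_significance <- function(modules, net, scores, ew, lam = NULL,
                                     n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(modules, "ew_module_set"))
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  lam <- lam %||% modules$params$lam
  sub <- build_ew_substrate(net, scores, ew)
  z <- sub$z
  nbrw <- sub$nbrw
  score_fn <- function(genes) {
    st <- module_edge_stats(genes, nbrw)
    combined_score(module_score(z[genes]),
                   if (st$m > 0L) st$sum_w / sqrt(st$m) else 0, lam)
  }
  sizes <- sort(unique(vapply(modules$modules, function(m) length(m$genes), 0L)))
  comp <- igraph::components(sub$net)
  if (max(sizes) > max(comp$csize)) {
    stop("module size exceeds the largest connected component", call. = FALSE)
  }
  set.seed(seed)
  null_by_size <- lapply(sizes, function(k) {
    vapply(seq_len(n_perm), function(i) {
      score_fn(random_connected_subgraph(sub$net, k, nbrw))
    }, 0)
  })
  names(null_by_size) <- as.character(sizes)
  modules$modules <- lapply(modules$modules, function(m) {
    null <- null_by_size[[as.character(length(m$genes))]]
    m$p_perm <- (1 + sum(null >= m$s)) / (n_perm + 1)
    m
  })
  modules$params$n_perm <- n_perm
  modules$params$perm_seed <- seed
  modules
}
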