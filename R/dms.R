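# Node-weighted greedy dense module search.
#
# Every scored gene in the network seeds one module. A module grows by
# best-first recruitment: all genes within distance d of the current members
# are tentatively scored one at a time, and the single candidate giving the
# highest new module score is recruited provided the new score exceeds
# Z_m * (1 + r). The search is deterministic: ties are broken by
# lexicographic gene symbol.
#
# The candidate score is always the singleton score of (members + candidate),
# the quantity Z_{m+1} of the expansion rule. Because candidates may sit two
# hops away, a recruited non-adjacent gene is accompanied by one linker gene
# (a common neighbor with the highest z, lexicographic tie-break) so that
# module gene sets always induce connected subgraphs. Termination therefore
# certifies local maximality with respect to singleton additions of every
# distance-<=d neighbor.

#' Raw module score
#'
#' `Z_m = sum(z) / sqrt(k)` over the k member gene z-scores.
#'
#' @param zs non-empty numeric vector of member z-scores.
#' @return the module score.
#' @export
module_score <- function(zs) {
  if (length(zs) == 0L) stop("module score of an empty gene set", call. = FALSE)
  sum(zs) / sqrt(length(zs))
}

# acceptance threshold for the expansion rule; the multiplicative criterion
# Z_{m+1} > Z_m * (1 + r) is ill-posed for Z_m <= 0, where the rule becomes
# new > Z_m + |Z_m| * r (strict improvement still required at Z_m = 0)
accept_threshold <- function(score, r) {
  if (score > 0) score * (1 + r) else score + abs(score) * r
}

# one linker gene joining `cand` to the module: a common neighbor of cand and
# the current members, highest z first, then lexicographic
pick_linker <- function(net, genes, cand, z) {
  nb_cand <- igraph::neighbors(net, cand)$name
  nb_mod <- unique(unlist(lapply(
    igraph::ego(net, order = 1, nodes = genes), function(v) v$name)))
  common <- setdiff(intersect(nb_cand, nb_mod), c(genes, cand))
  if (length(common) == 0L) {
    # distance > 2: fall back to interior of one shortest path
    sp <- igraph::shortest_paths(net, from = cand, to = genes[1L])$vpath[[1L]]$name
    return(setdiff(sp, c(genes, cand)))
  }
  common[order(-z[common], common)][1L]
}

# greedy best-first expansion shared by the node-weighted and edge-weighted
# searches; tent_fn(genes, cands) returns the tentative score of
# (genes + one candidate) for each candidate, score_fn(genes) the score of a
# full gene set
expand_greedy <- function(net, genes, z, tent_fn, score_fn, d, r,
                          max_size = Inf, max_iter = 1000L) {
  score <- score_fn(genes)
  nonpositive_rule <- 0L
  for (iter in seq_len(max_iter)) {
    if (length(genes) >= max_size) break
    cands <- neighborhood(net, genes, d)
    if (max_size - length(genes) < 2L) {
      # no room for a linker: only candidates adjacent to the module fit
      adj <- unique(unlist(lapply(igraph::ego(net, order = 1, nodes = genes),
                                  function(v) v$name)))
      cands <- intersect(cands, adj)
    }
    if (length(cands) == 0L) break
    tent <- tent_fn(genes, cands)
    best_i <- order(-tent, cands)[1L]
    best <- cands[best_i]
    if (score <= 0) nonpositive_rule <- nonpositive_rule + 1L
    if (!(tent[best_i] > accept_threshold(score, r))) break
    nb_best <- igraph::neighbors(net, best)$name
    if (!any(nb_best %in% genes)) {
      genes <- c(genes, pick_linker(net, genes, best, z), best)
    } else {
      genes <- c(genes, best)
    }
    score <- score_fn(genes)
    if (iter == max_iter) warning("module expansion hit max_iter", call. = FALSE)
  }
  list(genes = genes, score = score, nonpositive_rule = nonpositive_rule)
}

#' Dense module search on a node-weighted PPI network
#'
#' Runs one greedy expansion per seed gene. The search substrate is the
#' subgraph induced on genes that carry a z-score (network genes without
#' scores are excluded; scored genes absent from the network are ignored).
#'
#' @param net igraph PPI network.
#' @param scores gene score table (see [gene_score_table()]).
#' @param d neighborhood distance (default 2).
#' @param r expansion increment threshold (default 0.1); growth stops when no
#'   candidate achieves `Z_{m+1} > Z_m * (1 + r)`.
#' @param max_iter cap on expansion steps per module.
#' @param seeds optional character vector of seed genes (default: every
#'   scored network gene).
#' @return an object of class `module_set`: list with `modules` (each with
#'   `seed`, `genes` in insertion order and `z_m`) and `params`.
#' @export
dense_module_search <- function(net, scores, d = 2L, r = 0.1,
                                max_iter = 1000L, seeds = NULL) {
  stopifnot(d >= 1L, r >= 0)
  z <- scores$z
  names(z) <- scores$gene
  search_genes <- intersect(igraph::V(net)$name, scores$gene)
  if (!is.null(seeds)) {
    unscored <- setdiff(seeds, scores$gene)
    if (length(unscored) > 0L) {
      stop("seed gene without score: ", paste(unscored, collapse = ", "),
           call. = FALSE)
    }
    stop_if_missing_genes(seeds, igraph::V(net)$name)
  } else {
    seeds <- sort(search_genes)
  }
  snet <- igraph::induced_subgraph(net, search_genes)
  tent_fn <- function(genes, cands) {
    (sum(z[genes]) + z[cands]) / sqrt(length(genes) + 1)
  }
  score_fn <- function(genes) module_score(z[genes])
  modules <- lapply(seeds, function(seed) {
    res <- expand_greedy(snet, seed, z, tent_fn, score_fn, d, r,
                         max_iter = max_iter)
    list(seed = seed, genes = res$genes, z_m = res$score)
  })
  structure(list(modules = modules,
                 params = list(d = d, r = r, max_iter = max_iter)),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- vapply(x$modules, function(m) length(m$genes), 0L)
  cat(sprintf("module_set: %d modules (d = %s, r = %s)\n",
              length(x$modules), x$params$d, x$params$r))
  cat(sprintf("  size %d-%d, mean %.2f\n", min(sizes), max(sizes), mean(sizes)))
  if (!is.null(x$modules[[1L]]$z_n)) {
    zn <- vapply(x$modules, `[[`, 0, "z_n")
    cat(sprintf("  Z_n range %.2f to %.2f\n", min(zn), max(zn)))
  }
  invisible(x)
}

#' @export
as.data.frame.module_set <- function(x, ...) {
  data.frame(
    seed = vapply(x$modules, `[[`, "", "seed"),
    size = vapply(x$modules, function(m) length(m$genes), 0L),
    z_m = vapply(x$modules, `[[`, 0, "z_m"),
    z_n = if (!is.null(x$modules[[1L]]$z_n))
      vapply(x$modules, `[[`, 0, "z_n") else NA_real_,
    genes = vapply(x$modules, function(m) paste(m$genes, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
}

#' Normalize module scores across a module set
#'
#' `Z_n = (Z_m - mean) / sd` with the population (divide-by-n) standard
#' deviation over all modules of the run.
#'
#' @param ms `module_set`.
#' @return the module set with `z_n` added per module and `score_mean`,
#'   `score_sd` recorded.
#' @export
normalize_scores <- function(ms) {
  zm <- vapply(ms$modules, `[[`, 0, "z_m")
  if (length(zm) < 2L) stop("need >= 2 modules to normalize", call. = FALSE)
  s <- pop_sd(zm)
  if (s == 0) stop("zero variance in module scores", call. = FALSE)
  m <- mean(zm)
  ms$modules <- lapply(ms$modules, function(mod) {
    mod$z_n <- (mod$z_m - m) / s
    mod
  })
  ms$score_mean <- m
  ms$score_sd <- s
  ms
}

#' Top-k subnetwork and per-gene report
#'
#' Takes the k modules with the highest normalized score (ties broken
#' lexicographically by seed), merges them into one induced subgraph and
#' reports each member gene's p, z, the number of top-k modules containing
#' it, and a nominal-significance flag (p < 0.05).
#'
#' @param ms normalized `module_set`.
#' @param net igraph network the modules were searched on.
#' @param scores gene score table.
#' @param k number of top modules (default 50); when k exceeds the number of
#'   modules all are used with a warning.
#' @return list with `subnetwork` (igraph), `genes` (per-gene data frame),
#'   `frac_nominal` and the selected `modules`.
#' @export
top_k_subnetwork <- function(ms, net, scores, k = 50L) {
  stopifnot(k >= 1L)
  if (is.null(ms$modules[[1L]]$z_n)) ms <- normalize_scores(ms)
  if (k > length(ms$modules)) {
    warning("k exceeds the number of modules; using all modules", call. = FALSE)
    k <- length(ms$modules)
  }
  zn <- vapply(ms$modules, `[[`, 0, "z_n")
  seeds <- vapply(ms$modules, `[[`, "", "seed")
  top <- ms$modules[order(-zn, seeds)[seq_len(k)]]
  gene_sets <- lapply(top, `[[`, "genes")
  sub <- merge_modules(net, gene_sets)
  counts <- table(unlist(lapply(gene_sets, unique)))
  membership <- as.integer(counts)
  names(membership) <- names(counts)
  rep <- node_attributes(sub, scores, membership)
  rep$nominal <- rep$p < 0.05
  list(subnetwork = sub, genes = rep,
       frac_nominal = mean(rep$nominal, na.rm = TRUE),
       modules = top)
}

#' Post-hoc local-maximality certificate
#'
#' Exhaustively rescans every gene within distance d of a module and checks
#' that no singleton addition would have beaten the expansion threshold:
#' `module_score(genes + g) <= threshold(Z_m, r)` for all such g. Computed
#' naively, independent of any caching in the search.
#'
#' @param net igraph network (the search substrate).
#' @param scores gene score table.
#' @param ms `module_set` to certify.
#' @return logical vector, one certificate per module.
#' @export
check_local_maximality <- function(net, scores, ms) {
  z <- scores$z
  names(z) <- scores$gene
  snet <- igraph::induced_subgraph(net,
                                   intersect(igraph::V(net)$name, scores$gene))
  d <- ms$params$d
  r <- ms$params$r
  vapply(ms$modules, function(mod) {
    zm <- module_score(z[mod$genes])
    cands <- neighborhood(snet, mod$genes, d)
    if (length(cands) == 0L) return(TRUE)
    thr <- accept_threshold(zm, r)
    all(vapply(cands, function(g) module_score(z[c(mod$genes, g)]), 0) <= thr)
  }, TRUE)
}

#' Write a module table to TSV
#'
#' @param ms `module_set` (or edge-weighted module list from
#'   [ew_dense_module_search()]).
#' @param path output path.
#' @export
write_modules <- function(ms, path) {
  df <- as.data.frame(ms)
  df <- cbind(module_id = seq_len(nrow(df)), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
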