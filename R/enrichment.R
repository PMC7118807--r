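# Over-representation analysis of module genes.
#
# Standard hypergeometric ORA against GMT gene-set collections: sets are
# restricted to the background universe, filtered to 10..500 members, tested
# one-sided for over-representation and Bonferroni-corrected over the number
# of sets actually tested. A redundancy-reduction step clusters significant
# sets by Jaccard similarity with affinity propagation and flags one
# exemplar per cluster.

#' Read a GMT gene-set collection
#'
#' @param path GMT file: per row, set id, description and tab-separated
#'   member genes.
#' @param universe optional background gene vector; defaults to the union of
#'   all set members.
#' @return object of class `gene_set_collection`: list with `sets` (named
#'   list of gene vectors), `desc` and `universe`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 3L)
  if (length(bad) > 0L) {
    stop("malformed GMT row at line ", bad[1L], call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  names(desc) <- names(sets)
  gene_set_collection(sets, desc)
}

#' @rdname read_gmt
#' @param sets named list of gene vectors.
#' @param desc named character vector of set descriptions.
#' @export
gene_set_collection <- function(sets, desc = NULL, universe = NULL) {
  sets <- lapply(sets, function(s) unique(toupper(s)))
  desc <- desc %||% setNames(names(sets), names(sets))
  universe <- toupper(universe %||% unique(unlist(sets)))
  structure(list(sets = sets, desc = desc, universe = universe),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation test
#'
#' Query genes are restricted to the universe; sets whose universe-restricted
#' size falls outside `[min_size, max_size]` are excluded before testing and
#' do not count toward the Bonferroni denominator. The p-value is the
#' one-sided upper tail `P(X >= overlap)` of the hypergeometric distribution
#' with population `|universe|`, `pathway_size` successes and
#' `|query in universe|` draws.
#'
#' @param query character vector of genes.
#' @param coll `gene_set_collection`.
#' @param min_size,max_size set-size filters (defaults 10 and 500).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param universe optional override of the background; typically the
#'   intersection of the scored-gene list and the collection's universe.
#' @return data frame (set_id, set_name, pathway_size, overlap, p, p_adj,
#'   significant), sorted by p.
#' @export
enrich <- function(query, coll, min_size = 10L, max_size = 500L,
                   alpha = 0.05, universe = NULL) {
  stopifnot(inherits(coll, "gene_set_collection"))
  universe <- toupper(universe %||% coll$universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query <- intersect(unique(toupper(query)), universe)
  if (length(query) == 0L) stop("no query gene in the universe", call. = FALSE)
  sets_u <- lapply(coll$sets, intersect, universe)
  sizes <- vapply(sets_u, length, 0L)
  tested <- sizes >= min_size & sizes <= max_size
  sets_u <- sets_u[tested]
  if (length(sets_u) == 0L) {
    return(data.frame(set_id = character(), set_name = character(),
                      pathway_size = integer(), overlap = integer(),
                      p = numeric(), p_adj = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  N <- length(universe)
  n_q <- length(query)
  overlap <- vapply(sets_u, function(s) length(intersect(s, query)), 0L)
  size <- sizes[tested]
  p <- phyper(overlap - 1L, size, N - size, n_q, lower.tail = FALSE)
  p_adj <- pmin(1, p * length(sets_u))
  out <- data.frame(set_id = names(sets_u),
                    set_name = unname(coll$desc[names(sets_u)]),
                    pathway_size = unname(size), overlap = unname(overlap),
                    p = unname(p), p_adj = unname(p_adj),
                    significant = unname(p_adj <= alpha),
                    stringsAsFactors = FALSE)
  out[order(out$p, out$set_id), , drop = FALSE]
}

# affinity propagation on a similarity matrix; returns exemplar index per
# item or NULL when not converged. A deterministic sub-1e-9 jitter breaks the
# exact-tie symmetry of identical items, which otherwise never resolves.
affinity_propagation <- function(S, damping = 0.9, max_iter = 1000L,
                                 conv_iter = 50L) {
  n <- nrow(S)
  S <- S + outer(seq_len(n), seq_len(n), function(i, j) i + n * j) * 1e-10 / n
  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  stable <- 0L
  last <- rep(-1L, n)
  for (it in seq_len(max_iter)) {
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    max2 <- vapply(seq_len(n), function(i) {
      max(AS[i, -which1[i]])
    }, 0)
    Rnew <- S - max1
    for (i in seq_len(n)) Rnew[i, which1[i]] <- S[i, which1[i]] - max2[i]
    R <- damping * R + (1 - damping) * Rnew
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(rep(colsum, each = n), n, n) - Rp
    Anew <- pmin(Anew, 0)
    diag(Anew) <- colsum - diag(Rp)
    A <- damping * A + (1 - damping) * Anew
    exemplars <- which(diag(A + R) > 0)
    assign <- if (length(exemplars) > 0L) {
      vapply(seq_len(n), function(i) {
        exemplars[which.max(S[i, exemplars])]
      }, 0L)
    } else rep(-1L, n)
    if (length(exemplars) > 0L) assign[exemplars] <- exemplars
    if (identical(assign, last)) stable <- stable + 1L else stable <- 0L
    last <- assign
    if (stable >= conv_iter && length(exemplars) > 0L) return(assign)
  }
  NULL
}

#' Cluster redundant enriched sets and flag exemplars
#'
#' Significant rows are clustered on pairwise Jaccard similarity of their
#' universe-restricted gene sets using affinity propagation (damping 0.9,
#' preference = median similarity); if AP fails to converge within 1000
#' iterations a greedy fallback assigns sets, best p first, to an existing
#' exemplar at Jaccard >= 0.5 or opens a new cluster. All input rows are
#' preserved; significant rows gain a cluster id and an exemplar flag (the
#' cluster member with the smallest p).
#'
#' @param rows enrichment table from [enrich()].
#' @param coll `gene_set_collection` the rows were tested against.
#' @param universe optional universe override (must match the one used in
#'   [enrich()]).
#' @return `rows` with `cluster` and `exemplar` columns added.
#' @export
reduce_redundancy <- function(rows, coll, universe = NULL) {
  rows$cluster <- NA_integer_
  rows$exemplar <- FALSE
  sig <- which(rows$significant)
  if (length(sig) == 0L) return(rows)
  if (length(sig) == 1L) {
    rows$cluster[sig] <- 1L
    rows$exemplar[sig] <- TRUE
    return(rows)
  }
  universe <- toupper(universe %||% coll$universe)
  sets <- lapply(coll$sets[rows$set_id[sig]], intersect, universe)
  n <- length(sets)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        S[i, j] <- length(intersect(sets[[i]], sets[[j]])) /
          length(union(sets[[i]], sets[[j]]))
      }
    }
  }
  pref <- median(S[upper.tri(S) | lower.tri(S)])
  S0 <- S
  diag(S) <- pref
  assign <- affinity_propagation(S)
  if (!is.null(assign)) {
    # zero Jaccard overlap with the exemplar never justifies co-clustering
    lonely <- S0[cbind(seq_len(n), assign)] <= 0 & assign != seq_len(n)
    assign[lonely] <- which(lonely)
  }
  if (is.null(assign)) {
    # greedy fallback: best p first, join an exemplar at Jaccard >= 0.5
    ord <- order(rows$p[sig])
    assign <- integer(n)
    exemplars <- integer(0)
    for (i in ord) {
      sims <- if (length(exemplars) > 0L) S[i, exemplars] else numeric(0)
      if (length(sims) > 0L && max(sims) >= 0.5) {
        assign[i] <- exemplars[which.max(sims)]
      } else {
        exemplars <- c(exemplars, i)
        assign[i] <- i
      }
    }
  }
  cluster_ids <- match(assign, sort(unique(assign)))
  rows$cluster[sig] <- cluster_ids
  for (cl in unique(cluster_ids)) {
    members <- sig[cluster_ids == cl]
    rows$exemplar[members[which.min(rows$p[members])]] <- TRUE
  }
  rows
}

#' Venn-region counts for two or three gene sets
#'
#' @param named_sets named list of 2 or 3 character vectors.
#' @return list with `regions` (data frame of exclusive region counts, one
#'   row per membership pattern) and `totals` (per-set cardinality).
#' @export
summarize_overlap <- function(named_sets) {
  k <- length(named_sets)
  if (k < 2L || k > 3L) stop("need 2 or 3 sets", call. = FALSE)
  named_sets <- lapply(named_sets, unique)
  all_genes <- unique(unlist(named_sets))
  member <- vapply(named_sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1L)
  pattern <- apply(member, 1, function(m) paste(names(named_sets)[m], collapse = "&"))
  counts <- table(pattern)
  regions <- data.frame(region = names(counts), count = as.integer(counts),
                        stringsAsFactors = FALSE)
  list(regions = regions,
       totals = vapply(named_sets, length, 0L))
}
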