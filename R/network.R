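# Protein-protein interaction network substrate.
#
# The reference network is an undirected simple graph whose vertices are
# uppercased gene symbols. Gene identity is the symbol string itself: no alias
# resolution is attempted, matching the flat-file conventions of interaction
# databases such as HPRD. Disconnected components are kept; seeds that fall in
# small components simply produce small modules.

#' Build a PPI network from a two-column table of gene pairs
#'
#' Symbols are uppercased, self-loops dropped and duplicate (unordered) edges
#' collapsed. The load report is attached as the graph attribute
#' `load_report`.
#'
#' @param pairs two-column character matrix or data frame of interacting gene
#'   symbols.
#' @return an [igraph::igraph] object (undirected, simple) with a
#'   `load_report` graph attribute listing `n_input`, `n_self_loops`,
#'   `n_duplicates`.
#' @export
ppi_network <- function(pairs) {
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  mode(pairs) <- "character"
  pairs[] <- toupper(trimws(pairs))
  n_input <- nrow(pairs)
  symbols <- sort(unique(as.vector(pairs)))
  self <- pairs[, 1] == pairs[, 2]
  pairs <- pairs[!self, , drop = FALSE]
  key <- edge_key(pairs[, 1], pairs[, 2])
  dup <- duplicated(key)
  pairs <- pairs[!dup, , drop = FALSE]
  net <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  # nodes seen only in dropped rows stay in the graph as isolated vertices
  orphans <- setdiff(symbols, igraph::V(net)$name)
  if (length(orphans) > 0L) net <- igraph::add_vertices(net, length(orphans),
                                                        name = orphans)
  igraph::graph_attr(net, "load_report") <- list(
    n_input = n_input,
    n_self_loops = sum(self),
    n_duplicates = sum(dup)
  )
  net
}

#' Load a PPI network from disk
#'
#' Two dialects are supported: `edge_list`, a tab-delimited file whose first
#' two columns are interacting gene symbols (extra columns, as in HPRD flat
#' files, are ignored), and `sif`, where each row is
#' `source<TAB>relation<TAB>target1<TAB>target2...` and fans out to one edge
#' per target.
#'
#' @param path file path.
#' @param format `"edge_list"` or `"sif"`.
#' @param header logical; skip a header line (edge_list only).
#' @return an igraph network as from [ppi_network()].
#' @export
load_network <- function(path, format = c("edge_list", "sif"), header = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (header && length(lines) > 0L) lines <- lines[-1L]
  lines_keep <- nzchar(trimws(lines))
  fields <- strsplit(lines[lines_keep], "\t", fixed = TRUE)
  lineno <- which(lines_keep)
  if (length(fields) == 0L) stop("empty network file: ", path, call. = FALSE)
  if (format == "edge_list") {
    bad <- which(vapply(fields, length, 0L) < 2L)
    if (length(bad) > 0L) {
      stop(sprintf("malformed edge_list row at line %d of %s",
                   lineno[bad[1L]], path), call. = FALSE)
    }
    pairs <- t(vapply(fields, function(f) f[1:2], character(2)))
  } else {
    bad <- which(vapply(fields, length, 0L) < 3L)
    if (length(bad) > 0L) {
      stop(sprintf("malformed sif row at line %d of %s (need source, relation, >=1 target)",
                   lineno[bad[1L]], path), call. = FALSE)
    }
    pairs <- do.call(rbind, lapply(fields, function(f) {
      cbind(f[1L], f[3:length(f)])
    }))
  }
  ppi_network(pairs)
}

#' Write a network to disk
#'
#' @param net igraph network.
#' @param path output path.
#' @param format `"sif"`, `"edge_list"` or `"graphml"`.
#' @param relation interaction type written in SIF output.
#' @export
write_network <- function(net, path, format = c("sif", "edge_list", "graphml"),
                          relation = "pp") {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(net)
  if (format == "sif") {
    out <- data.frame(a = el[, 1], rel = relation, b = el[, 2])
  } else {
    out <- data.frame(a = el[, 1], b = el[, 2])
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Neighborhood of a gene set within a given distance
#'
#' Returns every node outside `genes` whose shortest-path distance to any
#' member of `genes` is at most `d`, measured on the full network.
#'
#' @param net igraph network.
#' @param genes character vector of member genes (must exist in `net`).
#' @param d positive integer distance.
#' @return sorted character vector of neighborhood genes.
#' @export
neighborhood <- function(net, genes, d = 1L) {
  stopifnot(d >= 1L)
  stop_if_missing_genes(genes, igraph::V(net)$name)
  hoods <- igraph::ego(net, order = d, nodes = genes)
  nb <- unique(unlist(lapply(hoods, function(v) v$name)))
  sort(setdiff(nb, genes))
}

#' Induced subgraph on the union of module gene sets
#'
#' @param net igraph network.
#' @param modules non-empty list of character vectors of genes.
#' @return igraph subgraph induced on the union of the module gene sets.
#' @export
merge_modules <- function(net, modules) {
  if (length(modules) == 0L) stop("no modules to merge", call. = FALSE)
  genes <- unique(unlist(modules))
  stop_if_missing_genes(genes, igraph::V(net)$name)
  igraph::induced_subgraph(net, genes)
}

#' Per-gene node attribute table for a subnetwork
#'
#' @param net igraph (sub)network.
#' @param scores gene score table (see [gene_score_table()]); optional.
#' @param membership optional named integer vector, genes to module counts.
#' @return data frame with gene, degree and, when available, p, z and module
#'   membership counts.
#' @export
node_attributes <- function(net, scores = NULL, membership = NULL) {
  genes <- igraph::V(net)$name
  out <- data.frame(gene = genes, degree = igraph::degree(net),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(scores)) {
    idx <- match(genes, scores$gene)
    out$p <- scores$p[idx]
    out$z <- scores$z[idx]
  }
  if (!is.null(membership)) {
    out$n_modules <- ifelse(is.na(match(genes, names(membership))), 0L,
                            as.integer(membership[genes]))
  }
  out
}
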