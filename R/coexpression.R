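# Case/control expression handling and differential co-expression.
#
# Expression values are log2-scale, already normalized upstream. The edge
# weight of an interaction measures how much the co-expression of its two
# genes changes between cases and controls: within-condition Pearson
# correlations are compared with the Fisher z-transform difference test, the
# standard two-correlation comparison. Weights fed to the module search are
# non-negative (|z|, standardized, floored at zero) so that a change in
# either direction is rewarded.

#' Construct an expression set
#'
#' @param values numeric gene x sample matrix (log2 scale) with row and
#'   column names.
#' @param condition character vector of `"case"`/`"control"` labels, one per
#'   sample (column), in column order or named by sample id.
#' @param check_scale warn when per-sample medians differ by more than
#'   `scale_band` (values should be comparably normalized).
#' @param scale_band allowed spread of per-sample medians (default 2 log2
#'   units).
#' @return object of class `expression_set`: list with `values` and
#'   `condition`.
#' @export
expression_set <- function(values, condition, check_scale = TRUE,
                           scale_band = 2) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  }
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene symbols; collapse probes first", call. = FALSE)
  }
  if (!is.null(names(condition))) {
    condition <- condition[colnames(values)]
  }
  condition <- as.character(condition)
  if (length(condition) != ncol(values) || any(is.na(condition))) {
    stop("every sample needs a condition label", call. = FALSE)
  }
  if (!all(condition %in% c("case", "control"))) {
    stop("condition labels must be 'case' or 'control'", call. = FALSE)
  }
  if (check_scale) {
    med <- apply(values, 2, median)
    if (diff(range(med)) > scale_band) {
      warning("per-sample medians differ by more than ", scale_band,
              " log2 units; values may not be comparably normalized",
              call. = FALSE)
    }
  }
  structure(list(values = values, condition = condition),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$condition == "case"), sum(x$condition == "control")))
  invisible(x)
}

#' Collapse probe-level values to gene level
#'
#' Genes measured by several probe sets get the arithmetic mean of those
#' probes, per sample. Probes absent from the map are dropped (count
#' reported in the `n_unmapped` attribute).
#'
#' @param probe_values probe x sample numeric matrix with probe rownames.
#' @param probe_map named character vector, probe id to gene symbol.
#' @param condition per-sample condition labels (see [expression_set()]).
#' @return `expression_set` at gene level.
#' @export
collapse_probes <- function(probe_values, probe_map, condition) {
  probe_values <- as.matrix(probe_values)
  mapped <- rownames(probe_values) %in% names(probe_map)
  n_unmapped <- sum(!mapped)
  if (!any(mapped)) stop("no probe maps to a gene", call. = FALSE)
  if (n_unmapped > 0L) {
    message(n_unmapped, " unmapped probe(s) dropped")
  }
  v <- probe_values[mapped, , drop = FALSE]
  gene <- toupper(unname(probe_map[rownames(v)]))
  sums <- rowsum(v, group = gene)
  counts <- as.vector(table(gene)[rownames(sums)])
  out <- expression_set(sums / counts, condition, check_scale = FALSE)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Differential expression between cases and controls
#'
#' `log2FC = mean(case) - mean(control)` on the log2-scale matrix; p-values
#' from Welch's two-sided two-sample t-test, reported nominally (no multiple
#' testing correction).
#'
#' @param es `expression_set` with at least two samples per condition.
#' @return data frame (gene, log2fc, p, nominal = p < 0.05,
#'   twofold = |log2FC| > 1).
#' @export
differential_expression <- function(es) {
  stopifnot(inherits(es, "expression_set"))
  case <- es$values[, es$condition == "case", drop = FALSE]
  ctrl <- es$values[, es$condition == "control", drop = FALSE]
  if (ncol(case) < 2L || ncol(ctrl) < 2L) {
    stop("need >= 2 samples per condition", call. = FALSE)
  }
  log2fc <- rowMeans(case) - rowMeans(ctrl)
  p <- vapply(seq_len(nrow(case)), function(i) {
    t.test(case[i, ], ctrl[i, ])$p.value
  }, 0)
  data.frame(gene = rownames(es$values), log2fc = unname(log2fc), p = p,
             nominal = p < 0.05, twofold = abs(log2fc) > 1,
             stringsAsFactors = FALSE)
}

# Fisher z-transform difference statistic between two correlations
fisher_z_diff <- function(r_case, r_control, n_case, n_control) {
  if (n_case - 3 <= 0 || n_control - 3 <= 0) {
    stop("need more than 3 samples per condition for the Fisher z test",
         call. = FALSE)
  }
  cl <- function(r) pmin(pmax(r, -0.999999), 0.999999)
  (atanh(cl(r_case)) - atanh(cl(r_control))) /
    sqrt(1 / (n_case - 3) + 1 / (n_control - 3))
}

#' Differential co-expression edge weights
#'
#' For every network edge with both endpoint genes measured, the Pearson
#' correlation is computed within cases and within controls, compared by the
#' Fisher z-transform difference statistic, and |z| is standardized across
#' edges (mean 0, sd 1) then shifted so the minimum weight is zero.
#'
#' @param es `expression_set` with >= 4 samples per condition.
#' @param net igraph PPI network.
#' @return data frame of class `edge_weight_table` (gene_a, gene_b, r_case,
#'   r_control, z_raw, w). Edges with a zero-variance endpoint in either
#'   condition are dropped with a warning; edges with an unmeasured endpoint
#'   are skipped (count in attribute `n_unmeasured`).
#' @export
edge_weight <- function(es, net) {
  stopifnot(inherits(es, "expression_set"))
  n_case <- sum(es$condition == "case")
  n_ctrl <- sum(es$condition == "control")
  if (n_case < 4L || n_ctrl < 4L) {
    stop("need >= 4 samples per condition for edge weighting", call. = FALSE)
  }
  el <- igraph::as_edgelist(net)
  measured <- el[, 1] %in% rownames(es$values) & el[, 2] %in% rownames(es$values)
  n_unmeasured <- sum(!measured)
  el <- el[measured, , drop = FALSE]
  if (nrow(el) == 0L) stop("no network edge has both genes measured", call. = FALSE)
  case <- es$values[, es$condition == "case", drop = FALSE]
  ctrl <- es$values[, es$condition == "control", drop = FALSE]
  sd_case <- apply(case, 1, sd)
  sd_ctrl <- apply(ctrl, 1, sd)
  degenerate <- sd_case[el[, 1]] == 0 | sd_case[el[, 2]] == 0 |
    sd_ctrl[el[, 1]] == 0 | sd_ctrl[el[, 2]] == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " edge(s) dropped: zero-variance gene within a condition",
            call. = FALSE)
    el <- el[!degenerate, , drop = FALSE]
  }
  if (nrow(el) == 0L) stop("all edges degenerate", call. = FALSE)
  r_case <- vapply(seq_len(nrow(el)), function(i) {
    cor(case[el[i, 1], ], case[el[i, 2], ])
  }, 0)
  r_ctrl <- vapply(seq_len(nrow(el)), function(i) {
    cor(ctrl[el[i, 1], ], ctrl[el[i, 2], ])
  }, 0)
  z_raw <- fisher_z_diff(r_case, r_ctrl, n_case, n_ctrl)
  a <- abs(z_raw)
  w <- if (length(a) > 1L && sd(a) > 0) (a - mean(a)) / sd(a) else a - mean(a)
  w <- w - min(w)
  out <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                    r_case = r_case, r_control = r_ctrl,
                    z_raw = z_raw, w = w, stringsAsFactors = FALSE)
  attr(out, "n_unmeasured") <- n_unmeasured
  class(out) <- c("edge_weight_table", "data.frame")
  out
}

#' Read / write expression and edge-weight tables
#'
#' Expression input is tab-delimited with the probe/gene id in the first
#' column and sample ids in the header; conditions come from a two-column
#' (sample, condition) file.
#'
#' @param path expression TSV path.
#' @param condition_path sample-condition TSV path.
#' @return `expression_set`.
#' @export
read_expression <- function(path, condition_path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1L]]
  cond <- read.delim(condition_path, stringsAsFactors = FALSE)
  labels <- cond[[2L]]
  names(labels) <- cond[[1L]]
  expression_set(mat, labels)
}

#' @rdname read_expression
#' @param ew edge weight table.
#' @export
write_edge_weights <- function(ew, path) {
  write.table(ew, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
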