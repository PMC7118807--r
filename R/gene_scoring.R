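# Gene-based association scores.
#
# SNP-level association p-values are mapped to genes using the gene body plus
# a symmetric flank (50 kb by default) and combined into one gene-level
# p-value, which is transformed to a z-score by the inverse normal
# distribution function, z = qnorm(1 - p). Genes with extreme p-values can
# overwhelm a node-weighted module search, so a capping step floors them to
# the smallest p-value among the remaining genes.
#
# The combiners shipped here (Sidak-corrected minimum and Fisher's method)
# are simple stand-ins that ignore linkage disequilibrium; when gene-level
# p-values from an LD-aware tool are available they can be supplied directly
# via gene_score_table().

#' Read SNP associations from a tab-delimited file
#'
#' Expects a header with columns `snp`, `chrom`, `pos`, `p` (extra columns are
#' ignored; alternative column names can be mapped via `columns`).
#'
#' @param path file path.
#' @param columns named character vector mapping standard names to file
#'   column names, e.g. `c(snp = "SNP", p = "P")`.
#' @return data frame with columns snp, chrom, pos, p.
#' @export
read_snp_associations <- function(path, columns = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  std <- c(snp = "snp", chrom = "chrom", pos = "pos", p = "p")
  if (!is.null(columns)) std[names(columns)] <- columns
  missing <- std[!std %in% names(df)]
  if (length(missing) > 0L) {
    stop("missing SNP association column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(snp = as.character(df[[std["snp"]]]),
                    chrom = as.character(df[[std["chrom"]]]),
                    pos = as.integer(df[[std["pos"]]]),
                    p = as.numeric(df[[std["p"]]]),
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$p)) || any(out$p <= 0 | out$p > 1)) {
    stop("SNP p-values must lie in (0, 1]", call. = FALSE)
  }
  if (any(out$pos < 1L)) stop("SNP positions must be >= 1", call. = FALSE)
  out
}

#' Read gene annotations
#'
#' Tab-delimited with header columns `gene`, `chrom`, `start`, `end` and
#' optionally `strand`. Coordinates are 1-based inclusive; set
#' `zero_based = TRUE` for 0-based half-open (BED) input, which is converted.
#'
#' @param path file path.
#' @param zero_based logical; input uses BED coordinate conventions.
#' @return data frame with gene, chrom, start, end, strand.
#' @export
read_gene_annotations <- function(path, zero_based = FALSE) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "start", "end")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("missing annotation column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(gene = toupper(as.character(df$gene)),
                    chrom = as.character(df$chrom),
                    start = as.integer(df$start),
                    end = as.integer(df$end),
                    strand = if ("strand" %in% names(df)) as.character(df$strand)
                             else "unknown",
                    stringsAsFactors = FALSE)
  if (zero_based) out$start <- out$start + 1L
  if (any(out$start > out$end)) stop("annotation start > end", call. = FALSE)
  out
}

#' Map SNPs to genes by position
#'
#' A SNP maps to a gene when the chromosome matches and its position falls in
#' the gene body extended by `flank` base pairs on both sides (boundaries
#' inclusive). The flank is symmetric in genomic coordinates regardless of
#' strand. A SNP may map to several genes; genes with no mapped SNP are
#' absent from the result.
#'
#' @param snps data frame as from [read_snp_associations()].
#' @param annot data frame as from [read_gene_annotations()].
#' @param flank flank size in bp (default 50000).
#' @return named list, gene to numeric vector of SNP p-values (named by SNP
#'   id).
#' @export
map_snps_to_genes <- function(snps, annot, flank = 50000L) {
  stopifnot(flank >= 0L)
  out <- list()
  if (nrow(snps) == 0L || nrow(annot) == 0L) return(out)
  by_chrom <- split(snps, snps$chrom)
  for (i in seq_len(nrow(annot))) {
    s <- by_chrom[[annot$chrom[i]]]
    if (is.null(s)) next
    hit <- s$pos >= annot$start[i] - flank & s$pos <= annot$end[i] + flank
    if (any(hit)) {
      p <- s$p[hit]
      names(p) <- s$snp[hit]
      gene <- annot$gene[i]
      out[[gene]] <- c(out[[gene]], p)
    }
  }
  out
}

#' Combine mapped SNP p-values into gene-level p-values
#'
#' `sidak_min` uses the Sidak-corrected minimum, `p = 1 - (1 - min p)^m`;
#' `fisher` uses Fisher's method, `X = -2 sum(log p)` on chi-squared with
#' `2m` degrees of freedom. Results are clipped to `[1e-300, 1 - 1e-16]`.
#' Both ignore LD between SNPs.
#'
#' @param mapping named list from [map_snps_to_genes()].
#' @param method `"sidak_min"` or `"fisher"`.
#' @return data frame with gene, p, n_snps.
#' @export
combine_snp_pvalues <- function(mapping, method = c("sidak_min", "fisher")) {
  method <- match.arg(method)
  if (length(mapping) == 0L) {
    return(data.frame(gene = character(), p = numeric(), n_snps = integer(),
                      stringsAsFactors = FALSE))
  }
  if (any(vapply(mapping, length, 0L) == 0L)) {
    stop("empty SNP list for a mapped gene", call. = FALSE)
  }
  p <- vapply(mapping, function(ps) {
    m <- length(ps)
    if (method == "sidak_min") {
      1 - (1 - min(ps))^m
    } else {
      pchisq(-2 * sum(log(ps)), df = 2 * m, lower.tail = FALSE)
    }
  }, 0)
  data.frame(gene = names(mapping), p = clip_p(unname(p)),
             n_snps = unname(vapply(mapping, length, 0L)),
             stringsAsFactors = FALSE)
}

#' Inverse normal transform of a p-value
#'
#' `z = qnorm(1 - p)`, the gene-level node weight. Strictly decreasing in p.
#'
#' @param p p-value(s) in (0, 1).
#' @return z-score(s).
#' @export
pvalue_to_z <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0 | p >= 1)) {
    stop("p must lie strictly inside (0, 1)", call. = FALSE)
  }
  qnorm(p, lower.tail = FALSE)
}

#' Assemble a gene score table
#'
#' @param gene character vector of gene symbols.
#' @param p gene-level p-values.
#' @param n_snps number of SNPs mapped per gene (0 when scores are supplied
#'   pre-computed at gene level).
#' @return data frame (gene, p, z, n_snps, capped) with `z = qnorm(1 - p)`
#'   computed on p clipped away from 0 and 1.
#' @export
gene_score_table <- function(gene, p, n_snps = 0L) {
  gene <- toupper(as.character(gene))
  if (anyDuplicated(gene)) stop("duplicate gene symbols in score table", call. = FALSE)
  p <- clip_p(as.numeric(p))
  data.frame(gene = gene, p = p, z = pvalue_to_z(p),
             n_snps = as.integer(rep_len(n_snps, length(gene))),
             capped = FALSE, stringsAsFactors = FALSE)
}

#' Read / write gene score tables
#'
#' Tab-delimited with header (gene, p, z, n_snps, capped); `z` and `capped`
#' are recomputed/validated on read.
#'
#' @param path file path.
#' @return data frame in [gene_score_table()] layout.
#' @export
read_gene_scores <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "p") %in% names(df))) {
    stop("gene score file needs columns gene, p", call. = FALSE)
  }
  out <- gene_score_table(df$gene, df$p,
                          if ("n_snps" %in% names(df)) df$n_snps else 0L)
  if ("capped" %in% names(df)) out$capped <- as.logical(df$capped)
  out
}

#' @rdname read_gene_scores
#' @param scores gene score table.
#' @export
write_gene_scores <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene-level Bonferroni threshold
#'
#' `0.05 / n_genes`, the genome-wide significance bound when the number of
#' genes (rather than SNPs) is the multiple-testing burden.
#'
#' @param n_genes number of scored genes.
#' @param alpha family-wise error rate (default 0.05).
#' @return the per-gene significance threshold.
#' @export
bonferroni_threshold <- function(n_genes, alpha = 0.05) {
  stopifnot(n_genes >= 1)
  alpha / n_genes
}

#' Cap extreme gene-level signals
#'
#' Genes whose p-value falls below `threshold` would dominate a node-weighted
#' module search. Under `floor_to_min_remaining` their p is raised to the
#' smallest p-value among genes at or above the threshold and the rows are
#' flagged `capped`; under `drop` they are removed. z is recomputed for
#' modified rows.
#'
#' @param table gene score table.
#' @param strategy `"floor_to_min_remaining"` or `"drop"`.
#' @param threshold p-value threshold; defaults to the gene-level Bonferroni
#'   bound `0.05 / nrow(table)`.
#' @return modified gene score table.
#' @export
cap_extreme_genes <- function(table,
                              strategy = c("floor_to_min_remaining", "drop"),
                              threshold = bonferroni_threshold(nrow(table))) {
  strategy <- match.arg(strategy)
  stopifnot(threshold > 0, threshold < 1)
  below <- table$p < threshold
  if (!any(below)) return(table)
  if (strategy == "drop") return(table[!below, , drop = FALSE])
  if (all(below)) {
    stop("all genes fall below the capping threshold; floor undefined",
         call. = FALSE)
  }
  floor_p <- min(table$p[!below])
  table$p[below] <- floor_p
  table$z[below] <- pvalue_to_z(floor_p)
  table$capped[below] <- TRUE
  table
}
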