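# shared fixture builders (all fixtures are generated in code)

# gene score table with prescribed z-scores
scores_from_z <- function(genes, z) {
  gene_score_table(genes, pnorm(z, lower.tail = FALSE))
}

# path graph A-B-C-...
path_net <- function(genes) {
  ppi_network(cbind(genes[-length(genes)], genes[-1L]))
}

# expression set with prescribed case/control values per gene
expr_fixture <- function(case, control) {
  stopifnot(identical(rownames(case), rownames(control)))
  values <- cbind(case, control)
  colnames(values) <- c(paste0("CA", seq_len(ncol(case))),
                        paste0("CO", seq_len(ncol(control))))
  expression_set(values,
                 c(rep("case", ncol(case)), rep("control", ncol(control))),
                 check_scale = FALSE)
}

module_sizes <- function(ms) vapply(ms$modules, function(m) length(m$genes), 0L)

module_gene_sets <- function(ms) lapply(ms$modules, `[[`, "genes")
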