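# Discovery/evaluation module selection.
#
# Modules are generated on a discovery GWAS dataset and re-scored with a
# second, evaluation dataset. Modules significant in both are treated as
# carrying consistent association signals. The design is one-directional
# (discovery -> evaluation); swap the inputs to run the other direction.

#' Re-score discovery modules with an evaluation dataset
#'
#' For each discovery module the raw score is recomputed with the evaluation
#' z-scores of the same genes; the evaluation normalized score uses the mean
#' and population sd of the evaluation scores over the discovery modules (no
#' fresh evaluation-side search is run).
#'
#' @param ms normalized discovery `module_set`.
#' @param eval_scores gene score table for the evaluation dataset.
#' @param strict if `TRUE` (default) a module gene absent from `eval_scores`
#'   is an error listing the genes; otherwise such modules are dropped with a
#'   warning.
#' @return object of class `dual_modules`: list with `modules` and a `table`
#'   data frame (seed, size, z_m_disc, z_n_disc, z_m_eval, z_n_eval).
#' @export
evaluate_modules <- function(ms, eval_scores, strict = TRUE) {
  if (is.null(ms$modules[[1L]]$z_n)) ms <- normalize_scores(ms)
  ze <- eval_scores$z
  names(ze) <- eval_scores$gene
  missing <- lapply(ms$modules, function(m) setdiff(m$genes, names(ze)))
  any_missing <- vapply(missing, length, 0L) > 0L
  if (any(any_missing)) {
    if (strict) {
      stop("module gene(s) absent from evaluation scores: ",
           paste(unique(unlist(missing)), collapse = ", "), call. = FALSE)
    }
    warning(sum(any_missing),
            " module(s) dropped: genes missing from evaluation scores",
            call. = FALSE)
    ms$modules <- ms$modules[!any_missing]
  }
  if (length(ms$modules) == 0L) stop("no evaluable modules", call. = FALSE)
  zme <- vapply(ms$modules, function(m) module_score(ze[m$genes]), 0)
  s <- pop_sd(zme)
  if (s == 0) stop("zero variance in evaluation module scores", call. = FALSE)
  zne <- (zme - mean(zme)) / s
  tab <- data.frame(
    seed = vapply(ms$modules, `[[`, "", "seed"),
    size = vapply(ms$modules, function(m) length(m$genes), 0L),
    z_m_disc = vapply(ms$modules, `[[`, 0, "z_m"),
    z_n_disc = vapply(ms$modules, `[[`, 0, "z_n"),
    z_m_eval = zme,
    z_n_eval = zne,
    stringsAsFactors = FALSE
  )
  structure(list(modules = ms$modules, table = tab), class = "dual_modules")
}

#' Select modules with consistent signals in both datasets
#'
#' Keeps modules whose discovery normalized score is at or above the
#' `disc_quantile` quantile of the discovery `Z_n` distribution and whose
#' evaluation normalized score is at least `eval_threshold`. Both cuts are
#' configurable; the defaults (top 1 percent, one-sided normal 0.05) are the
#' package's choices, not a published rule.
#'
#' @param dual `dual_modules` from [evaluate_modules()].
#' @param disc_quantile discovery-side quantile cut (default 0.99).
#' @param eval_threshold evaluation-side `Z_n` threshold (default 1.64).
#' @param disc_scores,eval_scores optional gene score tables used to fill the
#'   per-gene report.
#' @return list with `table` (selected rows), `modules`, `genes` (union gene
#'   report with p from both datasets and module counts) and
#'   `frac_nominal_disc`. An empty selection is returned with a warning, not
#'   an error.
#' @export
select_consistent <- function(dual, disc_quantile = 0.99, eval_threshold = 1.64,
                              disc_scores = NULL, eval_scores = NULL) {
  stopifnot(inherits(dual, "dual_modules"), nrow(dual$table) > 0L)
  cut_disc <- quantile(dual$table$z_n_disc, disc_quantile, names = FALSE)
  keep <- dual$table$z_n_disc >= cut_disc & dual$table$z_n_eval >= eval_threshold
  if (!any(keep)) warning("no module passes both thresholds", call. = FALSE)
  modules <- dual$modules[keep]
  gene_sets <- lapply(modules, `[[`, "genes")
  genes <- sort(unique(unlist(gene_sets)))
  counts <- table(unlist(lapply(gene_sets, unique)))
  rep <- data.frame(gene = genes,
                    n_modules = as.integer(counts[genes]),
                    stringsAsFactors = FALSE)
  if (length(genes) == 0L) rep$n_modules <- integer(0)
  if (!is.null(disc_scores)) rep$p_disc <- disc_scores$p[match(genes, disc_scores$gene)]
  if (!is.null(eval_scores)) rep$p_eval <- eval_scores$p[match(genes, eval_scores$gene)]
  frac <- if (!is.null(disc_scores) && length(genes) > 0L) {
    mean(rep$p_disc < 0.05, na.rm = TRUE)
  } else NA_real_
  list(table = dual$table[keep, , drop = FALSE], modules = modules,
       genes = rep, frac_nominal_disc = frac,
       params = list(disc_quantile = disc_quantile,
                     eval_threshold = eval_threshold))
}

#' Correlation between discovery and evaluation module scores
#'
#' Pearson correlation of raw module scores across modules; a positive
#' correlation supports running the discovery/evaluation design in that
#' direction.
#'
#' @param dual `dual_modules`.
#' @return Pearson correlation coefficient.
#' @export
score_correlation <- function(dual) {
  stopifnot(inherits(dual, "dual_modules"))
  if (nrow(dual$table) < 3L) stop("need >= 3 modules", call. = FALSE)
  if (var(dual$table$z_m_disc) == 0 || var(dual$table$z_m_eval) == 0) {
    stop("zero variance in module scores", call. = FALSE)
  }
  cor(dual$table$z_m_disc, dual$table$z_m_eval)
}
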