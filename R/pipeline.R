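# Pipeline orchestration.
#
# Stages (score, dms, dual, ew, enrich) run in dependency order from a flat
# config of input paths and parameters. Inputs required by the selected
# stages are validated before any computation starts; every run writes a
# manifest listing output files with input checksums, the effective
# parameters and the package version, so identical inputs and seeds yield
# identical outputs.

#' Build a pipeline run configuration
#'
#' All parameters carry defaults; paths default to `NULL` and are validated
#' against the selected stages at run time. The effective config is
#' serialized alongside the outputs.
#'
#' @param network,scores_disc,scores_eval,snps_disc,snps_eval,annotations,expression,conditions,gmt input paths.
#' @param out_dir output directory.
#' @param d,r,top_k node-weighted search parameters.
#' @param combine SNP p-value combiner for the score stage.
#' @param flank SNP-to-gene mapping flank in bp.
#' @param cap_strategy extreme-gene handling (see [cap_extreme_genes()]).
#' @param disc_quantile,eval_threshold dual-evaluation cuts.
#' @param lam,max_size,n_perm edge-weighted search parameters.
#' @param min_set,max_set,alpha enrichment parameters.
#' @param seed master seed; stage seeds are derived with [derive_seed()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(network = NULL, scores_disc = NULL,
                            scores_eval = NULL, snps_disc = NULL,
                            snps_eval = NULL, annotations = NULL,
                            expression = NULL, conditions = NULL, gmt = NULL,
                            out_dir = "dmsearch_out", d = 2L, r = 0.1,
                            top_k = 50L, combine = "sidak_min",
                            flank = 50000L, cap_strategy = "floor_to_min_remaining",
                            disc_quantile = 0.99, eval_threshold = 1.64,
                            lam = 0.5, max_size = 10L, n_perm = 1000L,
                            min_set = 10L, max_set = 500L, alpha = 0.05,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a flat key = value config file
#'
#' Lines of the form `key = value` (or `key<TAB>value`); `#` comments and
#' blank lines are ignored. Values are coerced to numeric where possible.
#' Keys must match [pipeline_config()] arguments.
#'
#' @param path config file path.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*|\t")
  bad <- which(vapply(kv, length, 0L) != 2L)
  if (length(bad) > 0L) stop("malformed config line: ", lines[bad[1L]], call. = FALSE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- lapply(kv, function(x) {
    v <- x[[2L]]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- keys
  unknown <- setdiff(keys, names(formals(pipeline_config)))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

stage_requirements <- function(cfg, stages) {
  scoring <- "score" %in% stages
  list(
    score = c("snps_disc", "annotations"),
    dms = c("network", if (!scoring) "scores_disc"),
    dual = c("network",
             if (!(scoring && !is.null(cfg$snps_eval))) "scores_eval"),
    ew = c("network", "expression", "conditions",
           if (!scoring) "scores_disc"),
    enrich = "gmt"
  )
}

#' Run the analysis pipeline
#'
#' @param cfg `pipeline_config`.
#' @param stages subset of `c("score", "dms", "dual", "ew", "enrich")`;
#'   dependencies among the selected stages are enforced by running them in
#'   that order. `dual` requires `dms`; `enrich` uses the consistent gene
#'   set when `dual` ran, otherwise the top-k subnetwork genes.
#' @return invisible manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(cfg, stages = c("score", "dms", "dual", "ew", "enrich")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  all_stages <- c("score", "dms", "dual", "ew", "enrich")
  stages <- all_stages[all_stages %in% match.arg(stages, all_stages,
                                                 several.ok = TRUE)]
  if ("dual" %in% stages && !"dms" %in% stages) {
    stop("stage 'dual' requires stage 'dms'", call. = FALSE)
  }
  # validate every required input up front, before any computation
  req <- stage_requirements(cfg, stages)
  inputs <- character(0)
  for (st in stages) {
    for (key in req[[st]]) {
      path <- cfg[[key]]
      if (is.null(path) || !file.exists(path)) {
        stop(sprintf("stage '%s' needs input '%s'%s", st, key,
                     if (is.null(path)) " (not set)" else paste0(": ", path)),
             call. = FALSE)
      }
      inputs[key] <- path
    }
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    outputs[name] <<- path
  }

  scores_disc <- scores_eval <- net <- topk <- sel <- NULL
  if ("score" %in% stages) {
    annot <- read_gene_annotations(cfg$annotations)
    score_one <- function(snp_path) {
      snps <- read_snp_associations(snp_path)
      tab <- combine_snp_pvalues(map_snps_to_genes(snps, annot, cfg$flank),
                                 cfg$combine)
      cap_extreme_genes(gene_score_table(tab$gene, tab$p, tab$n_snps),
                        cfg$cap_strategy)
    }
    scores_disc <- score_one(cfg$snps_disc)
    emit("gene_scores_discovery.tsv",
         function(p) write_gene_scores(scores_disc, p))
    if (!is.null(cfg$snps_eval)) {
      scores_eval <- score_one(cfg$snps_eval)
      emit("gene_scores_evaluation.tsv",
           function(p) write_gene_scores(scores_eval, p))
    }
  }
  needs_net <- any(c("dms", "dual", "ew") %in% stages)
  if (needs_net) net <- load_network(cfg$network, "edge_list")
  if (any(c("dms", "dual") %in% stages) && is.null(scores_disc)) {
    scores_disc <- read_gene_scores(cfg$scores_disc)
  }
  if ("dms" %in% stages) {
    ms <- normalize_scores(
      dense_module_search(net, scores_disc, d = cfg$d, r = cfg$r))
    topk <- top_k_subnetwork(ms, net, scores_disc, k = cfg$top_k)
    emit("modules.tsv", function(p) write_modules(ms, p))
    emit("subnetwork.sif", function(p) write_network(topk$subnetwork, p, "sif"))
    emit("subnetwork.graphml",
         function(p) write_network(topk$subnetwork, p, "graphml"))
    emit("subnetwork_genes.tsv", function(p)
      write.table(topk$genes, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }
  if ("dual" %in% stages) {
    if (is.null(scores_eval)) scores_eval <- read_gene_scores(cfg$scores_eval)
    dual <- evaluate_modules(ms, scores_eval, strict = FALSE)
    sel <- select_consistent(dual, cfg$disc_quantile, cfg$eval_threshold,
                             disc_scores = scores_disc,
                             eval_scores = scores_eval)
    emit("dual_modules.tsv", function(p)
      write.table(dual$table, p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("consistent_genes.tsv", function(p)
      write.table(sel$genes, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }
  if ("ew" %in% stages) {
    if (is.null(scores_disc)) scores_disc <- read_gene_scores(cfg$scores_disc)
    es <- read_expression(cfg$expression, cfg$conditions)
    ew <- edge_weight(es, net)
    emit("edge_weights.tsv", function(p) write_edge_weights(ew, p))
    emit("differential_expression.tsv", function(p)
      write.table(differential_expression(es), p, sep = "\t", quote = FALSE,
                  row.names = FALSE))
    ewms <- ew_dense_module_search(net, scores_disc, ew, lam = cfg$lam,
                                   d = cfg$d, r = cfg$r,
                                   max_size = cfg$max_size)
    ewms <- permutation_significance(ewms, net, scores_disc, ew,
                                     n_perm = cfg$n_perm,
                                     seed = derive_seed(cfg$seed, "perm"))
    emit("ew_modules.tsv", function(p) write_modules(ewms, p))
  }
  if ("enrich" %in% stages) {
    coll <- read_gmt(cfg$gmt)
    query <- if (!is.null(sel) && nrow(sel$genes) > 0L) {
      sel$genes$gene
    } else if (!is.null(topk)) {
      topk$genes$gene
    } else {
      stop("stage 'enrich' needs a gene set from 'dual' or 'dms'", call. = FALSE)
    }
    universe <- if (!is.null(scores_disc)) {
      intersect(scores_disc$gene, coll$universe)
    } else coll$universe
    rows <- enrich(query, coll, cfg$min_set, cfg$max_set, cfg$alpha,
                   universe = universe)
    rows <- reduce_redundancy(rows, coll, universe = universe)
    emit("enrichment.tsv", function(p)
      write.table(rows, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  params <- cfg[setdiff(names(cfg), "out_dir")]
  params <- params[!vapply(params, is.null, TRUE)]
  manifest <- list(
    package = "dmsearch",
    version = as.character(utils::packageVersion("dmsearch")),
    stages = stages,
    parameters = params,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
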