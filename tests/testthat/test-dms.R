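test_that("module_score is sum(z)/sqrt(k)", {
  expect_equal(module_score(2), 2)
  expect_equal(module_score(c(1, 1)), sqrt(2))
  expect_equal(module_score(c(3, 4, 5)), 12 / sqrt(3))
  expect_error(module_score(numeric(0)), "empty")
})

test_that("greedy expansion reproduces the hand-traced path-graph run", {
  net <- path_net(c("A", "B", "C"))
  sc <- scores_from_z(c("A", "B", "C"), c(2, 0.5, 3))
  ms <- dense_module_search(net, sc, d = 1, r = 0.1)
  mods <- setNames(module_gene_sets(ms), vapply(ms$modules, `[[`, "", "seed"))
  # seed A stays alone: (2 + 0.5)/sqrt(2) = 1.7678 <= 2 * 1.1
  expect_identical(mods$A, "A")
  expect_identical(mods$C, "C")
  # seed B recruits C then A: z_m = 5.5/sqrt(3)
  expect_identical(mods$B, c("B", "C", "A"))
  zB <- ms$modules[[which(names(mods) == "B")]]$z_m
  expect_equal(zB, 5.5 / sqrt(3), tolerance = 1e-12)
})

test_that("isolated seeds and huge r leave modules at their seed", {
  net <- ppi_network(rbind(c("A", "B"), c("C", "D")))
  sc <- scores_from_z(c("A", "B", "C", "D"), c(1, 1, 1, 1))
  ms <- dense_module_search(net, sc, d = 2, r = 10)
  expect_true(all(module_sizes(ms) == 1L))
  lone <- dense_module_search(net, sc, d = 1, r = 0.1, seeds = "A")
  expect_identical(lone$modules[[1]]$genes, c("A", "B"))
})

test_that("unscored seed genes are rejected by name", {
  net <- path_net(c("A", "B", "C"))
  sc <- scores_from_z(c("A", "B"), c(1, 1))
  expect_error(dense_module_search(net, sc, seeds = "C"), "C")
})

test_that("normalization centers and scales with the population sd", {
  ms <- structure(list(modules = list(
    list(seed = "A", genes = "A", z_m = 1),
    list(seed = "B", genes = "B", z_m = 2),
    list(seed = "C", genes = "C", z_m = 3)),
    params = list(d = 2, r = 0.1)), class = "module_set")
  nm <- normalize_scores(ms)
  zn <- vapply(nm$modules, `[[`, 0, "z_n")
  expect_equal(zn, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  expect_equal(mean(zn), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(zn^2)), 1, tolerance = 1e-9)
  pair <- ms
  pair$modules <- pair$modules[1:2]
  pair$modules[[1]]$z_m <- 0
  pair$modules[[2]]$z_m <- 2
  expect_equal(vapply(normalize_scores(pair)$modules, `[[`, 0, "z_n"),
               c(-1, 1))
  ms$modules <- lapply(ms$modules, function(m) { m$z_m <- 1; m })
  expect_error(normalize_scores(ms), "zero variance")
  expect_error(normalize_scores(structure(list(modules = ms$modules[1]),
                                          class = "module_set")), ">= 2")
})

test_that("top-k subnetwork merges the best modules and reports genes", {
  net <- ppi_network(rbind(c("A", "B"), c("B", "C"), c("D", "E")))
  sc <- scores_from_z(c("A", "B", "C", "D", "E"), c(3, 2.5, 0.2, 2, 1.9))
  ms <- normalize_scores(dense_module_search(net, sc, d = 1, r = 0.1))
  top1 <- top_k_subnetwork(ms, net, sc, k = 1)
  best <- ms$modules[[which.max(vapply(ms$modules, `[[`, 0, "z_n"))]]
  expect_setequal(igraph::V(top1$subnetwork)$name, best$genes)
  expect_warning(all_mod <- top_k_subnetwork(ms, net, sc, k = 99), "all modules")
  expect_true(all(all_mod$genes$nominal == (all_mod$genes$p < 0.05)))
  expect_equal(all_mod$frac_nominal, mean(all_mod$genes$p < 0.05))
  # membership counts: a gene in several top modules is counted once each
  expect_true(all(all_mod$genes$n_modules >= 1L))
})

test_that("search is deterministic", {
  inst <- random_instance(30, 42)
  a <- dense_module_search(inst$net, inst$scores)
  b <- dense_module_search(inst$net, inst$scores)
  expect_identical(module_gene_sets(a), module_gene_sets(b))
})

test_that("modules contain their seed and induce connected subgraphs", {
  for (seed in c(3, 9, 27)) {
    inst <- random_instance(25, seed)
    ms <- dense_module_search(inst$net, inst$scores)
    for (m in ms$modules) {
      expect_true(m$seed %in% m$genes)
      expect_true(igraph::is_connected(
        igraph::induced_subgraph(inst$net, m$genes)))
      # z_m is recomputable from member z-scores
      expect_equal(m$z_m, module_score(inst$z[m$genes]), tolerance = 1e-12)
    }
  }
})

test_that("search agrees with the independent step-by-step oracle", {
  for (seed in 1:30) {
    inst <- random_instance(sample(8:25, 1), seed)
    ms <- dense_module_search(inst$net, inst$scores)
    for (m in ms$modules) {
      expect_identical(m$genes, oracle_greedy(inst$adj, inst$z, m$seed,
                                              d = 2, r = 0.1))
    }
  }
})

test_that("every module passes the exhaustive local-maximality certificate", {
  for (seed in c(11, 22)) {
    inst <- random_instance(25, seed)
    ms <- dense_module_search(inst$net, inst$scores)
    expect_true(all(check_local_maximality(inst$net, inst$scores, ms)))
  }
})

test_that("a stricter r yields a prefix of the laxer insertion sequence", {
  genes <- c("A", "B", "C", "D", "E")
  net <- path_net(genes)
  sc <- scores_from_z(genes, c(1.2, 3, 2, 1.5, 0.1))
  lax <- dense_module_search(net, sc, d = 1, r = 0.01, seeds = "B")$modules[[1]]
  strict <- dense_module_search(net, sc, d = 1, r = 0.18, seeds = "B")$modules[[1]]
  expect_lte(length(strict$genes), length(lax$genes))
  expect_identical(strict$genes, lax$genes[seq_along(strict$genes)])
})

test_that("module tables are written with ids and joined genes", {
  inst <- random_instance(15, 2)
  ms <- normalize_scores(dense_module_search(inst$net, inst$scores))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_modules(ms, path)
  back <- read.delim(path)
  expect_equal(nrow(back), length(ms$modules))
  expect_true(all(c("module_id", "seed", "z_m", "z_n", "size", "genes") %in%
                    names(back)))
})
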