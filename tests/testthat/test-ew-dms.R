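# edge weight table fixture for a network, with prescribed or null weights
ew_fixture <- function(net, w = NULL) {
  el <- igraph::as_edgelist(net)
  out <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                    r_case = 0, r_control = 0, z_raw = 0,
                    w = w %||% rep(0, nrow(el)), stringsAsFactors = FALSE)
  class(out) <- c("edge_weight_table", "data.frame")
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("combined score is the lambda mixture and validates lambda", {
  expect_equal(combined_score(2, 4, 1), 2)
  expect_equal(combined_score(2, 4, 0), 4)
  expect_equal(combined_score(2, 4, 0.5), 3)
  expect_error(combined_score(1, 1, 1.2), "\\[0, 1\\]")
  expect_error(combined_score(1, 1, -0.1), "\\[0, 1\\]")
})

test_that("an isolated seed edge scores (z_node + z_edge mixture) exactly", {
  net <- ppi_network(rbind(c("A", "B"), c("C", "D")))
  sc <- scores_from_z(c("A", "B", "C", "D"), c(1, 1, 0, 0))
  ms <- ew_dense_module_search(net, sc, ew_fixture(net, c(2, 0)), lam = 0.5)
  df <- as.data.frame(ms)
  ab <- df[df$seed_edge == "A-B", ]
  expect_equal(ab$z_node, sqrt(2), tolerance = 1e-12)
  expect_equal(ab$z_edge, 2, tolerance = 1e-12)
  expect_equal(ab$s, (sqrt(2) + 2) / 2, tolerance = 1e-12)
  # s is recomputable as the mixture
  expect_equal(df$s, 0.5 * df$z_node + 0.5 * df$z_edge, tolerance = 1e-12)
  expect_true(all(df$size >= 2L))
})

test_that("huge r pins every module to its seed edge; duplicates collapse", {
  inst <- random_instance(20, 13)
  ewt <- ew_fixture(inst$net, abs(rnorm(igraph::ecount(inst$net))))
  ms <- ew_dense_module_search(inst$net, inst$scores, ewt, lam = 0.5, r = 1e9)
  expect_true(all(vapply(ms$modules, function(m) length(m$genes), 0L) == 2L))
  expect_equal(length(ms$modules), igraph::ecount(inst$net))
  # with growth allowed, identical gene sets are collapsed
  ms2 <- ew_dense_module_search(inst$net, inst$scores, ewt, lam = 0.5, r = 0.1)
  keys <- vapply(ms2$modules, function(m) paste(sort(m$genes), collapse = ","), "")
  expect_false(anyDuplicated(keys) > 0)
})

test_that("max_size caps module growth", {
  inst <- random_instance(30, 14)
  z <- inst$z + 3  # strong signal everywhere so modules want to grow
  sc <- scores_from_z(names(z), z)
  ewt <- ew_fixture(inst$net, rep(1, igraph::ecount(inst$net)))
  ms <- ew_dense_module_search(inst$net, sc, ewt, lam = 0.5, r = 0, max_size = 4)
  expect_true(all(vapply(ms$modules, function(m) length(m$genes), 0L) <= 4L))
})

test_that("with lam = 1 and zero edge weights the search matches the
           node-only greedy oracle started from the seed edge", {
  for (seed in c(21, 22, 23)) {
    inst <- random_instance(18, seed)
    ewt <- ew_fixture(inst$net)
    ms <- ew_dense_module_search(inst$net, inst$scores, ewt, lam = 1,
                                 max_size = 1000L)
    for (m in ms$modules) {
      expect_identical(sort(m$genes),
                       sort(oracle_greedy(inst$adj, inst$z, m$seed_edge,
                                          d = 2, r = 0.1)))
    }
  }
})

test_that("modules induce connected subgraphs with at least two genes", {
  inst <- random_instance(25, 31)
  ewt <- ew_fixture(inst$net, abs(rnorm(igraph::ecount(inst$net))))
  ms <- ew_dense_module_search(inst$net, inst$scores, ewt, lam = 0.5)
  for (m in ms$modules) {
    expect_gte(length(m$genes), 2L)
    expect_true(igraph::is_connected(
      igraph::induced_subgraph(inst$net, m$genes)))
  }
})

test_that("auto lambda balances node and edge spread and is reported", {
  inst <- random_instance(20, 15)
  ewt <- ew_fixture(inst$net, abs(rnorm(igraph::ecount(inst$net), sd = 4)))
  expect_message(
    ms <- ew_dense_module_search(inst$net, inst$scores, ewt, lam = "auto"),
    "auto lambda")
  lam <- ms$params$lam
  expect_true(lam > 0 && lam < 1)
  sz <- sd(inst$z)
  sw <- sd(ewt$w)
  expect_equal(lam * sz, (1 - lam) * sw, tolerance = 1e-9)
})

test_that("permutation p-values are valid, deterministic, and monotone in s", {
  inst <- random_instance(25, 16)
  ewt <- ew_fixture(inst$net, abs(rnorm(igraph::ecount(inst$net))))
  ms <- ew_dense_module_search(inst$net, inst$scores, ewt, lam = 0.5)
  expect_error(permutation_significance(ms, inst$net, inst$scores, ewt,
                                        n_perm = 99), ">= 100")
  p1 <- permutation_significance(ms, inst$net, inst$scores, ewt,
                                 n_perm = 100, seed = 5)
  p2 <- permutation_significance(ms, inst$net, inst$scores, ewt,
                                 n_perm = 100, seed = 5)
  pp <- vapply(p1$modules, `[[`, 0, "p_perm")
  expect_identical(pp, vapply(p2$modules, `[[`, 0, "p_perm"))
  expect_true(all(pp > 0 & pp <= 1))
  df <- as.data.frame(p1)
  for (k in unique(df$size)) {
    sub <- df[df$size == k, ]
    if (nrow(sub) > 1L) {
      ord <- order(sub$s, decreasing = TRUE)
      expect_true(all(diff(sub$p_perm[ord]) >= 0))
    }
  }
})

test_that("a score above every null draw gets the add-one minimum p", {
  inst <- random_instance(20, 17)
  ewt <- ew_fixture(inst$net, abs(rnorm(igraph::ecount(inst$net))))
  fake <- structure(list(modules = list(
    list(seed_edge = c("G0001", "G0002"), genes = c("G0001", "G0002"),
         z_node = 0, z_edge = 0, s = 1e9)),
    params = list(lam = 0.5, d = 2, r = 0.1, max_size = 10)),
    class = "ew_module_set")
  out <- permutation_significance(fake, inst$net, inst$scores, ewt,
                                  n_perm = 100, seed = 1)
  expect_equal(out$modules[[1]]$p_perm, 1 / 101)
})

test_that("null-drawn modules have roughly uniform permutation p", {
  inst <- random_instance(30, 18)
  ewt <- ew_fixture(inst$net, abs(rnorm(igraph::ecount(inst$net))))
  sub <- dmsearch:::build_ew_substrate(inst$net, inst$scores, ewt)
  set.seed(19)
  draws <- replicate(60, {
    g <- dmsearch:::random_connected_subgraph(sub$net, 4L, sub$nbrw)
    st <- dmsearch:::module_edge_stats(g, sub$nbrw)
    list(seed_edge = g[1:2], genes = g, z_node = module_score(sub$z[g]),
         z_edge = st$sum_w / sqrt(st$m),
         s = combined_score(module_score(sub$z[g]),
                            st$sum_w / sqrt(st$m), 0.5))
  }, simplify = FALSE)
  fake <- structure(list(modules = draws,
                         params = list(lam = 0.5, d = 2, r = 0.1,
                                       max_size = 10)),
                    class = "ew_module_set")
  out <- permutation_significance(fake, inst$net, inst$scores, ewt,
                                  n_perm = 400, seed = 20)
  pp <- vapply(out$modules, `[[`, 0, "p_perm")
  expect_lt(abs(mean(pp) - 0.5), 0.08)
})

test_that("weighted edges outside the network are reported by gene name", {
  net <- path_net(c("A", "B", "C"))
  sc <- scores_from_z(c("A", "B", "C", "X"), c(1, 1, 1, 1))
  ewt <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "X"),
                    r_case = 0, r_control = 0, z_raw = 0, w = 1)
  expect_error(ew_dense_module_search(net, sc, ewt), "X")
  # a substrate with no usable edge is rejected outright
  expect_error(ew_dense_module_search(net, scores_from_z("A", 1),
                                      ewt[1, ]), "no edge")
})
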