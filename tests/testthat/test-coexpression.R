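test_that("probe collapsing averages probes per gene and keeps samples", {
  values <- rbind(p1 = c(2, 10), p2 = c(4, 20), p3 = c(5, 5), px = c(9, 9))
  colnames(values) <- c("s1", "s2")
  map <- c(p1 = "g1", p2 = "g1", p3 = "g2")
  cond <- c(s1 = "case", s2 = "control")
  expect_message(es <- collapse_probes(values, map, cond), "1 unmapped")
  expect_equal(ncol(es$values), 2L)
  expect_equal(es$values["G1", ], c(s1 = 3, s2 = 15))
  expect_equal(es$values["G2", ], c(s1 = 5, s2 = 5))  # single probe unchanged
  expect_equal(attr(es, "n_unmapped"), 1L)
  # three probes 1, 2, 6 average to 3
  v3 <- rbind(a = c(1, 1), b = c(2, 2), c = c(6, 6))
  colnames(v3) <- c("s1", "s2")
  es3 <- collapse_probes(v3, c(a = "g", b = "g", c = "g"), cond)
  expect_equal(unname(es3$values["G", 1]), 3)
  # per-gene totals are preserved: k * mean == sum of probes
  expect_equal(2 * es$values["G1", ], colSums(values[c("p1", "p2"), ]))
  expect_error(collapse_probes(values, c(zz = "g9"), cond), "no probe")
})

test_that("differential expression is mean difference on the log2 scale", {
  genes <- c("FLAT", "UP1", "UP2")
  case <- matrix(rep(c(3, 4, 5), 4), 3, 4, dimnames = list(genes, NULL))
  ctrl <- matrix(rep(c(3, 3, 3), 4), 3, 4, dimnames = list(genes, NULL))
  # jitter so the t-test has within-group variance
  set.seed(1)
  case <- case + rnorm(12, sd = 0.01)
  ctrl <- ctrl + rnorm(12, sd = 0.01)
  de <- differential_expression(expr_fixture(case, ctrl))
  expect_equal(de$log2fc, c(0, 1, 2), tolerance = 0.05)
  # two-fold flag is strict: log2FC == 1 must not count
  de_exact <- data.frame(log2fc = c(1, 1.0001, 2))
  expect_identical(abs(de_exact$log2fc) > 1, c(FALSE, TRUE, TRUE))
  expect_false(de$twofold[1])
  expect_true(de$twofold[3])
  expect_true(de$p[3] < 0.05 && de$p[1] > 0.05)
  one <- expr_fixture(case[, 1, drop = FALSE], ctrl)
  expect_error(differential_expression(one), ">= 2 samples")
})

test_that("Fisher z difference statistic matches its closed form", {
  # r_case 0.9 vs r_control -0.9 at n = 7 vs 6:
  # (1.47222 + 1.47222)/sqrt(1/4 + 1/3) = 3.855
  expect_equal(dmsearch:::fisher_z_diff(0.9, -0.9, 7, 6), 3.855,
               tolerance = 1e-3)
  expect_equal(dmsearch:::fisher_z_diff(0.42, 0.42, 7, 6), 0)
  # clipping keeps perfect correlations finite
  expect_true(is.finite(dmsearch:::fisher_z_diff(1, -1, 7, 6)))
  expect_error(dmsearch:::fisher_z_diff(0.5, 0, 3, 6), "more than 3")
})

test_that("edge weights are antisymmetric in the labels and floored at zero", {
  net <- generate_network(20, seed = 4)
  truth <- structure(list(planted_genes = c("G0001", "G0002")),
                     class = "synthetic_truth")
  es <- generate_expression(net, truth, r_case = 0.7, seed = 5)
  ew <- edge_weight(es, net)
  expect_true(all(ew$r_case >= -1 & ew$r_case <= 1))
  expect_true(all(ew$w >= 0))
  expect_equal(min(ew$w), 0)
  flipped <- es
  flipped$condition <- ifelse(es$condition == "case", "control", "case")
  # swapped labels negate z_raw up to the unequal group sizes (6 vs 7 swaps
  # the variance terms symmetrically, so the statistic is exactly negated)
  ew2 <- edge_weight(flipped, net)
  expect_equal(ew2$z_raw, -ew$z_raw, tolerance = 1e-12)
  expect_equal(ew2$w, ew$w, tolerance = 1e-12)
})

test_that("degenerate genes drop their edges with a warning", {
  net <- path_net(c("A", "B", "C"))
  set.seed(2)
  vals <- matrix(rnorm(3 * 9, mean = 7), 3, 9,
                 dimnames = list(c("A", "B", "C"), paste0("s", 1:9)))
  vals["A", 1:5] <- 7  # zero variance within cases
  es <- expression_set(vals, setNames(c(rep("case", 5), rep("control", 4)),
                                      paste0("s", 1:9)), check_scale = FALSE)
  expect_warning(ew <- edge_weight(es, net), "zero-variance")
  expect_equal(nrow(ew), 1L)
  expect_setequal(c(ew$gene_a, ew$gene_b), c("B", "C"))
})

test_that("edges with unmeasured genes are skipped and counted", {
  net <- path_net(c("A", "B", "C"))
  set.seed(3)
  vals <- matrix(rnorm(2 * 9, mean = 7), 2, 9,
                 dimnames = list(c("A", "B"), paste0("s", 1:9)))
  es <- expression_set(vals, setNames(c(rep("case", 5), rep("control", 4)),
                                      paste0("s", 1:9)), check_scale = FALSE)
  ew <- edge_weight(es, net)
  expect_equal(nrow(ew), 1L)
  expect_equal(attr(ew, "n_unmeasured"), 1L)
})

test_that("permuted-label z_raw is centered near zero under the null", {
  net <- generate_network(25, seed = 6)
  truth <- structure(list(planted_genes = c("G0001", "G0002")),
                     class = "synthetic_truth")
  es <- generate_expression(net, truth, r_case = 0, r_control = 0, seed = 7)
  set.seed(8)
  n_case <- sum(es$condition == "case")
  means <- replicate(300, {
    perm <- es
    perm$condition <- sample(es$condition)
    mean(suppressWarnings(edge_weight(perm, net))$z_raw)
  })
  expect_lt(abs(mean(means)), 0.15)
})

test_that("expression and condition files round-trip through readers", {
  net <- generate_network(12, seed = 9)
  truth <- structure(list(planted_genes = c("G0001", "G0002")),
                     class = "synthetic_truth")
  es <- generate_expression(net, truth, seed = 10)
  epath <- withr::local_tempfile(fileext = ".tsv")
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = rownames(es$values), es$values,
                         check.names = FALSE),
              epath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = colnames(es$values),
                         condition = es$condition),
              cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_expression(epath, cpath)
  expect_equal(back$values, es$values, tolerance = 1e-10)
  expect_identical(back$condition, es$condition)
})
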