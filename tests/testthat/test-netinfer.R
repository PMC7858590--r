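test_that("mutual information is symmetric, non-negative, and hits known values", {
  set.seed(2)
  x <- rnorm(100); y <- rnorm(100)
  expect_identical(compute_mi(x, y), compute_mi(y, x))
  expect_gte(compute_mi(x, y), 0)
  # identical tie-free vectors attain ln(B) exactly for the raw plug-in
  v <- sample(1:100)
  B <- floor(sqrt(100))
  expect_equal(compute_mi(v, v, bias_correction = FALSE), log(B))
  expect_warning(mi0 <- compute_mi(rep(1, 50), rnorm(50)), "constant")
  expect_equal(mi0, 0)
  expect_error(compute_mi(1:5, 1:5), "at least 8")
})

test_that("binned MI approximates the Gaussian closed form", {
  set.seed(7)
  n <- 5000
  x <- rnorm(n)
  y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(n)
  truth <- -0.5 * log(1 - 0.8^2)  # 0.5108 nats
  expect_lt(abs(compute_mi(x, y) - truth) / truth, 0.25)
})

test_that("independent vectors fall below the permutation threshold", {
  thr <- mi_significance_threshold(200, alpha = 0.05, n_perm = 1000, seed = 3)
  set.seed(11)
  below <- vapply(seq_len(100), function(i)
    compute_mi(rnorm(200), rnorm(200)) < thr, logical(1))
  expect_gte(mean(below), 0.9)
})

test_that("the MI threshold behaves like a null quantile", {
  set.seed(4)
  # alpha = 0.5 recovers the null median
  thr50 <- mi_significance_threshold(100, alpha = 0.5, n_perm = 2000, seed = 5)
  B <- floor(sqrt(100))
  null_mi <- vapply(1:2000, function(i)
    compute_mi(rnorm(100), rnorm(100)), numeric(1))
  med <- median(null_mi)
  expect_lt(abs(thr50 - med), max(0.1 * med, 0.01))
  # monotone in alpha
  t1 <- mi_significance_threshold(100, alpha = 1e-4, n_perm = 2000, seed = 5)
  t2 <- mi_significance_threshold(100, alpha = 1e-2, n_perm = 2000, seed = 5)
  expect_gt(t1, t2)
  # null concentrates with more samples
  t_small <- mi_significance_threshold(50, alpha = 1e-4, n_perm = 2000, seed = 5)
  t_large <- mi_significance_threshold(200, alpha = 1e-4, n_perm = 2000, seed = 5)
  expect_gt(t_small, t_large)
})

test_that("DPI removes the weakest triangle edge with multiplicative tolerance", {
  tri <- function(mis) mi_network(c("a", "b", "c"),
    data.frame(gene_a = c("a", "b", "a"), gene_b = c("b", "c", "c"), mi = mis))
  # 0.3 < 0.9 * min(0.9, 0.8) -> removed
  pruned <- apply_dpi(tri(c(0.9, 0.8, 0.3)), 0.1)
  expect_equal(sort(pruned$edges$mi), c(0.8, 0.9))
  # 0.75 >= 0.72 -> rescued by tolerance
  kept <- apply_dpi(tri(c(0.9, 0.8, 0.75)), 0.1)
  expect_equal(nrow(kept$edges), 3)
  expect_error(apply_dpi(tri(c(0.9, 0.8, 0.3)), 1.5), "tolerance")
})

test_that("DPI matches an exhaustive triangle oracle on random networks", {
  for (s in 1:8) {
    ed <- random_edges(30, 0.25, seed = 400 + s)
    net <- mi_network(sprintf("n%02d", 1:30), ed)
    pruned <- apply_dpi(net, 0.1)
    oracle <- oracle_dpi(ed, 0.1)
    key <- function(d) sort(paste(pmin(d$gene_a, d$gene_b),
                                  pmax(d$gene_a, d$gene_b)))
    expect_identical(key(pruned$edges), key(oracle))
    # never adds edges
    expect_true(all(key(pruned$edges) %in% key(ed)))
    # single-pass idempotence on these instances
    twice <- apply_dpi(pruned, 0.1)
    expect_identical(key(twice$edges), key(pruned$edges))
  }
})

test_that("network inference is calibrated on pure noise and prunes Markov chains", {
  # null matrix: pre-DPI edge count near alpha * n_pairs
  set.seed(21)
  mat <- matrix(rnorm(60 * 100), 60, 100,
                dimnames = list(sprintf("g%02d", 1:60), NULL))
  alpha <- 0.02
  net <- build_network(mat, alpha = alpha, seed = 9, dpi = FALSE)
  n_pairs <- choose(60, 2)
  expected <- alpha * n_pairs
  expect_lt(abs(nrow(net$edges) - expected),
            3 * sqrt(n_pairs * alpha * (1 - alpha)) + 1)
  # Markov triple X -> Y -> Z: the X-Z edge is indirect and DPI-pruned
  removed <- vapply(1:10, function(s) {
    set.seed(600 + s)
    n <- 300
    x <- rnorm(n); y <- x + 0.4 * rnorm(n); z <- y + 0.4 * rnorm(n)
    m <- rbind(x = x, y = y, z = z)
    net <- build_network(m, alpha = 0.01, seed = 700 + s)
    ed <- net$edges
    !any((ed$gene_a == "x" & ed$gene_b == "z") |
         (ed$gene_a == "z" & ed$gene_b == "x"))
  }, logical(1))
  expect_gte(mean(removed), 0.9)
})

test_that("planted hubs land in the top decile with full recall", {
  for (s in 1:3) {
    ex <- simulate_expression(n_genes = 250, n_samples = 120, n_hubs = 5,
                              targets_per_hub = 20, seed = s)
    net <- suppressWarnings(build_network(cpm_normalize(ex$counts),
                                          seed = 100 + s))
    hubs <- select_hubs(net, 0.10)
    expect_equal(sum(ex$hubs %in% hubs$hubs), 5)
  }
})

test_that("hub selection follows the documented ranking and rounding", {
  # 12,549 nodes at fraction 0.10 -> exactly 1255 hubs
  nodes <- sprintf("g%05d", seq_len(12549))
  ed <- data.frame(gene_a = nodes[1:200], gene_b = nodes[201:400],
                   mi = runif(200))
  big <- mi_network(nodes, ed)
  expect_equal(select_hubs(big, 0.10)$n_hubs, 1255)
  # 10 nodes -> 1 hub
  small <- mi_network(sprintf("g%02d", 1:10),
                      data.frame(gene_a = "g01", gene_b = "g02", mi = 0.5))
  expect_equal(select_hubs(small, 0.10)$n_hubs, 1)
  # matches an independent sort-and-slice oracle on a random network
  ed2 <- random_edges(100, 0.05, seed = 12)
  nn <- sprintf("n%02d", 1:100)
  net2 <- mi_network(nn, ed2)
  hs <- select_hubs(net2, 0.10)
  deg <- sapply(nn, function(g) sum(ed2$gene_a == g) + sum(ed2$gene_b == g))
  msum <- sapply(nn, function(g)
    sum(ed2$mi[ed2$gene_a == g]) + sum(ed2$mi[ed2$gene_b == g]))
  oracle_rank <- nn[order(-deg, -msum, nn)]
  expect_identical(hs$hubs, oracle_rank[1:10])
  # hub-hub edge count is consistent
  expect_equal(hs$n_hub_edges,
               sum(ed2$gene_a %in% hs$hubs & ed2$gene_b %in% hs$hubs))
  expect_error(select_hubs(net2, 0), "fraction")
})
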