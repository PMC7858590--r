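test_that("CPM normalization divides by library size and rescales to one million", {
  m <- matrix(c(10, 990, 5, 495), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cpm <- cpm_normalize(m)
  expect_equal(cpm["g1", "s1"], 10 / 1000 * 1e6)
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
  # matches a direct two-line recomputation on a random matrix
  set.seed(8)
  r <- matrix(rpois(200, 50), 20, 10)
  expect_equal(cpm_normalize(r), t(t(r) / colSums(r)) * 1e6)
  # and edgeR's cpm
  expect_equal(unname(cpm_normalize(r)), unname(edgeR::cpm(r)), tolerance = 1e-8)
  bad <- matrix(c(1, 2, 0, 0), 2, 2, dimnames = list(NULL, c("ok", "empty")))
  expect_error(cpm_normalize(bad), "empty")
})

test_that("planted differential genes are recovered with controlled false positives", {
  tg <- simulate_counts_twogroup(n_genes = 5000, n_per_group = 3, n_deg = 100,
                                 lfc = 2, seed = 14)
  degs <- call_degs(tg$counts, which(tg$group == "B"), which(tg$group == "A"))
  recall <- mean(tg$deg_truth$gene %in% degs$gene)
  expect_gte(recall, 0.9)
  null_genes <- setdiff(rownames(tg$counts), tg$deg_truth$gene)
  fpr <- mean(null_genes %in% degs$gene)
  expect_lte(fpr, 0.05)
  # directions match the planted truth for every recovered gene
  hit <- merge(degs, tg$deg_truth, by = "gene")
  expect_true(all(hit$direction.x == hit$direction.y))
})

test_that("DEG calling is symmetric and null on identical groups", {
  tg <- simulate_counts_twogroup(n_genes = 1000, n_per_group = 3, n_deg = 20,
                                 lfc = 2, seed = 15)
  ib <- which(tg$group == "B"); ia <- which(tg$group == "A")
  d1 <- call_degs(tg$counts, ib, ia)
  d2 <- call_degs(tg$counts, ia, ib)
  m <- merge(d1, d2, by = "gene")
  expect_equal(m$log2_fold_change.x, -m$log2_fold_change.y)
  expect_equal(m$p.x, m$p.y)
  # same columns duplicated -> zero DEGs
  same <- cbind(tg$counts[, ia], tg$counts[, ia])
  colnames(same) <- sprintf("s%d", 1:6)
  expect_equal(nrow(call_degs(same, 1:3, 4:6)), 0)
})

test_that("uniform count scaling shifts raw log means but not CPM fold changes", {
  tg <- simulate_counts_twogroup(n_genes = 500, n_per_group = 3, n_deg = 0,
                                 seed = 16)
  doubled <- tg$counts
  ib <- which(tg$group == "B")
  doubled[, ib] <- doubled[, ib] * 2L
  # before normalization the raw log2 means shift by ~1...
  raw_shift <- rowMeans(log2(doubled[, ib] + 0.5)) -
    rowMeans(log2(tg$counts[, ib] + 0.5))
  expect_equal(mean(raw_shift), 1, tolerance = 0.02)
  # ...and after CPM normalization the fold change is unchanged
  lc1 <- log2(cpm_normalize(tg$counts) + 0.5)
  lc2 <- log2(cpm_normalize(doubled) + 0.5)
  expect_equal(lc1[, ib], lc2[, ib], tolerance = 1e-8)
})

test_that("the rank-based FDR formula and its step-up variant are exact", {
  # q_i = p_i * n / i on the worked example
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(fdr_adjust(0.2), 0.2)  # single p: n = i = 1
  # q is capped at 1 and never below p for the smallest p
  p <- c(0.9, 0.95, 0.2)
  q <- fdr_adjust(p)
  expect_true(all(q <= 1))
  expect_gte(q[which.min(p)], min(p))
  # monotone mode equals the classical step-up procedure (p.adjust oracle)
  set.seed(31)
  for (i in 1:20) {
    pv <- runif(sample(5:50, 1))
    expect_equal(fdr_adjust(pv, monotone = TRUE), p.adjust(pv, "BH"))
  }
  expect_error(fdr_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("enrichment scores match a brute-force running sum and front-loading", {
  # 12-gene worked example against the exhaustive scan oracle
  set.seed(41)
  genes <- sprintf("g%02d", 1:12)
  scores <- setNames(sort(rnorm(12), decreasing = TRUE), genes)
  set <- genes[c(1, 3, 4, 9)]
  res <- suppressWarnings(
    preranked_gsea(scores, list(s = set), n_perm = 200, seed = 2, min_size = 3))
  expect_equal(res$es, oracle_es(names(scores), unname(scores), set))
  # a set of the top 10 of 1000 genes is maximally front-loaded
  g1000 <- sprintf("g%04d", 1:1000)
  sc <- setNames(seq(3, -3, length.out = 1000), g1000)
  top <- preranked_gsea(sc, list(top10 = g1000[1:10]), n_perm = 100, seed = 3)
  expect_gt(top$es, 0.9)
  expect_lte(abs(top$es), 1)
  # independent cross-check against fgsea's enrichment statistic
  stats50 <- setNames(sort(rnorm(50), decreasing = TRUE), sprintf("h%02d", 1:50))
  set50 <- names(stats50)[c(1, 3, 4, 9, 20, 33)]
  ours <- suppressWarnings(preranked_gsea(stats50, list(s = set50),
                                          n_perm = 50, seed = 1))$es
  theirs <- fgsea::calcGseaStat(stats50,
                                selectedStats = which(names(stats50) %in% set50),
                                gseaParam = 1)
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("ES flips sign when a strictly monotone ranking is reversed", {
  genes <- sprintf("g%03d", 1:200)
  sc <- setNames(seq(2, -2, length.out = 200), genes)
  set <- genes[1:15]
  fwd <- preranked_gsea(sc, list(s = set), n_perm = 100, seed = 5)
  rev <- preranked_gsea(setNames(-unname(sc), genes), list(s = set),
                        n_perm = 100, seed = 5)
  expect_gt(fwd$es, 0)
  expect_lt(rev$es, 0)
})

test_that("random gene sets give approximately uniform permutation p-values", {
  genes <- sprintf("g%03d", 1:300)
  set.seed(61)
  sc <- setNames(rnorm(300), genes)
  ps <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    s <- sample(genes, 20)
    suppressWarnings(preranked_gsea(sc, list(x = s), n_perm = 100,
                                    seed = 2000 + i))$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("gene sets round-trip through GMT and small sets are skipped", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = sprintf("x%d", 1:8))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_identical(read_gmt(path), sets)
  sc <- setNames(rnorm(50), sprintf("g%02d", 1:50))
  expect_warning(res <- preranked_gsea(sc, list(tiny = c("g01", "g02")),
                                       n_perm = 50, seed = 1), "skipped")
  expect_equal(nrow(res), 0)
})

test_that("responsive-gene counting is a union over DEG tables", {
  t1 <- data.frame(gene = sprintf("a%d", 1:10))
  t2 <- data.frame(gene = sprintf("b%d", 1:10))
  expect_equal(count_responsive_genes(list(t1, t2)), 20)
  expect_equal(count_responsive_genes(list(t1, t1, t1)), 10)
  expect_equal(count_responsive_genes(list(t1, data.frame(gene = "a1"))), 10)
  expect_error(count_responsive_genes(list()), "at least one")
})
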