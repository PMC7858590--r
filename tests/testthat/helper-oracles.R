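# Independent oracles used across tests. These deliberately re-derive
# quantities by different routes than the package implementation.

# eccentricity from raw second central moments (closed-form eigenvalues,
# no eigen() call) of a pixel list
oracle_ecc <- function(rows, cols) {
  n <- length(rows)
  mu20 <- sum((rows - mean(rows))^2) / n
  mu02 <- sum((cols - mean(cols))^2) / n
  mu11 <- sum((rows - mean(rows)) * (cols - mean(cols))) / n
  disc <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + disc) / 2
  l2 <- (mu20 + mu02 - disc) / 2
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

# textbook Welch statistic written out in full
oracle_welch <- function(a, b) {
  (sum(a) / length(a) - sum(b) / length(b)) /
    sqrt(sum((a - mean(a))^2) / (length(a) - 1) / length(a) +
         sum((b - mean(b))^2) / (length(b) - 1) / length(b))
}

# exhaustive O(n^3) DPI: enumerate all vertex triples over an edge data
# frame, mark weakest edges, remove simultaneously
oracle_dpi <- function(edges, tolerance) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  mi <- stats::setNames(edges$mi, key(edges$gene_a, edges$gene_b))
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  drop <- character(0)
  if (length(nodes) >= 3) {
    combs <- utils::combn(nodes, 3)
    for (k in seq_len(ncol(combs))) {
      v <- combs[, k]
      ks <- c(key(v[1], v[2]), key(v[2], v[3]), key(v[1], v[3]))
      if (all(ks %in% names(mi))) {
        m <- mi[ks]
        w <- which.min(m)
        if (m[w] < (1 - tolerance) * min(m[-w])) drop <- c(drop, ks[w])
      }
    }
  }
  edges[!(key(edges$gene_a, edges$gene_b) %in% drop), , drop = FALSE]
}

# brute-force GSEA running sum evaluated at every position
oracle_es <- function(ranked, weights, set) {
  hit <- ranked %in% set
  nr <- sum(abs(weights)[hit])
  dev <- numeric(length(ranked))
  run <- 0
  for (i in seq_along(ranked)) {
    run <- run + if (hit[i]) abs(weights[i]) / nr else -1 / (length(ranked) - sum(hit))
    dev[i] <- run
  }
  dev[which.max(abs(dev))]
}

# random connected-ish edge set on n nodes for DPI comparisons
random_edges <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  data.frame(gene_a = pairs[1, keep], gene_b = pairs[2, keep],
             mi = stats::runif(sum(keep), 0.1, 1), stringsAsFactors = FALSE)
}

# rasterize a filled ellipse mask (integer center, arbitrary rotation)
ellipse_mask <- function(a, b, theta = 0, shape = c(128, 128),
                         center = round(shape / 2)) {
  r <- row(matrix(0, shape[1], shape[2])) - center[1]
  c <- col(matrix(0, shape[1], shape[2])) - center[2]
  u <- r * cos(theta) + c * sin(theta)
  v <- -r * sin(theta) + c * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}
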