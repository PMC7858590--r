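# ARACNe-style regulatory network inference: rank-binned mutual information,
# permutation-calibrated significance with exponential tail extrapolation,
# data-processing-inequality (DPI) triangle pruning, and hub selection by
# connectivity.

.bin_vector <- function(x, B) {
  n <- length(x)
  b <- ceiling(B * rank(x, ties.method = "average") / n)
  pmin(pmax(b, 1L), B)
}

.mi_from_bins <- function(bx, by, B, bias_correction = TRUE) {
  n <- length(bx)
  joint <- tabulate(bx + B * (by - 1L), nbins = B * B) / n
  px <- tabulate(bx, nbins = B) / n
  py <- tabulate(by, nbins = B) / n
  pp <- outer(px, py)
  idx <- joint > 0
  mi <- sum(joint[idx] * log(joint[idx] / pp[idx]))
  if (bias_correction) mi <- mi - (B - 1)^2 / (2 * n)
  max(mi, 0)
}

#' Mutual information between two sample vectors
#'
#' Rank-transforms both vectors, discretizes each into
#' \code{B = floor(sqrt(n))} equal-frequency bins, and evaluates the plug-in
#' mutual information \eqn{\sum_{ij} \hat p_{ij} \ln(\hat p_{ij}/(\hat p_i
#' \hat p_j))} in nats. By default the Miller-Madow first-order bias
#' \eqn{(B-1)^2/(2n)} is subtracted and the result clamped at 0, which makes
#' the estimator approximately unbiased at this bin count;
#' \code{bias_correction = FALSE} gives the raw plug-in value (for which two
#' identical tie-free vectors attain exactly \eqn{\ln B}).
#'
#' @param x,y Numeric vectors of equal length (n >= 8).
#' @param bias_correction Subtract the Miller-Madow bias term (default TRUE).
#' @return Non-negative mutual information in nats.
#' @export
compute_mi <- function(x, y, bias_correction = TRUE) {
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have equal length", call. = FALSE)
  if (n < 8) stop("need at least 8 samples", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: MI defined as 0", call. = FALSE)
    return(0)
  }
  B <- floor(sqrt(n))
  .mi_from_bins(.bin_vector(x, B), .bin_vector(y, B), B, bias_correction)
}

#' Permutation-calibrated MI significance threshold
#'
#' Builds a null distribution of MI values between independent vectors of
#' length \code{n_samples}. For moderate \code{alpha} the empirical
#' \code{1 - alpha} quantile is returned directly; for extreme levels (such
#' as the screen's 1e-7, unreachable by direct permutation) an exponential
#' tail is fitted to the exceedances over the null's 95th percentile
#' (peaks-over-threshold) and the quantile is extrapolated. Deterministic
#' given \code{seed}.
#'
#' @param n_samples Sample size of the expression profiles.
#' @param alpha Per-pair significance level in (0, 1).
#' @param n_perm Number of null draws (>= 1000).
#' @param seed Integer seed.
#' @param bias_correction Passed to the MI estimator.
#' @return MI threshold in nats.
#' @export
mi_significance_threshold <- function(n_samples, alpha = 1e-7, n_perm = 2000,
                                      seed = 1, bias_correction = TRUE) {
  .check_number(alpha, "alpha", 0, 1, allow_lower = FALSE, allow_upper = FALSE)
  if (n_perm < 1000) stop("n_perm must be at least 1000", call. = FALSE)
  set.seed(as.integer(seed))
  B <- floor(sqrt(n_samples))
  null_mi <- vapply(seq_len(n_perm), function(i) {
    .mi_from_bins(.bin_vector(stats::rnorm(n_samples), B),
                  .bin_vector(stats::rnorm(n_samples), B),
                  B, bias_correction)
  }, numeric(1))
  if (stats::sd(null_mi) == 0)
    stop("degenerate permutation null (zero variance)", call. = FALSE)
  q0 <- 0.95
  if (alpha >= 1 - q0)
    return(unname(stats::quantile(null_mi, 1 - alpha, type = 7)))
  u <- unname(stats::quantile(null_mi, q0, type = 7))
  exceed <- null_mi[null_mi > u] - u
  lambda <- mean(exceed)
  u + lambda * log((1 - q0) / alpha)
}

# exponential-tail p-value for observed MI values, given a null sample
.mi_tail_p <- function(mi, null_mi, q0 = 0.95) {
  u <- unname(stats::quantile(null_mi, q0, type = 7))
  lambda <- mean(null_mi[null_mi > u] - u)
  p_emp <- vapply(mi, function(m)
    (1 + sum(null_mi >= m)) / (1 + length(null_mi)), numeric(1))
  ifelse(mi > u, pmin((1 - q0) * exp(-(mi - u) / lambda), p_emp), p_emp)
}

#' Construct a mutual-information network object
#'
#' @param nodes Character vector of all node (gene) identifiers.
#' @param edges Data frame with columns \code{gene_a}, \code{gene_b},
#'   \code{mi} and optionally \code{p}; undirected, no self-edges or
#'   duplicate pairs.
#' @param alpha,dpi_tolerance Parameters recorded with the network.
#' @return Object of class \code{"mi_network"}.
#' @export
mi_network <- function(nodes, edges, alpha = NA_real_, dpi_tolerance = NA_real_) {
  stopifnot(is.data.frame(edges), all(c("gene_a", "gene_b", "mi") %in% names(edges)))
  if (nrow(edges)) {
    if (any(edges$gene_a == edges$gene_b)) stop("self-edges not allowed", call. = FALSE)
    key <- paste(pmin(edges$gene_a, edges$gene_b), pmax(edges$gene_a, edges$gene_b))
    if (anyDuplicated(key)) stop("duplicate edges not allowed", call. = FALSE)
  }
  if (!"p" %in% names(edges)) edges$p <- NA_real_
  structure(list(nodes = as.character(nodes), edges = edges,
                 alpha = alpha, dpi_tolerance = dpi_tolerance),
            class = "mi_network")
}

#' @export
print.mi_network <- function(x, ...) {
  cat(sprintf("MI network: %d nodes, %d edges (alpha = %g, DPI tolerance = %g)\n",
              length(x$nodes), nrow(x$edges), x$alpha, x$dpi_tolerance))
  invisible(x)
}

#' Prune indirect interactions with the data processing inequality
#'
#' For every triangle of edges the weakest edge is marked for removal when
#' its MI falls below \code{(1 - tolerance)} times the smaller of the other
#' two edges' MI; all marked edges are removed simultaneously after scanning
#' every triangle (ARACNe's convention, with multiplicative tolerance).
#'
#' @param network An \code{\link{mi_network}}.
#' @param tolerance DPI tolerance in [0, 1); the screen's analysis used 0.1.
#' @return The pruned \code{mi_network}.
#' @export
apply_dpi <- function(network, tolerance = 0.1) {
  stopifnot(inherits(network, "mi_network"))
  if (!is.numeric(tolerance) || tolerance < 0 || tolerance >= 1)
    stop("tolerance must lie in [0, 1)", call. = FALSE)
  ed <- network$edges
  if (nrow(ed) < 3) {
    network$dpi_tolerance <- tolerance
    return(network)
  }
  g <- igraph::graph_from_data_frame(ed[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  igraph::E(g)$mi <- ed$mi
  igraph::E(g)$eid <- seq_len(nrow(ed))
  tri <- igraph::triangles(g)
  drop <- logical(nrow(ed))
  if (length(tri)) {
    tri <- matrix(as.integer(tri), nrow = 3)
    # one vectorized edge-id lookup for all triangle sides
    pairs <- rbind(tri[1, ], tri[2, ], tri[2, ], tri[3, ], tri[1, ], tri[3, ])
    eids <- matrix(igraph::get_edge_ids(g, as.vector(pairs)), nrow = 3)
    mi_tri <- matrix(igraph::E(g)$mi[eids], nrow = 3)
    for (k in seq_len(ncol(tri))) {
      mis <- mi_tri[, k]
      w <- which.min(mis)
      if (mis[w] < (1 - tolerance) * min(mis[-w]))
        drop[igraph::E(g)$eid[eids[w, k]]] <- TRUE
    }
  }
  network$edges <- ed[!drop, , drop = FALSE]
  rownames(network$edges) <- NULL
  network$dpi_tolerance <- tolerance
  network
}

#' Infer an MI network from an expression matrix
#'
#' Scores every gene pair with \code{\link{compute_mi}} (the rank transform
#' makes the result invariant to monotone per-gene normalization such as CPM
#' vs log-CPM), keeps pairs whose MI exceeds the permutation-calibrated
#' threshold at level \code{alpha}, attaches tail-extrapolated p-values, and
#' prunes indirect edges with \code{\link{apply_dpi}}.
#'
#' @param expr Numeric matrix, genes in rows (rownames used as identifiers),
#'   samples in columns (>= 8).
#' @param alpha Per-pair significance level (the screen used 1e-7).
#' @param tolerance DPI tolerance (the screen used 0.1).
#' @param seed Integer seed for the permutation null.
#' @param n_perm Null draws for threshold calibration.
#' @param dpi Apply DPI pruning (set FALSE to keep the raw thresholded
#'   network).
#' @return An \code{\link{mi_network}}.
#' @export
build_network <- function(expr, alpha = 1e-7, tolerance = 0.1, seed = 1,
                          n_perm = 2000, dpi = TRUE) {
  expr <- as.matrix(expr)
  n <- ncol(expr)
  if (n < 8) stop("need at least 8 samples", call. = FALSE)
  genes <- rownames(expr)
  if (is.null(genes)) genes <- sprintf("g%04d", seq_len(nrow(expr)))
  B <- floor(sqrt(n))
  binmat <- t(apply(expr, 1, .bin_vector, B = B))

  set.seed(derive_seed(seed, 1))
  null_mi <- vapply(seq_len(n_perm), function(i) {
    .mi_from_bins(.bin_vector(stats::rnorm(n), B),
                  .bin_vector(stats::rnorm(n), B), B)
  }, numeric(1))
  q0 <- 0.95
  u <- unname(stats::quantile(null_mi, q0, type = 7))
  lambda <- mean(null_mi[null_mi > u] - u)
  threshold <- if (alpha >= 1 - q0) unname(stats::quantile(null_mi, 1 - alpha, type = 7))
               else u + lambda * log((1 - q0) / alpha)

  ng <- nrow(expr)
  res <- vector("list", ng - 1L)
  for (i in seq_len(ng - 1L)) {
    js <- (i + 1L):ng
    mis <- vapply(js, function(j)
      .mi_from_bins(binmat[i, ], binmat[j, ], B), numeric(1))
    keep <- mis >= threshold
    if (any(keep))
      res[[i]] <- data.frame(gene_a = genes[i], gene_b = genes[js[keep]],
                             mi = mis[keep], stringsAsFactors = FALSE)
  }
  ed <- do.call(rbind, res)
  if (is.null(ed))
    ed <- data.frame(gene_a = character(0), gene_b = character(0), mi = numeric(0))
  ed$p <- .mi_tail_p(ed$mi, null_mi, q0)
  net <- mi_network(genes, ed, alpha = alpha, dpi_tolerance = tolerance)
  if (dpi) net <- apply_dpi(net, tolerance)
  net
}

#' Select top-connectivity hub genes
#'
#' Ranks nodes by degree (edge count), breaking ties by summed edge MI and
#' then lexicographic identifier, and returns the top
#' \code{round(fraction * n_nodes)} genes (half away from zero, so a
#' 12,549-node network at fraction 0.10 yields 1255 hubs). Also reports the
#' number of network edges with both endpoints among the hubs.
#'
#' @param network An \code{\link{mi_network}} (all nodes participate in the
#'   ranking; isolated nodes have degree 0).
#' @param fraction Top fraction of nodes to select, in (0, 1].
#' @return Object of class \code{"hub_set"}: list with \code{hubs},
#'   \code{n_hubs}, \code{fraction}, \code{ranking} (data frame with degree
#'   and summed MI) and \code{n_hub_edges}.
#' @export
select_hubs <- function(network, fraction = 0.10) {
  stopifnot(inherits(network, "mi_network"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  nodes <- network$nodes
  if (!length(nodes)) stop("empty network", call. = FALSE)
  ed <- network$edges
  deg <- stats::setNames(integer(length(nodes)), nodes)
  smi <- stats::setNames(numeric(length(nodes)), nodes)
  if (nrow(ed)) {
    ta <- table(factor(ed$gene_a, levels = nodes))
    tb <- table(factor(ed$gene_b, levels = nodes))
    deg <- as.integer(ta + tb); names(deg) <- nodes
    sa <- tapply(ed$mi, factor(ed$gene_a, levels = nodes), sum, default = 0)
    sb <- tapply(ed$mi, factor(ed$gene_b, levels = nodes), sum, default = 0)
    smi <- as.numeric(sa + sb); names(smi) <- nodes
  }
  ord <- order(-deg, -smi, nodes)
  ranking <- data.frame(gene = nodes[ord], degree = deg[ord],
                        mi_sum = smi[ord], stringsAsFactors = FALSE)
  rownames(ranking) <- NULL
  n_hubs <- as.integer(round_half_up(fraction * length(nodes)))
  n_hubs <- max(n_hubs, 0L)
  hubs <- ranking$gene[seq_len(min(n_hubs, nrow(ranking)))]
  n_hub_edges <- if (nrow(ed))
    sum(ed$gene_a %in% hubs & ed$gene_b %in% hubs) else 0L
  structure(list(hubs = hubs, n_hubs = n_hubs, fraction = fraction,
                 ranking = ranking, n_hub_edges = n_hub_edges),
            class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("Hub set: %d hubs (top %.0f%% of %d nodes), %d hub-hub edges\n",
              x$n_hubs, 100 * x$fraction, nrow(x$ranking), x$n_hub_edges))
  invisible(x)
}
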