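# Expression-side analyses: CPM normalization, differential-expression
# calling at the screen's thresholds (two-fold change, P < 0.05), the
# rank-based FDR formula q = P * n / i, and preranked gene-set enrichment
# against module collections.

#' Counts-per-million normalization
#'
#' Each entry is divided by its sample's library size (column sum) and
#' scaled to one million, so every output column sums to 1e6.
#'
#' @param counts Non-negative genes x samples matrix.
#' @return CPM matrix of the same dimensions.
#' @export
cpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  libs <- colSums(counts)
  zero <- which(libs == 0)
  if (length(zero))
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[zero] %||% zero, collapse = ", "), call. = FALSE)
  sweep(counts, 2, libs, "/") * 1e6
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call differentially expressed genes between two groups
#'
#' Log2 fold changes come from pseudocounted CPM group means (pseudocount
#' 0.5). P-values use a normal approximation on log2-CPM with variances
#' pooled across genes of similar abundance: genes are split into
#' equal-count abundance bins, the within-group variance is averaged per bin
#' (with duplicate designs, a robust spread of the fold changes in the bin
#' substitutes), and each gene's fold change is standardized by the binned
#' variance. Genes passing both \code{|log2FC| >= log2(fc_threshold)} and
#' \code{p < p_threshold} are emitted.
#'
#' @param counts Genes x samples count matrix with column names.
#' @param group_a,group_b Column names or indices of the two groups (each
#'   non-empty; group A is the treatment in the reported fold change).
#' @param fc_threshold Fold-change threshold (default 2).
#' @param p_threshold P-value threshold (default 0.05).
#' @param n_bins Number of abundance bins for variance pooling.
#' @return Data frame with one row per called gene: \code{gene},
#'   \code{log2_fold_change}, \code{p}, \code{q} (from
#'   \code{\link{fdr_adjust}} over all tested genes), \code{direction}.
#' @export
call_degs <- function(counts, group_a, group_b, fc_threshold = 2,
                      p_threshold = 0.05, n_bins = 20) {
  counts <- as.matrix(counts)
  a <- counts[, group_a, drop = FALSE]
  b <- counts[, group_b, drop = FALSE]
  if (!ncol(a) || !ncol(b)) stop("both groups must be non-empty", call. = FALSE)
  lc <- log2(cpm_normalize(cbind(a, b)) + 0.5)
  ia <- seq_len(ncol(a)); ib <- ncol(a) + seq_len(ncol(b))
  ma <- rowMeans(lc[, ia, drop = FALSE])
  mb <- rowMeans(lc[, ib, drop = FALSE])
  lfc <- ma - mb
  abund <- rowMeans(lc)
  n_bins <- max(1L, min(n_bins, floor(nrow(counts) / 10)))
  bin <- .abundance_bins(abund, n_bins)
  na <- ncol(a); nb <- ncol(b)
  dfree <- (na - 1) + (nb - 1)
  if (dfree > 0) {
    va <- apply(lc[, ia, drop = FALSE], 1, stats::var)
    vb <- apply(lc[, ib, drop = FALSE], 1, stats::var)
    if (na < 2) va <- 0
    if (nb < 2) vb <- 0
    pooled <- ((na - 1) * va + (nb - 1) * vb) / dfree
    s2_bin <- tapply(pooled, bin, mean)
    se <- sqrt(s2_bin[bin] * (1 / na + 1 / nb))
  } else {
    # duplicate-free design: spread of fold changes within the abundance bin
    spread <- tapply(lfc, bin, stats::mad)
    se <- pmax(spread[bin], 1e-8)
  }
  se <- pmax(as.numeric(se), 1e-8)
  p <- 2 * stats::pnorm(-abs(lfc) / se)
  q <- fdr_adjust(p)
  genes <- rownames(counts) %||% sprintf("g%04d", seq_len(nrow(counts)))
  pass <- abs(lfc) >= log2(fc_threshold) & p < p_threshold
  out <- data.frame(gene = genes[pass], log2_fold_change = lfc[pass],
                    p = p[pass], q = q[pass],
                    direction = ifelse(lfc[pass] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$p), , drop = FALSE]
}

# equal-count binning robust to ties
.abundance_bins <- function(x, n_bins) {
  if (n_bins <= 1) return(rep(1L, length(x)))
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(n_bins * r / length(x)))
}

#' Rank-based FDR adjustment (q = P * n / i)
#'
#' Computes \eqn{q_i = p_i \cdot n / i} after sorting the p-values
#' ascending (n = number of tests, i = sort rank), maps the values back to
#' the input order, and caps them at 1. By default the literal formula is
#' applied; \code{monotone = TRUE} adds the classical step-up
#' cumulative-minimum correction, making the result identical to
#' Benjamini-Hochberg adjustment.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @param monotone Apply the step-up monotonicity correction (default FALSE).
#' @return Vector of q-values in the input order.
#' @export
fdr_adjust <- function(p_values, monotone = FALSE) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  n <- length(p)
  if (!n) return(numeric(0))
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  if (monotone) q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# weighted KS running-sum enrichment score (weight exponent 1)
.gsea_es <- function(ranked_genes, weights, set) {
  hit <- ranked_genes %in% set
  nh <- sum(hit)
  n <- length(ranked_genes)
  if (nh == 0 || nh == n) return(NA_real_)
  w <- abs(weights)
  wh <- w * hit
  sum_wh <- sum(wh)
  if (sum_wh == 0) wh <- hit / nh else wh <- wh / sum_wh
  p_hit <- cumsum(wh)
  p_miss <- cumsum(!hit) / (n - nh)
  dev <- p_hit - p_miss
  dev[which.max(abs(dev))]
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov running-sum statistic (weight =
#' |score|, exponent 1): genes are ordered by decreasing score, the running
#' sum increments by a hit gene's normalized |score| and decrements by
#' 1/(N - Nh) for misses, and the enrichment score (ES) is the signed
#' maximal deviation. The null is built by drawing random gene sets of the
#' same size from the ranked universe (gene-label permutation); NES divides
#' ES by the mean |null ES| of matching sign and the permutation p-value is
#' one-sided within the matching sign. q-values come from
#' \code{\link{fdr_adjust}} across sets.
#'
#' @param scores Named numeric vector: ranking scores for the whole gene
#'   universe (names are gene identifiers); sorted internally.
#' @param sets Named list of character vectors (gene sets).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param min_size Minimum set size after intersection with the universe;
#'   smaller sets are skipped with a warning.
#' @return Data frame with columns \code{set}, \code{size}, \code{es},
#'   \code{nes}, \code{p}, \code{q}.
#' @export
preranked_gsea <- function(scores, sets, n_perm = 1000, seed = 1, min_size = 5) {
  if (is.null(names(scores))) stop("'scores' must be named by gene", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  ranked <- names(scores)[ord]
  w <- as.numeric(scores)[ord]
  set.seed(as.integer(seed))
  rows <- list()
  for (nm in names(sets)) {
    s <- intersect(sets[[nm]], ranked)
    if (length(s) < min_size) {
      warning("set '", nm, "' has fewer than ", min_size,
              " genes in the universe; skipped", call. = FALSE)
      next
    }
    es <- .gsea_es(ranked, w, s)
    null_es <- vapply(seq_len(n_perm), function(i)
      .gsea_es(ranked, w, sample(ranked, length(s))), numeric(1))
    null_es <- null_es[is.finite(null_es)]
    same <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    p <- if (length(same)) (1 + sum(abs(same) >= abs(es))) / (1 + length(same)) else 1
    rows[[nm]] <- data.frame(set = nm, size = length(s), es = es, nes = nes,
                             p = p, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p = numeric(0), q = numeric(0)))
  out <- do.call(rbind, rows)
  out$q <- fdr_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Number of genes responsive to at least one compound
#'
#' Size of the union of gene identifiers across a list of per-compound DEG
#' tables (data frames with a \code{gene} column, or character vectors).
#'
#' @param deg_tables List of DEG tables.
#' @return Integer count of distinct responsive genes.
#' @export
count_responsive_genes <- function(deg_tables) {
  if (!length(deg_tables)) stop("need at least one DEG table", call. = FALSE)
  genes <- unlist(lapply(deg_tables, function(t)
    if (is.data.frame(t)) t$gene else as.character(t)))
  length(unique(genes))
}
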