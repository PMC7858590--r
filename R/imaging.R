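# Cell segmentation from two-channel images (nucleus + cytoskeleton) and
# per-cell moment eccentricity. Segmentation follows the standard
# high-content recipe: Otsu threshold on the nucleus channel with a
# distance-transform watershed to split touching nuclei, then nucleus-seeded
# region growing over the cytoskeleton foreground to delineate cell bodies.

.relabel <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (!length(u)) return(matrix(0L, nrow(lab), ncol(lab)))
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab > 0] <- match(lab[lab > 0], u)
  out
}

.get_channel <- function(image, i) {
  if (is.list(image)) return(as.matrix(image[[i]]))
  if (length(dim(image)) == 3) return(image[, , i])
  if (i == 1) return(as.matrix(image))
  stop("image must carry two channels (nucleus, cytoskeleton)", call. = FALSE)
}

#' Segment nuclei from the nucleus channel
#'
#' Otsu threshold on the nucleus channel, connected-component labeling,
#' removal of components below \code{min_area}, and a distance-transform
#' watershed to split touching nuclei. A constant channel yields zero labels.
#'
#' @param image Two-channel array (\code{dim = c(rows, cols, 2)}, nucleus
#'   first) as produced by \code{\link{render_well_image}}, or a single
#'   matrix.
#' @param min_area Minimum nucleus area in pixels.
#' @return Integer label matrix; 0 is background, labels are consecutive
#'   from 1.
#' @export
segment_nuclei <- function(image, min_area = 20) {
  nuc <- .get_channel(image, 1)
  if (max(nuc) - min(nuc) < .Machine$double.eps^0.5)
    return(matrix(0L, nrow(nuc), ncol(nuc)))
  th <- EBImage::otsu(EBImage::Image(nuc))
  mask <- nuc > th
  if (!any(mask)) return(matrix(0L, nrow(nuc), ncol(nuc)))
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < min_area)
  if (length(small)) lab[lab %in% small] <- 0
  .relabel(lab)
}

#' Segment cell bodies by nucleus-seeded growth over the cytoskeleton
#'
#' The cytoskeleton channel is thresholded (Otsu) to a foreground mask and
#' nucleus labels are propagated through the mask by seeded watershed/region
#' growing, so each returned cell contains exactly one nucleus seed;
#' foreground unreachable from any seed is discarded and nuclei with no
#' surrounding cytoskeleton signal are dropped.
#'
#' @param nuclei Integer label matrix from \code{\link{segment_nuclei}}.
#' @param image Two-channel array (nucleus, cytoskeleton).
#' @return Integer cell label matrix with consecutive labels.
#' @export
segment_cells <- function(nuclei, image) {
  cyt <- .get_channel(image, 2)
  if (!any(nuclei > 0)) return(matrix(0L, nrow(cyt), ncol(cyt)))
  if (max(cyt) - min(cyt) < .Machine$double.eps^0.5)
    return(matrix(0L, nrow(cyt), ncol(cyt)))
  th <- EBImage::otsu(EBImage::Image(cyt))
  mask <- cyt > th
  seeds <- nuclei
  seeds[!mask] <- 0L   # seeds must lie in the foreground
  if (!any(seeds > 0)) return(matrix(0L, nrow(cyt), ncol(cyt)))
  lab <- EBImage::propagate(EBImage::Image(cyt), seeds = EBImage::Image(seeds),
                            mask = mask, lambda = 1e-4)
  .relabel(EBImage::imageData(lab))
}

# population covariance eigenvalues of a label's pixel coordinates
.region_ecc <- function(rows, cols) {
  n <- length(rows)
  if (n < 2) return(0)
  mr <- mean(rows); mc <- mean(cols)
  crr <- sum((rows - mr)^2) / n
  ccc <- sum((cols - mc)^2) / n
  crc <- sum((rows - mr) * (cols - mc)) / n
  ev <- eigen(matrix(c(crr, crc, crc, ccc), 2, 2), symmetric = TRUE,
              only.values = TRUE)$values
  l1 <- max(ev); l2 <- min(ev)
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

#' Per-cell morphology measurements from a label map
#'
#' For each label the eccentricity of the ellipse with the same second
#' central moments is computed: \eqn{e = \sqrt{1 - \lambda_2/\lambda_1}}
#' where \eqn{\lambda_1 \ge \lambda_2} are the eigenvalues of the 2x2
#' covariance matrix of the label's pixel coordinates (0 for a disc,
#' approaching 1 for a line; defined as 0 for degenerate regions). Regions
#' below \code{min_area} are removed.
#'
#' @param cells Integer label matrix.
#' @param well_id,field_id Identifiers copied into the output.
#' @param min_area Minimum region area in pixels.
#' @return Data frame with one row per retained cell: \code{cell_id},
#'   \code{well_id}, \code{field_id}, \code{x} (column), \code{y} (row),
#'   \code{area_px}, \code{eccentricity}.
#' @export
measure_morphology <- function(cells, well_id = "", field_id = 1L,
                               min_area = 100) {
  labs <- sort(unique(cells[cells > 0]))
  rec <- lapply(labs, function(l) {
    idx <- which(cells == l, arr.ind = TRUE)
    if (nrow(idx) < min_area) return(NULL)
    data.frame(cell_id = l, well_id = well_id, field_id = field_id,
               x = mean(idx[, 2]), y = mean(idx[, 1]),
               area_px = nrow(idx),
               eccentricity = .region_ecc(idx[, 1], idx[, 2]),
               stringsAsFactors = FALSE)
  })
  rec <- rec[!vapply(rec, is.null, logical(1))]
  if (!length(rec))
    return(data.frame(cell_id = integer(0), well_id = character(0),
                      field_id = integer(0), x = numeric(0), y = numeric(0),
                      area_px = integer(0), eccentricity = numeric(0)))
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  out
}
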