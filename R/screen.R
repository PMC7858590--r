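# Plate data model and Z-score hit calling. The screen's "Z-score" is the
# Welch two-sample t statistic comparing a treated well's per-cell
# eccentricities against the pooled DMSO control cells of the same plate row:
# negative Z means cells rounded up (M1-like), positive Z means cells
# elongated (M2-like).

.WELL_ROWS <- LETTERS[1:16]

#' Build a 384-well plate layout
#'
#' Standard geometry: 16 rows (A-P) by 24 columns. The first and last two
#' columns of every row are DMSO controls, pooled per row as the control for
#' that row's 20 treatment wells. Positive-control stimulus wells (classical
#' M1 and M2 stimuli used to calibrate the gold-standard cutoffs) occupy the
#' last treatment positions of the plate; compounds fill treatment wells in
#' row-major order and any left-over treatment wells are marked empty.
#'
#' @param compounds Character vector of compound identifiers, one treatment
#'   well each.
#' @param concentration_um Treatment concentration in uM applied to every
#'   compound well (the primary screen used a single concentration).
#' @param plate_id Plate identifier.
#' @param control_cols Columns with DMSO controls (default c(1, 2, 23, 24)).
#' @param n_pos_m1,n_pos_m2 Number of positive-control wells for the M1 and
#'   M2 stimulus.
#' @return Data frame of class \code{"plate_layout"} with columns
#'   \code{plate_id, well, row, col, role, compound_id, concentration_um};
#'   roles are \code{dmso}, \code{treatment}, \code{positive_m1},
#'   \code{positive_m2}, and \code{empty} for unassigned treatment slots
#'   (left untreated and excluded from scoring).
#' @export
plate_layout <- function(compounds, concentration_um = 20, plate_id = "plate1",
                         control_cols = c(1, 2, 23, 24),
                         n_pos_m1 = 10, n_pos_m2 = 10) {
  stopifnot(all(control_cols %in% 1:24))
  grid <- expand.grid(col = 1:24, row = .WELL_ROWS, stringsAsFactors = FALSE)
  grid <- grid[order(grid$row, grid$col), c("row", "col")]
  layout <- data.frame(
    plate_id = plate_id,
    well = sprintf("%s%02d", grid$row, grid$col),
    row = grid$row, col = grid$col,
    role = "dmso", compound_id = "DMSO", concentration_um = 0,
    stringsAsFactors = FALSE)
  treat_idx <- which(!(layout$col %in% control_cols))
  # unassigned treatment slots stay untreated and take no part in scoring
  layout$role[treat_idx] <- "empty"
  layout$compound_id[treat_idx] <- NA_character_
  n_slots <- length(treat_idx)
  n_pos <- n_pos_m1 + n_pos_m2
  if (length(compounds) > n_slots - n_pos)
    stop("too many compounds: ", length(compounds), " for ",
         n_slots - n_pos, " available treatment wells", call. = FALSE)
  if (length(compounds)) {
    sel <- treat_idx[seq_along(compounds)]
    layout$role[sel] <- "treatment"
    layout$compound_id[sel] <- as.character(compounds)
    layout$concentration_um[sel] <- concentration_um
  }
  if (n_pos_m1 > 0) {
    sel <- treat_idx[n_slots - n_pos + seq_len(n_pos_m1)]
    layout$role[sel] <- "positive_m1"
    layout$compound_id[sel] <- "M1_stimulus"
    layout$concentration_um[sel] <- concentration_um
  }
  if (n_pos_m2 > 0) {
    sel <- treat_idx[n_slots - n_pos_m2 + seq_len(n_pos_m2)]
    layout$role[sel] <- "positive_m2"
    layout$compound_id[sel] <- "M2_stimulus"
    layout$concentration_um[sel] <- concentration_um
  }
  class(layout) <- c("plate_layout", "data.frame")
  layout
}

#' Pool a row's DMSO control cells
#'
#' Concatenates the eccentricities of all cells in the given row's DMSO
#' wells; this pooled sample is the shared control for the row's treatment
#' wells.
#'
#' @param cells Per-cell data frame (columns \code{well}, \code{eccentricity}).
#' @param layout A \code{\link{plate_layout}}.
#' @param row Row letter (\code{"A"}-\code{"P"}).
#' @return Numeric vector of control eccentricities.
#' @export
pool_row_controls <- function(cells, layout, row) {
  dmso_wells <- layout$well[layout$row == row & layout$role == "dmso"]
  pool <- cells$eccentricity[cells$well %in% dmso_wells]
  if (length(pool) < 2)
    stop("no usable DMSO control cells in row ", row, call. = FALSE)
  pool
}

#' Welch Z-score between treated and control cell eccentricities
#'
#' Computes the screen's Z statistic: the Welch two-sample t statistic
#' \eqn{(\bar x_t - \bar x_c) / \sqrt{s_t^2/n_t + s_c^2/n_c}}, positive when
#' treated cells are more elongated than controls.
#'
#' @param treated,control Numeric vectors of per-cell eccentricities, each of
#'   length >= 2.
#' @return List with \code{z}, \code{n_treated}, \code{n_control}.
#' @export
zscore_well <- function(treated, control) {
  nt <- length(treated); nc <- length(control)
  if (nt < 2 || nc < 2)
    stop("both samples need at least 2 cells", call. = FALSE)
  vt <- stats::var(treated); vc <- stats::var(control)
  if (vt + vc == 0)
    stop("degenerate variance: both samples are constant", call. = FALSE)
  z <- (mean(treated) - mean(control)) / sqrt(vt / nt + vc / nc)
  list(z = z, n_treated = nt, n_control = nc)
}

#' Score every non-control well of a plate
#'
#' Applies \code{\link{zscore_well}} to each treatment and positive-control
#' well against its row's pooled DMSO cells. Rows without usable controls
#' are skipped with a warning.
#'
#' @param cells Per-cell data frame (\code{well}, \code{eccentricity}, ...).
#' @param layout A \code{\link{plate_layout}}.
#' @return Data frame with one row per scored well: \code{plate_id, well,
#'   row, col, role, compound_id, concentration_um, n_treated, n_control, z}.
#' @export
score_plate <- function(cells, layout) {
  out <- list()
  for (r in unique(layout$row)) {
    wells_r <- layout[layout$row == r &
                      !(layout$role %in% c("dmso", "empty")), , drop = FALSE]
    if (!nrow(wells_r)) next
    pool <- tryCatch(pool_row_controls(cells, layout, r), error = function(e) {
      warning("skipping row ", r, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(pool)) next
    for (i in seq_len(nrow(wells_r))) {
      w <- wells_r[i, ]
      treated <- cells$eccentricity[cells$well == w$well]
      if (length(treated) < 2) next
      zs <- zscore_well(treated, pool)
      out[[length(out) + 1L]] <- data.frame(
        plate_id = w$plate_id, well = w$well, row = w$row, col = w$col,
        role = w$role, compound_id = w$compound_id,
        concentration_um = w$concentration_um,
        n_treated = zs$n_treated, n_control = zs$n_control, z = zs$z,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Calibrate gold-standard cutoffs from positive-control wells
#'
#' The M1 cutoff is the mean Z over wells treated with the classical M1
#' stimulus and the M2 cutoff the mean Z over M2-stimulus wells (the screen's
#' calibration gave -4 and +6).
#'
#' @param scores Data frame from \code{\link{score_plate}} (or any data frame
#'   with columns \code{role} and \code{z}).
#' @return List of class \code{"cutoff_pair"} with \code{m1_cutoff} and
#'   \code{m2_cutoff}.
#' @export
calibrate_cutoffs <- function(scores) {
  z1 <- scores$z[scores$role == "positive_m1"]
  z2 <- scores$z[scores$role == "positive_m2"]
  if (!length(z1) || !length(z2))
    stop("need at least one positive_m1 and one positive_m2 well", call. = FALSE)
  m1 <- mean(z1); m2 <- mean(z2)
  if (!(m1 < 0 && m2 > 0))
    warning("calibrated cutoffs do not bracket zero (m1 = ",
            signif(m1, 3), ", m2 = ", signif(m2, 3), ")", call. = FALSE)
  structure(list(m1_cutoff = m1, m2_cutoff = m2), class = "cutoff_pair")
}

#' @export
print.cutoff_pair <- function(x, ...) {
  cat(sprintf("Z-score cutoffs: M1 <= %.3f, M2 >= %.3f\n", x$m1_cutoff, x$m2_cutoff))
  invisible(x)
}

#' Call screening hits from Z-scores
#'
#' A well is an M1 hit when \code{z <= m1_cutoff} and an M2 hit when
#' \code{z >= m2_cutoff} (inclusive comparisons); otherwise no call.
#'
#' @param scores Data frame with at least \code{compound_id},
#'   \code{concentration_um} and \code{z}.
#' @param cutoffs A \code{\link{calibrate_cutoffs}} result, or a list with
#'   \code{m1_cutoff < 0 < m2_cutoff}.
#' @return The input data frame with an added \code{call} column
#'   (\code{"M1"}, \code{"M2"} or \code{"none"}).
#' @export
call_hits <- function(scores, cutoffs) {
  stopifnot(is.data.frame(scores), all(c("compound_id", "z") %in% names(scores)))
  if (!(cutoffs$m1_cutoff < 0 && cutoffs$m2_cutoff > 0))
    stop("require m1_cutoff < 0 < m2_cutoff", call. = FALSE)
  scores$call <- ifelse(scores$z <= cutoffs$m1_cutoff, "M1",
                        ifelse(scores$z >= cutoffs$m2_cutoff, "M2", "none"))
  scores
}

#' Reprogramming hits confirmed at two concentrations
#'
#' The reprogramming re-screen tests hit compounds on pre-polarized
#' macrophages at 5 and 10 uM; a compound is retained only when it is called
#' in the expected direction at both concentrations.
#'
#' @param hits_a,hits_b Hit tables from \code{\link{call_hits}} for the two
#'   concentrations; they must cover the same compound set.
#' @param expected_direction \code{"M1"} or \code{"M2"}.
#' @return Sorted character vector of confirmed compound identifiers.
#' @export
reprogramming_hits <- function(hits_a, hits_b, expected_direction = c("M1", "M2")) {
  expected_direction <- match.arg(expected_direction)
  ca <- unique(hits_a$compound_id); cb <- unique(hits_b$compound_id)
  only_a <- setdiff(ca, cb); only_b <- setdiff(cb, ca)
  if (length(only_a) || length(only_b))
    stop("compound sets differ between screens; only in first: ",
         paste(only_a, collapse = ", "), "; only in second: ",
         paste(only_b, collapse = ", "), call. = FALSE)
  hit_a <- unique(hits_a$compound_id[hits_a$call == expected_direction])
  hit_b <- unique(hits_b$compound_id[hits_b$call == expected_direction])
  sort(intersect(hit_a, hit_b))
}
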