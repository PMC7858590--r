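# Synthetic-data generators: cell populations, compound effects, whole screens,
# rendered well images, and expression matrices with planted structure. All
# other modules are testable against the ground truth these functions record.

#' Parameters of a latent two-state cell morphology population
#'
#' Non-activated macrophage cultures are modelled as a mixture of two
#' morphology states: a "round" majority and an "elongated" minority
#' (about 20\% of cells at baseline). Each state's per-cell eccentricity is
#' drawn from a beta distribution parameterized by its mode and a common
#' concentration (dispersion) parameter, so sampled eccentricities always lie
#' in [0, 1).
#'
#' @param fraction_elongated Proportion of cells in the elongated state, in
#'   [0, 1]. Default 0.2 (baseline M0 culture).
#' @param ecc_round_mode Mode of the round state's eccentricity distribution,
#'   in [0, 1).
#' @param ecc_elong_mode Mode of the elongated state's eccentricity
#'   distribution, in [0, 1); must exceed \code{ecc_round_mode}.
#' @param dispersion Beta concentration parameter (> 2); larger values give
#'   tighter per-state distributions.
#' @param cells_per_well_mean Mean number of imaged cells per well (> 0);
#'   realized counts are Poisson around this mean.
#' @return An object of class \code{"population_params"}.
#' @export
population_params <- function(fraction_elongated = 0.2,
                              ecc_round_mode = 0.45,
                              ecc_elong_mode = 0.88,
                              dispersion = 40,
                              cells_per_well_mean = 1000) {
  .check_number(fraction_elongated, "fraction_elongated", 0, 1)
  .check_number(ecc_round_mode, "ecc_round_mode", 0, 1, allow_upper = FALSE)
  .check_number(ecc_elong_mode, "ecc_elong_mode", 0, 1, allow_upper = FALSE)
  .check_number(dispersion, "dispersion", 2, Inf, allow_lower = FALSE)
  .check_number(cells_per_well_mean, "cells_per_well_mean", 0, Inf, allow_lower = FALSE)
  if (ecc_elong_mode <= ecc_round_mode)
    stop("'ecc_elong_mode' must exceed 'ecc_round_mode'", call. = FALSE)
  structure(list(fraction_elongated = fraction_elongated,
                 ecc_round_mode = ecc_round_mode,
                 ecc_elong_mode = ecc_elong_mode,
                 dispersion = dispersion,
                 cells_per_well_mean = cells_per_well_mean),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("Cell population parameters:\n")
  cat(sprintf("  elongated fraction : %.3f\n", x$fraction_elongated))
  cat(sprintf("  eccentricity modes : %.2f (round) / %.2f (elongated), kappa = %g\n",
              x$ecc_round_mode, x$ecc_elong_mode, x$dispersion))
  cat(sprintf("  cells per well     : %g (Poisson mean)\n", x$cells_per_well_mean))
  invisible(x)
}

# beta shape parameters from (mode, concentration); requires kappa > 2
.beta_shapes <- function(mode, kappa) {
  list(shape1 = 1 + mode * (kappa - 2), shape2 = 1 + (1 - mode) * (kappa - 2))
}

#' Analytic mean and variance of the mixture eccentricity distribution
#'
#' Closed-form first two moments of the two-state beta mixture defined by a
#' \code{\link{population_params}} object. Used to predict asymptotic plate
#' Z-scores (see \code{\link{expected_zscore}}) and to calibrate synthetic
#' positive-control stimuli.
#'
#' @param params A \code{population_params} object.
#' @return List with elements \code{mean} and \code{var}.
#' @export
mixture_moments <- function(params) {
  stopifnot(inherits(params, "population_params"))
  f <- params$fraction_elongated
  k <- params$dispersion
  comp <- function(mode) {
    s <- .beta_shapes(mode, k)
    m <- s$shape1 / (s$shape1 + s$shape2)
    v <- s$shape1 * s$shape2 / ((s$shape1 + s$shape2)^2 * (s$shape1 + s$shape2 + 1))
    c(m, v)
  }
  r <- comp(params$ecc_round_mode)
  e <- comp(params$ecc_elong_mode)
  mu <- f * e[1] + (1 - f) * r[1]
  v <- f * e[2] + (1 - f) * r[2] + f * (1 - f) * (e[1] - r[1])^2
  list(mean = mu, var = v)
}

#' Sample per-cell eccentricities from a population
#'
#' Draws \code{n_cells} eccentricities from the two-component mixture: each
#' cell is elongated with probability \code{fraction_elongated}, and its
#' eccentricity comes from the corresponding beta component.
#'
#' @param params A \code{\link{population_params}} object.
#' @param n_cells Number of cells to draw (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of length \code{n_cells}, values in [0, 1).
#' @export
sample_population <- function(params, n_cells, seed = NULL) {
  stopifnot(inherits(params, "population_params"))
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1)
    stop("'n_cells' must be a positive count", call. = FALSE)
  n_cells <- as.integer(n_cells)
  .set_seed_if(seed)
  elong <- stats::runif(n_cells) < params$fraction_elongated
  sr <- .beta_shapes(params$ecc_round_mode, params$dispersion)
  se <- .beta_shapes(params$ecc_elong_mode, params$dispersion)
  ecc <- numeric(n_cells)
  if (any(!elong)) ecc[!elong] <- stats::rbeta(sum(!elong), sr$shape1, sr$shape2)
  if (any(elong)) ecc[elong] <- stats::rbeta(sum(elong), se$shape1, se$shape2)
  pmin(ecc, 1 - 1e-12)
}

#' Define a compound's latent effect on macrophage morphology
#'
#' Compound action is modelled as state switching: a dose-dependent shift of
#' the population's elongated fraction with saturating (Michaelis-Menten)
#' concentration dependence. M1-activating compounds reduce the elongated
#' fraction (cells round up, negative shift); M2-activating compounds
#' increase it; inert compounds have zero maximal shift.
#'
#' @param compound_id Character identifier.
#' @param direction One of \code{"M1"}, \code{"M2"}, \code{"inert"}.
#' @param km_um Concentration (uM) at half-maximal effect (> 0).
#' @param max_shift Maximal signed change of the elongated fraction; must be
#'   negative for M1, positive for M2, and 0 for inert compounds.
#' @return An object of class \code{"compound_effect"}.
#' @export
compound_effect <- function(compound_id, direction = c("M1", "M2", "inert"),
                            km_um = 1, max_shift = 0) {
  direction <- match.arg(direction)
  .check_number(km_um, "km_um", 0, Inf, allow_lower = FALSE)
  .check_number(max_shift, "max_shift", -1, 1)
  if (direction == "inert" && max_shift != 0)
    stop("inert compounds must have max_shift = 0", call. = FALSE)
  if (direction == "M1" && max_shift >= 0)
    stop("M1 compounds must have max_shift < 0", call. = FALSE)
  if (direction == "M2" && max_shift <= 0)
    stop("M2 compounds must have max_shift > 0", call. = FALSE)
  structure(list(compound_id = as.character(compound_id), direction = direction,
                 km_um = km_um, max_shift = max_shift),
            class = "compound_effect")
}

#' Apply a compound effect to a population at a given concentration
#'
#' Shifts the elongated fraction by
#' \code{max_shift * conc / (km_um + conc)}, clamped to [0, 1]; all other
#' population parameters are unchanged.
#'
#' @param params A \code{\link{population_params}} object.
#' @param effect A \code{\link{compound_effect}} object.
#' @param conc_um Concentration in uM (>= 0).
#' @return A new \code{population_params} object.
#' @export
apply_compound <- function(params, effect, conc_um) {
  stopifnot(inherits(params, "population_params"), inherits(effect, "compound_effect"))
  .check_number(conc_um, "conc_um", 0, Inf)
  shift <- effect$max_shift * conc_um / (effect$km_um + conc_um)
  out <- params
  out$fraction_elongated <- min(max(params$fraction_elongated + shift, 0), 1)
  out
}

#' Asymptotic plate Z-score between two populations
#'
#' Analytic value of the Welch statistic comparing \code{n_treated} cells
#' from the treated population against \code{n_control} pooled control cells,
#' using the mixture's closed-form moments (i.e. the large-sample expectation
#' of \code{\link{zscore_well}}).
#'
#' @param params_treated,params_control \code{population_params} objects.
#' @param n_treated,n_control Cell counts entering the comparison.
#' @return A single number.
#' @export
expected_zscore <- function(params_treated, params_control,
                            n_treated = 1000, n_control = 4000) {
  mt <- mixture_moments(params_treated)
  mc <- mixture_moments(params_control)
  (mt$mean - mc$mean) / sqrt(mt$var / n_treated + mc$var / n_control)
}

#' Solve for the fraction shift that attains a target plate Z-score
#'
#' Inverts \code{\link{expected_zscore}} over the elongated-fraction shift:
#' finds the signed shift such that a treated well of \code{n_treated} cells
#' scores \code{z_target} against \code{n_control} control cells drawn from
#' the unshifted population. Used to calibrate synthetic positive-control
#' stimuli to the screen's gold-standard cutoffs.
#'
#' @param params Baseline \code{population_params}.
#' @param z_target Desired asymptotic Z (nonzero).
#' @param n_treated,n_control Cell counts assumed for the comparison.
#' @return The required shift of the elongated fraction.
#' @export
shift_for_target_z <- function(params, z_target, n_treated = 1000, n_control = 4000) {
  .check_number(z_target, "z_target")
  if (z_target == 0) return(0)
  f0 <- params$fraction_elongated
  fn <- function(shift) {
    p <- params
    p$fraction_elongated <- min(max(f0 + shift, 0), 1)
    expected_zscore(p, params, n_treated, n_control) - z_target
  }
  lo <- -f0 + 1e-9
  hi <- 1 - f0 - 1e-9
  if (z_target < 0) hi <- 0 else lo <- 0
  stats::uniroot(fn, c(lo, hi), tol = 1e-10)$root
}

#' Built-in positive-control stimulus effects
#'
#' Returns compound effects for the plate's M1 and M2 positive-control
#' stimuli, with maximal fraction shifts solved so that their asymptotic
#' plate Z-scores equal the targets (defaults -4 and +6, the gold-standard
#' calibration values of the screen). The half-maximal concentration is set
#' far below working concentrations so the stimuli act at saturation.
#'
#' @param params Baseline \code{population_params}.
#' @param z_m1,z_m2 Target asymptotic Z for the M1 / M2 stimulus.
#' @param n_treated,n_control Cell counts assumed for the calibration.
#' @return Named list of two \code{compound_effect} objects
#'   (\code{M1_stimulus}, \code{M2_stimulus}).
#' @export
default_stimulus_effects <- function(params, z_m1 = -4, z_m2 = 6,
                                     n_treated = 1000, n_control = 4000) {
  s1 <- shift_for_target_z(params, z_m1, n_treated, n_control)
  s2 <- shift_for_target_z(params, z_m2, n_treated, n_control)
  list(
    M1_stimulus = compound_effect("M1_stimulus", "M1", km_um = 1e-3, max_shift = s1),
    M2_stimulus = compound_effect("M2_stimulus", "M2", km_um = 1e-3, max_shift = s2)
  )
}

#' Simulate a full screening plate at the per-cell level
#'
#' Every well receives an independently sampled cell population: DMSO wells
#' draw from the baseline population, treatment and positive-control wells
#' from the population shifted by their compound's effect at the well's
#' concentration. Realized cell counts are Poisson around
#' \code{cells_per_well_mean} and cells are assigned to six imaging fields.
#'
#' @param layout A \code{\link{plate_layout}} data frame.
#' @param effects Named list of \code{\link{compound_effect}} objects covering
#'   every non-DMSO compound in the layout.
#' @param params Baseline \code{\link{population_params}}.
#' @param seed Integer seed; per-well sub-seeds are derived deterministically.
#' @return List with \code{cells} (data frame: plate, well, field, cell_id,
#'   x, y, area_px, eccentricity) and \code{truth} (per-well realized latent
#'   state and ground-truth direction labels).
#' @export
simulate_screen <- function(layout, effects, params, seed = 1) {
  stopifnot(is.data.frame(layout), inherits(params, "population_params"))
  if (length(effects)) {
    ids <- vapply(effects, function(e) e$compound_id, character(1))
    names(effects) <- ids
  }
  need <- unique(layout$compound_id[!(layout$role %in% c("dmso", "empty"))])
  missing <- setdiff(need, names(effects))
  if (length(missing))
    stop("no compound_effect supplied for: ", paste(missing, collapse = ", "),
         call. = FALSE)

  cells_list <- vector("list", nrow(layout))
  truth <- layout
  truth$fraction_elongated <- NA_real_
  truth$direction <- "control"
  truth$n_cells <- NA_integer_

  for (i in seq_len(nrow(layout))) {
    w <- layout[i, ]
    p <- params
    dir_i <- "control"
    if (!(w$role %in% c("dmso", "empty"))) {
      eff <- effects[[w$compound_id]]
      p <- apply_compound(params, eff, w$concentration_um)
      dir_i <- eff$direction
    }
    set.seed(derive_seed(seed, i))
    n <- stats::rpois(1, params$cells_per_well_mean)
    if (n > 0) {
      ecc <- sample_population(p, n)
      cells_list[[i]] <- data.frame(
        plate = w$plate_id, well = w$well,
        field = sample.int(6, n, replace = TRUE),
        cell_id = seq_len(n),
        x = stats::runif(n, 0, 2048), y = stats::runif(n, 0, 2048),
        area_px = pmax(100L, as.integer(round(stats::rnorm(n, 2500, 300)))),
        eccentricity = ecc,
        stringsAsFactors = FALSE)
    }
    truth$fraction_elongated[i] <- p$fraction_elongated
    truth$direction[i] <- dir_i
    truth$n_cells[i] <- n
  }
  list(cells = do.call(rbind, cells_list), truth = truth)
}

#' Render a two-channel well image from requested cell shapes
#'
#' Produces a nucleus + cytoskeleton raster: for each requested eccentricity
#' one filled ellipse of the given area is placed at a random position and
#' orientation (rejection sampling guarantees no overlap), with a smaller
#' elliptical nucleus blob at its centroid. Before noise, each ellipse's
#' second-moment eccentricity equals the requested value. Optional Gaussian
#' blur and additive Gaussian noise emulate imaging.
#'
#' @param eccentricities Numeric vector in [0, 1); one cell per value.
#' @param area_px Cell area in pixels (all cells share it).
#' @param image_shape Integer c(rows, cols) of the raster.
#' @param seed Optional integer seed.
#' @param noise_sd Additive Gaussian noise standard deviation (0 disables).
#' @param blur_sigma Gaussian blur sigma in pixels (0 disables).
#' @return Numeric array of dim \code{c(rows, cols, 2)}; slice 1 is the
#'   nucleus channel, slice 2 the cytoskeleton channel, intensities in [0, 1].
#' @export
render_well_image <- function(eccentricities, area_px = 600,
                              image_shape = c(256, 256), seed = NULL,
                              noise_sd = 0.02, blur_sigma = 1) {
  if (length(eccentricities) && (any(eccentricities < 0) || any(eccentricities >= 1)))
    stop("eccentricities must lie in [0, 1)", call. = FALSE)
  .set_seed_if(seed)
  h <- image_shape[1]; wd <- image_shape[2]
  nuc <- matrix(0, h, wd)
  cyt <- matrix(0, h, wd)
  n <- length(eccentricities)
  if (n > 0) {
    # semi-axes from area and eccentricity: area = pi*a*b, b = a*sqrt(1-e^2)
    ratio <- sqrt(1 - eccentricities^2)
    a <- sqrt(area_px / (pi * ratio))
    b <- a * ratio
    centers <- matrix(NA_real_, n, 2)
    radius <- a + 2
    tries <- 0L
    for (i in seq_len(n)) {
      placed <- FALSE
      while (!placed) {
        tries <- tries + 1L
        if (tries > 200L * n)
          stop("could not place ", n, " cells without overlap", call. = FALSE)
        # centers snap to pixel coordinates: subpixel placement adds
        # quantization anisotropy that inflates measured eccentricity near 0
        cand <- round(c(stats::runif(1, radius[i] + 1, h - radius[i] - 1),
                        stats::runif(1, radius[i] + 1, wd - radius[i] - 1)))
        if (i == 1L || all(sqrt(rowSums(sweep(centers[seq_len(i - 1L), , drop = FALSE],
                                              2, cand)^2)) >
                           radius[seq_len(i - 1L)] + radius[i])) {
          centers[i, ] <- cand
          placed <- TRUE
        }
      }
    }
    theta <- stats::runif(n, 0, pi)
    rows <- row(nuc); cols <- col(nuc)
    for (i in seq_len(n)) {
      dr <- rows - centers[i, 1]
      dc <- cols - centers[i, 2]
      u <- dr * cos(theta[i]) + dc * sin(theta[i])
      v <- -dr * sin(theta[i]) + dc * cos(theta[i])
      inside <- (u / a[i])^2 + (v / b[i])^2 <= 1
      cyt[inside] <- 0.7
      nin <- (u / (a[i] / 2.5))^2 + (v / (b[i] / 2.5))^2 <= 1
      nuc[nin] <- 0.8
    }
  }
  if (blur_sigma > 0) {
    nuc <- as.matrix(EBImage::gblur(EBImage::Image(nuc), sigma = blur_sigma))
    cyt <- as.matrix(EBImage::gblur(EBImage::Image(cyt), sigma = blur_sigma))
  }
  if (noise_sd > 0) {
    nuc <- nuc + matrix(stats::rnorm(h * wd, 0, noise_sd), h, wd)
    cyt <- cyt + matrix(stats::rnorm(h * wd, 0, noise_sd), h, wd)
  }
  out <- array(0, dim = c(h, wd, 2), dimnames = list(NULL, NULL,
               c("nucleus", "cytoskeleton")))
  out[, , 1] <- pmin(pmax(nuc, 0), 1)
  out[, , 2] <- pmin(pmax(cyt, 0), 1)
  out
}

#' Simulate a count matrix with planted regulatory hubs
#'
#' Each hub is given a latent activity per sample; the hub gene and its
#' target genes have log-means that follow that activity linearly (targets
#' with additional noise), and all remaining genes are independent. Counts
#' are negative-binomial around the exponentiated means, emulating RNA-seq.
#'
#' @param n_genes Total number of genes.
#' @param n_samples Number of samples (perturbation profiles).
#' @param n_hubs Number of planted hub genes.
#' @param targets_per_hub Targets regulated by each hub;
#'   \code{n_hubs * (targets_per_hub + 1) <= n_genes} is required.
#' @param noise_sd Standard deviation of the target-gene log-scale noise.
#' @param seed Integer seed.
#' @param base_log_mean Baseline natural-log mean count.
#' @param effect_size Log-scale regression coefficient of activity.
#' @param nb_size Negative-binomial size (inverse overdispersion).
#' @return List with \code{counts} (genes x samples integer matrix),
#'   \code{hubs} (character vector of hub gene ids) and \code{targets}
#'   (named list mapping each hub to its target gene ids).
#' @export
simulate_expression <- function(n_genes = 250, n_samples = 120, n_hubs = 5,
                                targets_per_hub = 20, noise_sd = 0.7, seed = 1,
                                base_log_mean = 5, effect_size = 1.5,
                                nb_size = 50) {
  if (n_hubs * (targets_per_hub + 1) > n_genes)
    stop("n_hubs * (targets_per_hub + 1) must not exceed n_genes", call. = FALSE)
  .check_number(noise_sd, "noise_sd", 0, Inf)
  set.seed(as.integer(seed))
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  logmu <- matrix(stats::rnorm(n_genes * n_samples, base_log_mean, 0.3),
                  n_genes, n_samples, dimnames = list(gene_ids, NULL))
  hubs <- character(0); targets <- list()
  if (n_hubs > 0) {
    idx <- 1L
    for (hbi in seq_len(n_hubs)) {
      hub <- gene_ids[idx]
      tg <- gene_ids[idx + seq_len(targets_per_hub)]
      idx <- idx + targets_per_hub + 1L
      act <- stats::rnorm(n_samples)
      logmu[hub, ] <- base_log_mean + effect_size * act
      # alternate activation/repression so the planted cluster leaves
      # library sizes balanced (otherwise CPM induces spurious background
      # correlation through the shared denominator)
      sgn <- rep(c(1, -1), length.out = length(tg))
      for (ti in seq_along(tg))
        logmu[tg[ti], ] <- base_log_mean + sgn[ti] * effect_size * act +
          stats::rnorm(n_samples, 0, noise_sd)
      hubs <- c(hubs, hub)
      targets[[hub]] <- tg
    }
  }
  counts <- matrix(stats::rnbinom(n_genes * n_samples, mu = exp(logmu),
                                  size = nb_size),
                   n_genes, n_samples,
                   dimnames = list(gene_ids, sprintf("s%02d", seq_len(n_samples))))
  list(counts = counts, hubs = hubs, targets = targets)
}

#' Simulate a two-group count matrix with planted differential genes
#'
#' Baseline counts are negative binomial around a common log mean; the first
#' \code{n_deg} genes receive a fold change of \code{2^lfc} in group B
#' (alternating up/down). Used to benchmark differential-expression calling
#' with known truth.
#'
#' @param n_genes Total genes; \code{n_deg} of them are differential.
#' @param n_per_group Samples per group.
#' @param n_deg Number of planted differential genes.
#' @param lfc Absolute log2 fold change of the planted genes.
#' @param seed Integer seed.
#' @param base_log_mean Baseline natural-log mean count.
#' @param nb_size Negative-binomial size parameter.
#' @return List with \code{counts}, \code{group} (factor of "A"/"B"), and
#'   \code{deg_truth} (data frame: gene, direction of change in B vs A).
#' @export
simulate_counts_twogroup <- function(n_genes = 5000, n_per_group = 3,
                                     n_deg = 100, lfc = 2, seed = 1,
                                     base_log_mean = 4, nb_size = 20) {
  set.seed(as.integer(seed))
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  n_samples <- 2L * n_per_group
  base <- stats::rnorm(n_genes, base_log_mean, 0.8)
  logmu <- matrix(base, n_genes, n_samples)
  dir_vec <- rep(c(1, -1), length.out = n_deg)
  in_b <- n_per_group + seq_len(n_per_group)
  if (n_deg > 0)
    logmu[seq_len(n_deg), in_b] <- logmu[seq_len(n_deg), in_b] +
      dir_vec * lfc * log(2)
  counts <- matrix(stats::rnbinom(length(logmu), mu = exp(logmu), size = nb_size),
                   n_genes, n_samples,
                   dimnames = list(gene_ids,
                                   c(sprintf("A%d", seq_len(n_per_group)),
                                     sprintf("B%d", seq_len(n_per_group)))))
  truth <- if (n_deg > 0)
    data.frame(gene = gene_ids[seq_len(n_deg)],
               direction = ifelse(dir_vec > 0, "up", "down"),
               stringsAsFactors = FALSE)
  else data.frame(gene = character(0), direction = character(0))
  list(counts = counts,
       group = factor(rep(c("A", "B"), each = n_per_group)),
       deg_truth = truth)
}
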