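# End-to-end pipeline driver over the synthetic generators, plus the plain
# text readers/writers shared by all stages (CSV for per-cell and plate
# tables, TSV for expression and edge lists, GMT for gene sets).

#' Pipeline configuration with the screen's default parameters
#'
#' Collects every tunable of the pipeline in one list. Defaults follow the
#' published screen: Z cutoffs -4 (M1) and +6 (M2), 20 uM primary screen
#' concentration, 5 and 10 uM reprogramming concentrations, MI significance
#' 1e-7, DPI tolerance 0.1, hub fraction 0.10, two-fold change at P < 0.05
#' for DEGs.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param m1_cutoff,m2_cutoff Z-score hit cutoffs.
#' @param primary_conc_um Primary screen concentration (uM).
#' @param reprogram_concs_um Two re-screen concentrations (uM).
#' @param alpha MI significance level.
#' @param dpi_tolerance DPI tolerance.
#' @param hub_fraction Top fraction of nodes selected as hubs.
#' @param fc_threshold,p_threshold DEG thresholds.
#' @param n_compounds Compounds simulated on the primary screen plate.
#' @param n_active_m1,n_active_m2 Planted true actives per direction.
#' @param ... Overrides for the synthetic generators (passed to
#'   \code{\link{population_params}}).
#' @return List of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(seed = 1, m1_cutoff = -4, m2_cutoff = 6,
                            primary_conc_um = 20, reprogram_concs_um = c(5, 10),
                            alpha = 1e-7, dpi_tolerance = 0.1,
                            hub_fraction = 0.10, fc_threshold = 2,
                            p_threshold = 0.05, n_compounds = 80,
                            n_active_m1 = 8, n_active_m2 = 8, ...) {
  structure(list(seed = seed, m1_cutoff = m1_cutoff, m2_cutoff = m2_cutoff,
                 primary_conc_um = primary_conc_um,
                 reprogram_concs_um = reprogram_concs_um, alpha = alpha,
                 dpi_tolerance = dpi_tolerance, hub_fraction = hub_fraction,
                 fc_threshold = fc_threshold, p_threshold = p_threshold,
                 n_compounds = n_compounds, n_active_m1 = n_active_m1,
                 n_active_m2 = n_active_m2,
                 population = population_params(...)),
            class = "pipeline_config")
}

# planted compound panel: actives at high potency, the rest inert
.demo_effects <- function(config) {
  n <- config$n_compounds
  ids <- sprintf("cmpd%03d", seq_len(n))
  eff <- vector("list", n)
  for (i in seq_len(n)) {
    eff[[i]] <- if (i <= config$n_active_m1)
      compound_effect(ids[i], "M1", km_um = 2, max_shift = -0.3)
    else if (i <= config$n_active_m1 + config$n_active_m2)
      compound_effect(ids[i], "M2", km_um = 2, max_shift = 0.4)
    else compound_effect(ids[i], "inert", km_um = 1, max_shift = 0)
  }
  names(eff) <- ids
  eff
}

#' Run the full synthetic screen pipeline
#'
#' Executes simulate -> score -> calibrate -> call hits -> reprogramming
#' re-screen -> dose-response fits -> MI network and hubs -> DEGs -> GSEA on
#' synthetic data with planted ground truth, writing every stage's table to
#' \code{out_dir} together with a manifest of the parameters used. The run
#' is deterministic: identical config and seed reproduce identical artifact
#' files.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the main in-memory results (scores, hit
#'   table, cutoffs, reprogramming hits, dose fits, network, hubs, DEG
#'   table, GSEA table, and ground truth).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("msrun")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config$population
  effects <- .demo_effects(config)
  stim <- default_stimulus_effects(params, config$m1_cutoff, config$m2_cutoff,
                                   n_treated = params$cells_per_well_mean,
                                   n_control = 4 * params$cells_per_well_mean)
  all_eff <- c(effects, stim)

  # primary screen
  layout <- plate_layout(names(effects), concentration_um = config$primary_conc_um)
  sim <- simulate_screen(layout, all_eff, params, seed = derive_seed(config$seed, 11))
  scores <- score_plate(sim$cells, layout)
  cutoffs <- calibrate_cutoffs(scores)
  hits <- call_hits(scores[scores$role == "treatment", , drop = FALSE], cutoffs)

  # reprogramming re-screen of primary hits at two concentrations
  hit_ids <- unique(hits$compound_id[hits$call != "none"])
  reprog <- list()
  if (length(hit_ids) >= 1) {
    rescreens <- lapply(seq_along(config$reprogram_concs_um), function(k) {
      lay <- plate_layout(hit_ids, concentration_um = config$reprogram_concs_um[k])
      s <- simulate_screen(lay, all_eff, params,
                           seed = derive_seed(config$seed, 20 + k))
      call_hits(score_plate(s$cells, lay), cutoffs)
    })
    reprog <- list(
      m1 = reprogramming_hits(rescreens[[1]], rescreens[[2]], "M1"),
      m2 = reprogramming_hits(rescreens[[1]], rescreens[[2]], "M2"))
  }

  # dose-response of the first active in each direction
  dose_fits <- list()
  doses <- c(0.5, 1, 2, 5, 10, 20)
  for (cid in c(names(effects)[1], names(effects)[config$n_active_m1 + 1])) {
    eff <- effects[[cid]]
    zz <- vapply(seq_along(doses), function(k) {
      p <- apply_compound(params, eff, doses[k])
      set.seed(derive_seed(config$seed, 300 + k))
      treated <- sample_population(p, 1000)
      control <- sample_population(params, 2000)
      zscore_well(treated, control)$z
    }, numeric(1))
    cutoff <- if (eff$direction == "M1") config$m1_cutoff else config$m2_cutoff
    dose_fits[[cid]] <- fit_mm(doses, zz, cutoff = cutoff, compound_id = cid)
  }

  # expression: planted-hub network and two-group DEGs
  ex <- simulate_expression(n_genes = 200, n_samples = 120, n_hubs = 4,
                            targets_per_hub = 15,
                            seed = derive_seed(config$seed, 31))
  net <- build_network(cpm_normalize(ex$counts), alpha = config$alpha,
                       tolerance = config$dpi_tolerance,
                       seed = derive_seed(config$seed, 32))
  hubs <- select_hubs(net, config$hub_fraction)

  tg <- simulate_counts_twogroup(n_genes = 2000, n_per_group = 3, n_deg = 60,
                                 lfc = 2, seed = derive_seed(config$seed, 41))
  degs <- call_degs(tg$counts, which(tg$group == "B"), which(tg$group == "A"),
                    fc_threshold = config$fc_threshold,
                    p_threshold = config$p_threshold)

  # GSEA of the DEG ranking against the planted gene sets
  lc <- log2(cpm_normalize(tg$counts) + 0.5)
  rank_scores <- rowMeans(lc[, tg$group == "B"]) - rowMeans(lc[, tg$group == "A"])
  sets <- list(planted_up = tg$deg_truth$gene[tg$deg_truth$direction == "up"],
               planted_down = tg$deg_truth$gene[tg$deg_truth$direction == "down"])
  gsea <- preranked_gsea(rank_scores, sets, n_perm = 500,
                         seed = derive_seed(config$seed, 42))

  # artifacts
  write_cells_csv(sim$cells, file.path(out_dir, "cells.csv"))
  utils::write.csv(layout, file.path(out_dir, "platemap.csv"), row.names = FALSE)
  utils::write.csv(scores, file.path(out_dir, "zscores.csv"), row.names = FALSE)
  utils::write.csv(hits, file.path(out_dir, "hits.csv"), row.names = FALSE)
  utils::write.csv(sim$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  write_edges_tsv(net$edges, file.path(out_dir, "network.tsv"))
  utils::write.csv(hubs$ranking, file.path(out_dir, "hub_ranking.csv"),
                   row.names = FALSE)
  utils::write.csv(degs, file.path(out_dir, "degs.csv"), row.names = FALSE)
  utils::write.csv(gsea, file.path(out_dir, "gsea.csv"), row.names = FALSE)
  manifest <- c(
    sprintf("seed: %d", config$seed),
    sprintf("m1_cutoff: %g", config$m1_cutoff),
    sprintf("m2_cutoff: %g", config$m2_cutoff),
    sprintf("calibrated_m1: %.6f", cutoffs$m1_cutoff),
    sprintf("calibrated_m2: %.6f", cutoffs$m2_cutoff),
    sprintf("primary_conc_um: %g", config$primary_conc_um),
    sprintf("reprogram_concs_um: %s",
            paste(config$reprogram_concs_um, collapse = ", ")),
    sprintf("alpha: %g", config$alpha),
    sprintf("dpi_tolerance: %g", config$dpi_tolerance),
    sprintf("hub_fraction: %g", config$hub_fraction),
    sprintf("fc_threshold: %g", config$fc_threshold),
    sprintf("p_threshold: %g", config$p_threshold))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  invisible(list(cells = sim$cells, truth = sim$truth, scores = scores,
                 cutoffs = cutoffs, hits = hits, reprogramming = reprog,
                 dose_fits = dose_fits, network = net, hubs = hubs,
                 degs = degs, gsea = gsea, out_dir = out_dir))
}

#' Write / read a per-cell table as CSV
#'
#' Columns: plate, well, field, cell_id, x, y, area_px, eccentricity.
#' @param cells Per-cell data frame.
#' @param path File path.
#' @return \code{read_cells_csv} returns the data frame.
#' @export
write_cells_csv <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read an MI edge list as TSV
#'
#' @param edges Data frame with gene_a, gene_b, mi, p.
#' @param path File path.
#' @return \code{read_edges_tsv} returns the data frame.
#' @export
write_edges_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edges_tsv
#' @export
read_edges_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a genes-by-samples count/CPM matrix as TSV
#'
#' Gene identifiers in the first column, sample identifiers in the header.
#' @param mat Numeric matrix with rownames.
#' @param path File path.
#' @return \code{read_counts_tsv} returns the matrix.
#' @export
write_counts_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read / write gene-set collections in GMT format
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#' @param path File path.
#' @param sets Named list of character vectors.
#' @return \code{read_gmt} returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a rendered two-channel well image as multi-page TIFF
#'
#' Page order: nucleus first, then cytoskeleton.
#' @param image Array of dim c(rows, cols, 2) from
#'   \code{\link{render_well_image}}.
#' @param path File path.
#' @return \code{read_well_tiff} returns the array.
#' @export
write_well_tiff <- function(image, path) {
  img <- EBImage::Image(aperm(image, c(2, 1, 3)))
  EBImage::writeImage(img, path, type = "tiff")
  invisible(path)
}

#' @rdname write_well_tiff
#' @export
read_well_tiff <- function(path) {
  img <- EBImage::readImage(path)
  arr <- aperm(EBImage::imageData(img), c(2, 1, 3))
  dimnames(arr) <- list(NULL, NULL, c("nucleus", "cytoskeleton"))
  arr
}
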