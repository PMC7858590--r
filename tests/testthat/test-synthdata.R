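test_that("sampled populations reproduce the elongated fraction and mixture moments", {
  p <- population_params(fraction_elongated = 0.2)
  n <- 10000
  ecc <- sample_population(p, n, seed = 11)
  # empirical elongated fraction ~ 0.20 within binomial error (3 SE)
  cutpoint <- (p$ecc_round_mode + p$ecc_elong_mode) / 2
  frac <- mean(ecc > cutpoint)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n) + 0.02)
  # analytic mixture mean within 3 standard errors of the empirical mean
  mm <- mixture_moments(p)
  expect_lt(abs(mean(ecc) - mm$mean), 3 * sqrt(mm$var / n))
  expect_lt(abs(var(ecc) - mm$var) / mm$var, 0.1)
  expect_true(all(ecc >= 0 & ecc < 1))
})

test_that("degenerate mixtures and determinism behave as contracted", {
  p0 <- population_params(fraction_elongated = 0)
  e0 <- sample_population(p0, 500, seed = 3)
  expect_lt(mean(e0), p0$ecc_elong_mode)
  expect_identical(sample_population(p0, 100, seed = 7),
                   sample_population(p0, 100, seed = 7))
  expect_error(population_params(fraction_elongated = 1.5), "range")
  expect_error(population_params(dispersion = -1), "range")
  expect_error(population_params(ecc_round_mode = 0.9, ecc_elong_mode = 0.5),
               "exceed")
})

test_that("compound action is a clamped saturating shift of the elongated fraction", {
  p <- population_params()
  eff <- compound_effect("drugA", "M2", km_um = 4, max_shift = 0.4)
  expect_equal(apply_compound(p, eff, 0)$fraction_elongated, p$fraction_elongated)
  expect_equal(apply_compound(p, eff, 4)$fraction_elongated,
               p$fraction_elongated + 0.2)  # half-saturation
  expect_equal(apply_compound(p, eff, 1e9)$fraction_elongated,
               p$fraction_elongated + 0.4, tolerance = 1e-6)
  # monotone in concentration, and sign-symmetric for M1
  concs <- c(0, 0.5, 1, 2, 5, 20, 100)
  fr <- vapply(concs, function(cc) apply_compound(p, eff, cc)$fraction_elongated,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
  m1 <- compound_effect("drugB", "M1", km_um = 2, max_shift = -0.15)
  fr1 <- vapply(concs, function(cc) apply_compound(p, m1, cc)$fraction_elongated,
                numeric(1))
  expect_true(all(diff(fr1) <= 0))
  # clamping at 0
  strong <- compound_effect("drugC", "M1", km_um = 0.1, max_shift = -0.9)
  expect_equal(apply_compound(p, strong, 100)$fraction_elongated, 0)
  expect_error(apply_compound(p, eff, -1), "range")
  expect_error(compound_effect("x", "inert", max_shift = 0.1), "inert")
  expect_error(compound_effect("x", "M1", max_shift = 0.1), "M1")
})

test_that("simulated screens have the requested well occupancy and record truth", {
  p <- population_params(cells_per_well_mean = 1000)
  lay <- plate_layout(sprintf("c%03d", 1:50))
  effects <- c(lapply(1:50, function(i) compound_effect(sprintf("c%03d", i), "inert")),
               default_stimulus_effects(p))
  sim <- simulate_screen(lay, effects, p, seed = 5)
  per_well <- table(sim$cells$well)
  expect_equal(length(per_well), 384)
  # realized mean cells/well within 5% of 1000 over a full plate
  expect_lt(abs(mean(per_well) - 1000) / 1000, 0.05)
  expect_true(all(sim$cells$field %in% 1:6))
  expect_equal(nrow(sim$truth), 384)
  expect_true(all(sim$truth$direction[sim$truth$role == "dmso"] == "control"))
  # missing effect entry errors with the compound named
  expect_error(simulate_screen(lay, effects[-3], p, seed = 5), "c003")
})

test_that("an all-control plate is valid and deterministic", {
  p <- population_params(cells_per_well_mean = 50)
  lay <- plate_layout(character(0), n_pos_m1 = 0, n_pos_m2 = 0)
  sim <- simulate_screen(lay, list(), p, seed = 2)
  expect_true(all(lay$role %in% c("dmso", "empty")))
  expect_equal(sum(lay$role == "dmso"), 64)  # 4 control columns x 16 rows
  expect_gt(nrow(sim$cells), 0)
  sim2 <- simulate_screen(lay, list(), p, seed = 2)
  expect_identical(sim$cells, sim2$cells)
})

test_that("rendered single cells round-trip their eccentricity through measurement", {
  for (ecc in c(0, 0.3, 0.6, 0.9)) {
    img <- render_well_image(ecc, area_px = 2500, image_shape = c(160, 160),
                             seed = 40 + round(10 * ecc),
                             noise_sd = 0, blur_sigma = 0)
    cells <- segment_cells(segment_nuclei(img), img)
    m <- measure_morphology(cells, min_area = 100)
    expect_equal(nrow(m), 1)
    expect_lt(abs(m$eccentricity - ecc), 0.02)
  }
  # with noise and blur a circle still reads as round
  img <- render_well_image(0, area_px = 2500, image_shape = c(160, 160),
                           seed = 9, noise_sd = 0.02, blur_sigma = 1)
  m <- measure_morphology(segment_cells(segment_nuclei(img), img), min_area = 100)
  expect_lt(m$eccentricity[1], 0.15)
  # zero cells -> background only
  blank <- render_well_image(numeric(0), image_shape = c(64, 64), seed = 1,
                             noise_sd = 0, blur_sigma = 0)
  expect_equal(max(segment_nuclei(blank)), 0)
  expect_error(render_well_image(c(0.2, 1.2)), "0, 1")
})

test_that("planted expression hubs dominate their targets' dependence structure", {
  ex <- simulate_expression(n_genes = 60, n_samples = 100, n_hubs = 1,
                            targets_per_hub = 10, noise_sd = 0.05, seed = 21)
  lc <- log2(cpm_normalize(ex$counts) + 0.5)
  hub <- ex$hubs[1]
  tg <- ex$targets[[hub]]
  mi_ht <- vapply(tg, function(g) compute_mi(lc[hub, ], lc[g, ]), numeric(1))
  # MI(hub, target) beats MI between random non-target pairs for all targets
  others <- setdiff(rownames(lc), c(hub, tg))
  set.seed(1)
  null_pairs <- replicate(30, {
    pr <- sample(others, 2)
    compute_mi(lc[pr[1], ], lc[pr[2], ])
  })
  expect_true(all(mi_ht > max(null_pairs)))
  # fixed seed reproducibility
  ex2 <- simulate_expression(n_genes = 60, n_samples = 100, n_hubs = 1,
                             targets_per_hub = 10, noise_sd = 0.05, seed = 21)
  expect_identical(ex$counts, ex2$counts)
  expect_error(simulate_expression(n_genes = 10, n_hubs = 2, targets_per_hub = 10),
               "exceed")
})
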