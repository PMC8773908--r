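# Simulator: cell geometry, molecule sampling statistics, rendering
# physics, and the RNase R / knockdown thinning operators.

test_that("cell generation places disjoint nuclei inside their territories", {
  cfg <- tiny_config(n_cells = 1)
  maps <- generate_cells(cfg)
  expect_identical(sort(setdiff(unique(as.vector(maps$nuclear_labels)), 0L)), 1L)
  expect_identical(sort(setdiff(unique(as.vector(maps$cell_labels)), 0L)), 1L)
  # nucleus strictly inside its cell
  expect_true(all(maps$cell_labels[maps$nuclear_labels == 1L] == 1L))

  # determinism under a pinned seed
  cfg2 <- sim_config(n_cells = 6, field_shape = c(8, 400, 400), rng_seed = 17)
  m1 <- generate_cells(cfg2)
  m2 <- generate_cells(cfg2)
  expect_identical(m1$nuclear_labels, m2$nuclear_labels)
  expect_identical(m1$cell_labels, m2$cell_labels)

  # pairwise disjoint nuclei, checked against the ellipse parameters
  nuc <- m1$nuclei
  for (i in seq_len(nrow(nuc) - 1)) {
    for (j in (i + 1):nrow(nuc)) {
      d <- sqrt((nuc$cy[i] - nuc$cy[j])^2 + (nuc$cx[i] - nuc$cx[j])^2)
      expect_gt(d, max(nuc$a[i], nuc$b[i]) + max(nuc$a[j], nuc$b[j]))
    }
  }
  # every nuclear pixel belongs to the same-id cell territory
  idx <- which(m1$nuclear_labels > 0)
  expect_true(all(m1$cell_labels[idx] == m1$nuclear_labels[idx]))
})

test_that("placement failure on an overcrowded field is reported", {
  expect_error(
    generate_cells(sim_config(n_cells = 50, field_shape = c(4, 120, 120),
                              rng_seed = 1)),
    "field|nuclei"
  )
})

test_that("molecule sampling respects means, compartments and fractions", {
  cfg0 <- tiny_config(mean_counts = c(linear = 0, circular = 0, fragment = 0))
  maps <- generate_cells(cfg0)
  gt0 <- sample_molecules(cfg0, maps)
  expect_identical(nrow(gt0$molecules), 0L)

  # nuclear flags agree with the nuclear mask at the molecule pixel
  cfg <- sim_config(n_cells = 20, field_shape = c(16, 512, 512),
                    mean_counts = c(linear = 50, circular = 10, fragment = 5),
                    rng_seed = 23)
  maps <- generate_cells(cfg)
  gt <- sample_molecules(cfg, maps)
  py <- floor(gt$molecules$y_nm / cfg$voxel_size_nm[2]) + 1
  px <- floor(gt$molecules$x_nm / cfg$voxel_size_nm[3]) + 1
  on_nucleus <- maps$nuclear_labels[cbind(py, px)] > 0
  expect_identical(unname(on_nucleus),
                   gt$molecules$compartment == "nuclear")

  # realised nuclear fraction within 3 binomial SDs of the target 0.25
  lin <- dplyr::filter(gt$molecules, rna_class == "linear")
  p_hat <- mean(lin$compartment == "nuclear")
  tol <- 3 * sqrt(0.25 * 0.75 / nrow(lin))
  expect_lt(abs(p_hat - 0.25), tol)

  # total circular count within 3 Poisson SDs of n_cells * mean
  n_circ <- sum(gt$molecules$rna_class == "circular")
  expect_lt(abs(n_circ - 200), 3 * sqrt(200))
})

test_that("rendering encodes the class-channel contract and PSF photometry", {
  cfg <- tiny_config(mean_counts = c(linear = 0, circular = 0, fragment = 0),
                     background_level = 7, read_noise_sd = 0)
  maps <- generate_cells(cfg)
  st <- render(sample_molecules(cfg, maps), cfg, noise = FALSE)
  expect_true(all(st$channels$PL == 7))
  expect_true(all(st$channels$PC == 7))

  # one linear molecule, no jitter: PL and PC peak at the same voxel
  cfg1 <- sim_config(n_cells = 1, field_shape = c(16, 96, 96),
                     mean_counts = c(linear = 1, circular = 0, fragment = 0),
                     nucleus_axes_px = c(6, 8),
                     registration_sd_nm = 0, background_level = 0,
                     rng_seed = 31)
  maps1 <- generate_cells(cfg1)
  gt1 <- sample_molecules(cfg1, maps1)
  while (nrow(gt1$molecules) != 1) {
    cfg1 <- sim_config(n_cells = 1, field_shape = c(16, 96, 96),
                       mean_counts = c(linear = 1, circular = 0, fragment = 0),
                       nucleus_axes_px = c(6, 8),
                       registration_sd_nm = 0, background_level = 0,
                       rng_seed = cfg1$rng_seed + 1)
    gt1 <- sample_molecules(cfg1, generate_cells(cfg1))
  }
  st1 <- render(gt1, cfg1, noise = FALSE)
  expect_identical(which.max(st1$channels$PL), which.max(st1$channels$PC))

  # integrated intensity matches the analytic Gaussian integral within 1%
  cfg2 <- sim_config(field_shape = c(16, 128, 128), background_level = 0,
                     rng_seed = 2)
  gt2 <- withr::with_seed(8, uniform_ground_truth(
    c(circular = 20), cfg2, min_separation_nm = 1500,
    margin_nm = c(z = 1050, xy = 800)
  ))
  st2 <- render(gt2, cfg2, noise = FALSE)
  sig <- c(350, 170, 170)
  expected <- 20 * cfg2$spot_amplitude *
    prod(sqrt(2 * pi) * sig / cfg2$voxel_size_nm)
  expect_lt(abs(sum(st2$channels$PC) / expected - 1), 0.01)
  # circular molecules do not render in PL
  expect_true(all(st2$channels$PL == 0))

  # bit-exact reproducibility of the full scene under a pinned seed
  cfgr <- tiny_config()
  s1 <- simulate_scene(cfgr)
  s2 <- simulate_scene(cfgr)
  expect_identical(s1$ground_truth$molecules, s2$ground_truth$molecules)
  expect_identical(s1$stack$channels, s2$stack$channels)
})

test_that("RNase R thinning follows exponential survival and is monotone", {
  cfg <- sim_config(n_cells = 10, field_shape = c(8, 512, 512),
                    mean_counts = c(linear = 100, circular = 100, fragment = 0),
                    rng_seed = 41)
  gt <- sample_molecules(cfg, generate_cells(cfg))
  expect_error(apply_rnase_r(gt, -1), "t_hours")

  # t = 0 keeps everything
  expect_identical(nrow(apply_rnase_r(gt, 0, seed = 1)$molecules),
                   nrow(gt$molecules))

  # linear survival 2^-4 at 4 h with a 1 h half-life (3 binomial SDs)
  n_lin <- sum(gt$molecules$rna_class == "linear")
  surv <- apply_rnase_r(gt, 4, linear_half_life_h = 1, seed = 9)
  k <- sum(surv$molecules$rna_class == "linear")
  p <- 2^-4
  expect_lt(abs(k - n_lin * p), 3 * sqrt(n_lin * p * (1 - p)) + 1)

  # circular survival 2^-0.5 at 24 h with a 48 h half-life
  n_circ <- sum(gt$molecules$rna_class == "circular")
  k2 <- sum(apply_rnase_r(gt, 24, circular_half_life_h = 48,
                          seed = 9)$molecules$rna_class == "circular")
  p2 <- 2^-0.5
  expect_lt(abs(k2 - n_circ * p2), 3 * sqrt(n_circ * p2 * (1 - p2)))

  # same draws: survivors at a later time nest inside earlier survivors
  s2h <- apply_rnase_r(gt, 2, seed = 77)$molecules$molecule_id
  s6h <- apply_rnase_r(gt, 6, seed = 77)$molecules$molecule_id
  expect_true(all(s6h %in% s2h))
})

test_that("knockdown removes only the target class at the set efficiency", {
  cfg <- sim_config(n_cells = 10, field_shape = c(8, 512, 512),
                    mean_counts = c(linear = 50, circular = 100, fragment = 5),
                    rng_seed = 43)
  gt <- sample_molecules(cfg, generate_cells(cfg))
  tab <- table(gt$molecules$rna_class)

  # efficiency 0 is the identity
  expect_identical(apply_knockdown(gt, "circular", 0, seed = 1)$molecules,
                   gt$molecules)

  # efficiency 1 removes the class entirely, leaves the others untouched
  kd1 <- apply_knockdown(gt, "circular", 1, seed = 1)
  expect_identical(sum(kd1$molecules$rna_class == "circular"), 0L)
  expect_identical(sum(kd1$molecules$rna_class == "linear"),
                   as.integer(tab[["linear"]]))

  # efficiency 0.8: survivors within 3 binomial SDs of 20%
  n <- as.integer(tab[["circular"]])
  k <- sum(apply_knockdown(gt, "circular", 0.8,
                           seed = 5)$molecules$rna_class == "circular")
  expect_lt(abs(k - 0.2 * n), 3 * sqrt(n * 0.2 * 0.8))
})

test_that("idealised spot tables respect the class-channel contract", {
  cfg <- tiny_config()
  sc <- simulate_scene(cfg, render_stack = FALSE)
  tabs <- withr::with_seed(1, simulate_spot_tables(sc$ground_truth))
  mol <- sc$ground_truth$molecules
  expect_identical(nrow(tabs$PL),
                   sum(mol$rna_class %in% c("linear", "fragment")))
  expect_identical(nrow(tabs$PC),
                   sum(mol$rna_class %in% c("linear", "circular")))
  # PL positions are exact molecule positions; PC are jittered
  expect_true(all(tabs$PL$z_nm %in% mol$z_nm))
  expect_false(any(tabs$PC$z_nm %in% mol$z_nm))
})
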