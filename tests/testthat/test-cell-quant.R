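# Quantification: segmentation fidelity, spot assignment, per-cell
# conservation, the pooled t-test summary, and localisation fractions.

test_that("nuclear segmentation recovers simulated nuclei almost perfectly", {
  cfg <- sim_config(n_cells = 10, field_shape = c(8, 400, 400),
                    mean_counts = c(linear = 20, circular = 10, fragment = 3),
                    rng_seed = 9)
  sc <- simulate_scene(cfg, noise = FALSE)
  seg <- segment_nuclei(sc$stack)
  expect_identical(max(seg$nuclear_labels), 10L)
  # Jaccard of each true nucleus against its best segmented counterpart
  for (i in 1:10) {
    ti <- sc$maps$nuclear_labels == i
    lab <- seg$nuclear_labels[ti]
    j <- as.integer(names(sort(table(lab[lab > 0]), decreasing = TRUE))[1])
    si <- seg$nuclear_labels == j
    expect_gte(sum(ti & si) / sum(ti | si), 0.99)
  }
  # nuclei sit inside their own cell territory
  idx <- which(seg$nuclear_labels > 0)
  expect_true(all(seg$cell_labels[idx] == seg$nuclear_labels[idx]))

  # blank DAPI errors
  expect_error(segment_nuclei(array(3, c(4, 64, 64))), "nuclei")
})

test_that("touching-free nuclei at small separation are split into 2 labels", {
  img <- matrix(0, 120, 120)
  yy <- row(img); xx <- col(img)
  img[((yy - 40)^2 / 15^2 + (xx - 60)^2 / 12^2) <= 1] <- 100
  img[((yy - 75)^2 / 12^2 + (xx - 60)^2 / 15^2) <= 1] <- 100 # 5 px gap
  seg <- segment_nuclei(img)
  expect_identical(max(seg$nuclear_labels), 2L)
})

test_that("spot assignment reads cell and compartment off the label maps", {
  cfg <- tiny_config()
  sc <- simulate_scene(cfg, render_stack = FALSE)
  maps <- sc$maps
  # a nuclear pixel of cell 1 and a background corner
  i <- which(maps$nuclear_labels == 1L)[1]
  py <- ((i - 1) %% nrow(maps$nuclear_labels)) + 1
  px <- ((i - 1) %/% nrow(maps$nuclear_labels)) + 1
  spots <- tibble::tibble(
    class = c("linear", "circular"),
    z_nm = c(0, 0),
    y_nm = c((py - 0.5) * 130, 0.5 * 130),
    x_nm = c((px - 0.5) * 130, 0.5 * 130)
  )
  out <- assign_spots(spots, maps)
  expect_identical(out$cell_id[1], 1L)
  expect_identical(out$compartment[1], "nuclear")
  expect_true(is.na(out$cell_id[2]))
  expect_false(out$assigned[2])

  # ground-truth molecules reassign to their true cell and compartment
  asp <- molecules_as_spots(sc$ground_truth)
  re <- assign_spots(asp, maps)
  expect_identical(re$cell_id, asp$cell_id)
  expect_identical(re$compartment, asp$compartment)
})

test_that("per-cell counts include empty cells and conserve totals", {
  spots <- tibble::tibble(
    class = c(rep("linear", 5), rep("circular", 3)),
    cell_id = 1L,
    compartment = c(rep("nuclear", 2), rep("cytoplasmic", 3),
                    rep("nuclear", 1), rep("cytoplasmic", 2))
  )
  counts <- per_cell_counts(spots)
  expect_equal(counts$n[counts$class == "linear"], 5L)
  expect_equal(counts$n[counts$class == "circular"], 3L)
  expect_equal(counts$n[counts$class == "fragment"], 0L)
  expect_equal(counts$n_nuclear[counts$class == "linear"], 2L)
  expect_true(is.na(counts$nuclear_fraction[counts$class == "fragment"]))

  # conservation on a simulated scene, including zero-count cells
  cfg <- sim_config(n_cells = 8, field_shape = c(8, 420, 420),
                    mean_counts = c(linear = 20, circular = 5, fragment = 1),
                    rng_seed = 15)
  sc <- simulate_scene(cfg, render_stack = FALSE)
  asp <- molecules_as_spots(sc$ground_truth)
  counts <- per_cell_counts(asp, maps = sc$maps, exclude_border = FALSE)
  expect_identical(dplyr::n_distinct(counts$cell_id), 8L)
  expect_identical(sum(counts$n), nrow(asp))
  per_class <- counts |>
    dplyr::group_by(class) |>
    dplyr::summarise(n = sum(n))
  truth <- table(asp$class)
  for (k in names(truth)) {
    expect_identical(per_class$n[per_class$class == k],
                     as.integer(truth[[k]]))
  }
  expect_true(all(counts$n_nuclear <= counts$n))

  # sample mean within the 95% CI of the Poisson mean
  cfg2 <- sim_config(n_cells = 100, field_shape = c(8, 1200, 1200),
                     mean_counts = c(linear = 20, circular = 0, fragment = 0),
                     rng_seed = 27)
  sc2 <- simulate_scene(cfg2, render_stack = FALSE)
  counts2 <- per_cell_counts(molecules_as_spots(sc2$ground_truth),
                             maps = sc2$maps, exclude_border = FALSE)
  lin <- dplyr::filter(counts2, class == "linear")
  expect_lt(abs(mean(lin$n) - 20), 1.96 * sqrt(20 / 100))
})

test_that("condition summary computes pooled t-tests with star codes", {
  mk <- function(n, cls = "linear") tibble::tibble(
    cell_id = seq_along(n), class = cls, n = n,
    n_nuclear = 0L, nuclear_fraction = ifelse(n > 0, 0, NA_real_)
  )
  # a condition against itself: t = 0, p = 1, ns
  counts <- bind_conditions(list(a = mk(c(5, 6, 7, 8)), b = mk(c(5, 6, 7, 8))))
  s <- suppressWarnings(summarize_conditions(counts))
  cmp <- tidy(s, "comparisons")
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_identical(cmp$stars, "ns")

  # hand data, frozen from the pooled-variance formula (and cross-checked
  # against the textbook oracle): t = -10.954, p < 0.001
  a <- c(10, 12, 11, 13)
  b <- c(20, 22, 21, 23)
  s2 <- suppressWarnings(summarize_conditions(
    bind_conditions(list(A = mk(a), B = mk(b)))
  ))
  cmp2 <- tidy(s2, "comparisons")
  expect_equal(cmp2$t_statistic, -10.9545, tolerance = 1e-4)
  expect_equal(cmp2$t_statistic, oracle_pooled_t(a, b), tolerance = 1e-10)
  expect_lt(cmp2$p_value, 0.001)
  expect_identical(cmp2$stars, "***")

  # the stats side carries the 1.96 * SEM half-width
  st <- tidy(s2, "stats")
  expect_equal(st$ci95_halfwidth[st$condition == "A"],
               1.96 * sd(a) / sqrt(4))

  # under-n conditions warn; n < 2 skips the test
  expect_warning(summarize_conditions(
    bind_conditions(list(A = mk(1:5), B = mk(2:6)))
  ), class = "circfish_few_cells")
  expect_warning(suppressWarnings(
    summarize_conditions(bind_conditions(list(A = mk(3), B = mk(1:4))),
                         min_cells = 1),
    classes = "circfish_few_cells"
  ), class = "circfish_ttest_skipped")

  # glance gives the one-row overview
  g <- glance(s2)
  expect_identical(g$n_conditions, 2L)
  expect_identical(g$n_significant, 1L)
})

test_that("t.test-based comparisons equal the pooled formula on random data", {
  withr::with_seed(5, {
    for (rep in 1:100) {
      a <- rnorm(sample(3:12, 1), mean = 10, sd = 2)
      b <- rnorm(sample(3:12, 1), mean = runif(1, 8, 12), sd = 2)
      tt <- t.test(a, b, var.equal = TRUE)
      expect_equal(unname(tt$statistic), oracle_pooled_t(a, b),
                   tolerance = 1e-6)
    }
  })
})

test_that("localisation fractions recover the simulated compartment split", {
  # all nuclear: fraction exactly 1
  spots <- tibble::tibble(class = "linear", cell_id = rep(1:3, each = 2),
                          compartment = "nuclear")
  fr <- localization_fractions(per_cell_counts(spots))
  expect_equal(fr$nuclear_fraction[fr$class == "linear"], 1)
  expect_true(is.na(fr$nuclear_fraction[fr$class == "circular"]))
  expect_equal(fr$cytoplasmic_fraction[fr$class == "linear"], 0)

  # simulated 0.25 / 0.50 split over 100 cells, recovered within the CI
  cfg <- scenario_config(n_cells = 100, rng_seed = 37)
  sc <- simulate_scene(cfg, render_stack = FALSE)
  counts <- per_cell_counts(molecules_as_spots(sc$ground_truth),
                            maps = sc$maps, exclude_border = FALSE)
  fr2 <- localization_fractions(counts)
  lin <- fr2[fr2$class == "linear", ]
  circ <- fr2[fr2$class == "circular", ]
  expect_lt(abs(lin$nuclear_fraction - 0.25), lin$ci95_halfwidth)
  expect_lt(abs(circ$nuclear_fraction - 0.50), circ$ci95_halfwidth)
  expect_equal(lin$cytoplasmic_fraction, 1 - lin$nuclear_fraction)
})
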