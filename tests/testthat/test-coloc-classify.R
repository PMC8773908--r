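# Colocalization: greedy one-to-one matching against a maximum-matching
# oracle, the 250 nm boundary, classification identities, and multiplexing.

test_that("matching honours the inclusive 250 nm boundary and picks nearest", {
  # identical coordinate lists: everything matches at distance 0
  A <- withr::with_seed(1, matrix(runif(30, 0, 5000), 10))
  m <- match_spots(as_spots(A), as_spots(A))
  expect_identical(nrow(m$pairs), 10L)
  expect_true(all(m$pairs$distance_nm == 0))
  expect_identical(m$pairs$pl, m$pairs$pc)

  # 251 nm apart: no pair; exactly 250 nm: a pair (inclusive radius)
  far <- match_spots(as_spots(matrix(c(0, 0, 0), 1)),
                     as_spots(matrix(c(0, 0, 251), 1)))
  expect_identical(nrow(far$pairs), 0L)
  expect_identical(far$unmatched_pl, 1L)
  expect_identical(far$unmatched_pc, 1L)
  at <- match_spots(as_spots(matrix(c(0, 0, 0), 1)),
                    as_spots(matrix(c(0, 0, 250), 1)))
  expect_identical(nrow(at$pairs), 1L)

  # one PL, two PC candidates: greedy takes the nearer one (brute force
  # over both assignments agrees)
  m2 <- match_spots(as_spots(matrix(c(0, 0, 0), 1)),
                    as_spots(rbind(c(0, 0, 100), c(0, 0, 200))))
  expect_identical(m2$pairs$pc, 1L)
  expect_identical(m2$unmatched_pc, 2L)
  expect_equal(m2$pairs$distance_nm, 100)
})

test_that("one-to-one matching never repeats an index and grows with radius", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      A <- matrix(runif(3 * sample(0:15, 1), 0, 2000), ncol = 3)
      B <- matrix(runif(3 * sample(0:15, 1), 0, 2000), ncol = 3)
      sizes <- vapply(c(100, 250, 500, 1000), function(r) {
        m <- match_spots(as_spots(A), as_spots(B), radius_nm = r)
        expect_identical(anyDuplicated(m$pairs$pl), 0L)
        expect_identical(anyDuplicated(m$pairs$pc), 0L)
        # partition property
        expect_setequal(c(m$pairs$pl, m$unmatched_pl), seq_len(nrow(A)))
        expect_setequal(c(m$pairs$pc, m$unmatched_pc), seq_len(nrow(B)))
        expect_true(all(m$pairs$distance_nm <= r))
        nrow(m$pairs)
      }, numeric(1))
      expect_true(all(diff(sizes) >= 0))
    }
  })
})

test_that("greedy matching attains the maximum-matching oracle bound", {
  withr::with_seed(11, {
    ratios <- numeric(0)
    for (rep in 1:200) {
      nA <- sample(1:20, 1)
      nB <- sample(1:20, 1)
      A <- matrix(runif(3 * nA, 0, 1500), ncol = 3)
      B <- matrix(runif(3 * nB, 0, 1500), ncol = 3)
      m <- match_spots(as_spots(A), as_spots(B))
      hits <- pairs_within(A, B, 250)
      adj <- lapply(seq_len(nA), function(i) hits[hits[, 1] == i, 2])
      opt <- oracle_max_matching(adj, nB)
      expect_lte(nrow(m$pairs), opt)
      if (opt > 0) ratios <- c(ratios, nrow(m$pairs) / opt)
      # greedy is exactly optimal when every spot has <= 1 candidate
      if (max(table(factor(hits[, 1], seq_len(nA)))) <= 1 &&
          max(table(factor(hits[, 2], seq_len(nB)))) <= 1) {
        expect_identical(nrow(m$pairs), opt)
      }
    }
    expect_gte(mean(ratios), 0.95)
  })
})

test_that("classification preserves the channel conservation identities", {
  # all coincident: everything is linear
  A <- withr::with_seed(2, matrix(runif(30, 0, 4000), 10))
  cl <- classify_spots(as_spots(A), as_spots(A))
  expect_equal(unname(class_counts(cl)), c(10, 0, 0))

  # no PL spots: everything PC is circular (the RNase-R multiplex regime)
  cl2 <- classify_spots(as_spots(matrix(numeric(0), 0, 3)),
                        as_spots(A[1:7, ]))
  expect_equal(unname(class_counts(cl2)), c(0, 7, 0))

  # random instances: |linear| + |circular| = #PC, |linear| + |fragment| = #PL
  withr::with_seed(3, {
    for (rep in 1:10) {
      A <- matrix(runif(3 * sample(1:25, 1), 0, 2500), ncol = 3)
      B <- matrix(runif(3 * sample(1:25, 1), 0, 2500), ncol = 3)
      cc <- class_counts(classify_spots(as_spots(A), as_spots(B)))
      expect_identical(unname(cc["linear"] + cc["circular"]),
                       as.integer(nrow(B)))
      expect_identical(unname(cc["linear"] + cc["fragment"]),
                       as.integer(nrow(A)))
    }
  })

  # linear position is the pair midpoint
  one <- classify_spots(as_spots(matrix(c(0, 0, 0), 1)),
                        as_spots(matrix(c(0, 0, 100), 1)))
  expect_equal(one$x_nm[1], 50)
  expect_equal(one$pair_distance_nm[1], 100)

  # inconsistent match objects are rejected
  m <- match_spots(as_spots(A[1:3, , drop = FALSE]),
                   as_spots(A[1:3, , drop = FALSE]))
  expect_error(classify_spots(as_spots(A[1:2, , drop = FALSE]),
                              as_spots(A[1:3, , drop = FALSE]), match = m),
               "inconsistent")
})

test_that("a sub-resolution-density scene is classified exactly", {
  cfg <- sim_config(n_cells = 1, field_shape = c(16, 300, 300),
                    nucleus_axes_px = c(14, 18), dilation_factor = 2.8,
                    min_separation_nm = 600, rng_seed = 21)
  sc <- simulate_scene(cfg, render_stack = FALSE)
  tabs <- withr::with_seed(1, simulate_spot_tables(sc$ground_truth))
  cc <- class_counts(classify_spots(tabs$PL, tabs$PC))
  truth <- table(factor(sc$ground_truth$molecules$rna_class,
                        c("linear", "circular", "fragment")))
  expect_equal(unname(cc), as.vector(truth))
})

test_that("many-to-one mode pairs every spot with an in-radius counterpart", {
  # two PL spots share one PC neighbour: one-to-one leaves a fragment,
  # many-to-one colocalizes both
  pl <- as_spots(rbind(c(0, 0, 0), c(0, 0, 120)))
  pc <- as_spots(matrix(c(0, 0, 60), 1))
  m1 <- match_spots(pl, pc)
  expect_identical(nrow(m1$pairs), 1L)
  m2 <- match_spots(pl, pc, one_to_one = FALSE)
  expect_identical(nrow(m2$pairs), 2L)
  expect_identical(length(m2$unmatched_pc), 0L)
})

test_that("multiplex counting is per channel with bleed-through warnings", {
  A <- withr::with_seed(4, matrix(runif(45, 0, 20000), 15))
  B <- A + 5000 # disjoint, far away
  out <- multiplex_counts(list(circA = as_spots(A), circB = as_spots(B)))
  expect_equal(out$n_spots, c(15, 15))
  expect_equal(out$n_bleed_warnings, c(0, 0))

  # identical lists: every spot is flagged, once per channel
  w <- capture_warnings(
    out2 <- multiplex_counts(list(circA = as_spots(A), circB = as_spots(A)))
  )
  expect_length(w, 2)
  expect_match(w, "bleed-through", all = TRUE)
  expect_equal(out2$n_bleed_warnings, c(15, 15))

  # per-cell means recovered across cells for two simulated circRNA panels
  cfg <- sim_config(n_cells = 40, field_shape = c(16, 1000, 1000),
                    mean_counts = c(linear = 0, circular = 15, fragment = 0),
                    rng_seed = 61)
  maps <- generate_cells(cfg)
  gt1 <- sample_molecules(cfg, maps)
  cfg2 <- sim_config(n_cells = 40, field_shape = c(16, 1000, 1000),
                     mean_counts = c(linear = 0, circular = 8, fragment = 0),
                     rng_seed = 62)
  gt2 <- sample_molecules(cfg2, maps)
  panel <- multiplex_counts(list(
    circZNF609 = dplyr::select(gt1$molecules, z_nm, y_nm, x_nm),
    circCSNK1G3 = dplyr::select(gt2$molecules, z_nm, y_nm, x_nm)
  ), check_bleed = FALSE)
  n_cells <- 40
  for (i in 1:2) {
    mu <- c(15, 8)[i]
    mean_hat <- panel$n_spots[i] / n_cells
    ci <- 1.96 * sqrt(mu / n_cells) # Poisson SE of the per-cell mean
    expect_lt(abs(mean_hat - mu), ci)
  }
})
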