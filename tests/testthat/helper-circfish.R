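# Shared fixtures and independent oracles for the test suite.

# small, fast scene configuration
tiny_config <- function(...) {
  args <- list(
    n_cells = 2, field_shape = c(16, 160, 160),
    mean_counts = c(linear = 10, circular = 5, fragment = 2),
    nucleus_axes_px = c(7, 10), rng_seed = 42, ...
  )
  args <- args[!duplicated(names(args), fromLast = TRUE)]
  do.call(sim_config, args)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force greedy tiling oracle: independent re-implementation used to
# freeze expected counts (no GC filter)
oracle_tile_count <- function(L, probe_len, gap) {
  count <- 0L
  cursor <- 0L
  while (cursor + probe_len <= L) {
    count <- count + 1L
    cursor <- cursor + probe_len + gap
  }
  count
}

# maximum-cardinality bipartite matching by augmenting paths (oracle for
# the greedy matcher); adj: list over PL of PC candidate indices
oracle_max_matching <- function(adj, n_pc) {
  match_pc <- rep(0L, n_pc)
  try_augment <- function(u, seen) {
    for (v in adj[[u]]) {
      if (!seen[v]) {
        seen[v] <- TRUE
        if (match_pc[v] == 0L || Recall(match_pc[v], seen)) {
          match_pc[v] <<- u
          return(TRUE)
        }
      }
    }
    FALSE
  }
  size <- 0L
  for (u in seq_along(adj)) {
    seen <- rep(FALSE, n_pc)
    if (length(adj[[u]]) && try_augment(u, seen)) size <- size + 1L
  }
  size
}

# textbook pooled-variance two-sample t statistic (oracle for t.test)
oracle_pooled_t <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# greedy matched-pair count on raw coordinate matrices (m x 3), oracle-side
pairs_within <- function(A, B, radius) {
  if (nrow(A) == 0 || nrow(B) == 0) return(matrix(numeric(0), 0, 2))
  d <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2 +
    outer(A[, 3], B[, 3], "-")^2
  which(d <= radius^2, arr.ind = TRUE)
}

as_spots <- function(m) {
  tibble::tibble(z_nm = m[, 1], y_nm = m[, 2], x_nm = m[, 3])
}
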