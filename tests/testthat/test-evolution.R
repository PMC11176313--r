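test_that("non-dominated sorting matches hand cases and handles edge cases", {
  pts <- rbind(c(1, 2), c(2, 1), c(3, 3))
  expect_equal(non_dominated_sort(pts), list(c(1L, 2L), 3L))

  expect_equal(non_dominated_sort(matrix(c(1, 2), 1)), list(1L))
  expect_equal(non_dominated_sort(matrix(0, 0, 2)), list())

  same <- matrix(1, 5, 2)
  expect_equal(non_dominated_sort(same), list(1:5))
})

test_that("non-dominated sorting agrees with the brute-force oracle", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(2:50, 1)
    m <- sample(1:3, 1)
    pts <- matrix(sample(1:8, n * m, replace = TRUE), n, m)
    expect_identical(lapply(non_dominated_sort(pts), sort),
                     lapply(brute_fronts(pts), sort))
  }
})

test_that("crowding distance follows the standard formula", {
  two <- rbind(c(0, 1), c(1, 0))
  expect_equal(crowding_distance(two), c(Inf, Inf))

  col3 <- rbind(c(0, 2), c(1, 1), c(2, 0))
  expect_equal(crowding_distance(col3), c(Inf, 2, Inf))

  dup <- rbind(c(1, 1), c(1, 1), c(1, 1))
  d <- crowding_distance(dup)
  expect_true(all(is.finite(d) | is.infinite(d)))
  expect_true(all(d >= 0))
  expect_false(any(is.nan(d)))
})

test_that("block crossover inherits whole tiles at a fair rate", {
  params <- tiny_params()
  pa <- init_pattern(params, seed = 1)
  pb <- init_pattern(params, seed = 2)

  # identical parents reproduce the parent (up to renormalization = exact
  # here since the parent already has unit spectral radius)
  set.seed(1)
  same <- crossover(pa, pa, 2)
  expect_equal(same$W, pa$W, tolerance = 1e-12)

  # tile-wise audit: every 2x2 tile equals one parent's tile
  set.seed(2)
  child <- crossover(pa, pb, 2, normalize = FALSE)
  from_a <- 0; total <- 0
  for (ti in seq_len(24)) {
    for (tj in seq_len(24)) {
      rows <- (2 * ti - 1):(2 * ti); cols <- (2 * tj - 1):(2 * tj)
      ca <- identical(child$W[rows, cols], pa$W[rows, cols])
      cb <- identical(child$W[rows, cols], pb$W[rows, cols])
      expect_true(ca || cb)
      total <- total + 1
      if (ca && !cb) from_a <- from_a + 1
    }
  }

  # inheritance rate ~50%, counted over tiles where the parents differ
  # (tiles identical in both parents, e.g. all-zero ones, are ambiguous)
  set.seed(3)
  counts <- replicate(20, {
    ch <- crossover(pa, pb, 2, normalize = FALSE)
    n_a <- 0; n_resolved <- 0
    for (ti in seq_len(24)) for (tj in seq_len(24)) {
      rows <- (2 * ti - 1):(2 * ti); cols <- (2 * tj - 1):(2 * tj)
      if (identical(pa$W[rows, cols], pb$W[rows, cols])) next
      n_resolved <- n_resolved + 1
      if (identical(ch$W[rows, cols], pa$W[rows, cols])) n_a <- n_a + 1
    }
    c(n_a, n_resolved)
  })
  frac <- sum(counts[1, ]) / sum(counts[2, ])
  expect_true(frac > 0.47 && frac < 0.53)

  small <- pa; small$W <- pa$W[1:4, 1:4]
  expect_error(crossover(pa, small), "identical dimensions")

  # metadata is inherited untouched
  expect_identical(child$subtype, pa$subtype)
  expect_identical(child$coords, pa$coords)
})

test_that("mutation deletes or refills one aligned block", {
  params <- tiny_params()
  p <- init_pattern(params, seed = 3)

  # deletion branch zeroes the chosen 2x2 region
  set.seed(4)
  del <- mutate_pattern(p, block_size = 2, p_delete = 1, normalize = FALSE)
  changed <- which(del$W != p$W, arr.ind = TRUE)
  expect_true(nrow(changed) <= 4)
  expect_true(all(del$W[changed] == 0))
  zeroed <- which(p$W != 0 & del$W == 0, arr.ind = TRUE)
  if (nrow(zeroed) > 1) {   # all zeroed entries sit in one 2x2 tile
    expect_lte(diff(range(ceiling(zeroed[, 1] / 2))), 0)
    expect_lte(diff(range(ceiling(zeroed[, 2] / 2))), 0)
  }

  # addition branch refills at the initial sparsity with uniform values;
  # block_size = 48 refills the whole matrix, giving clean statistics
  set.seed(5)
  refills <- replicate(30, {
    m <- mutate_pattern(p, block_size = 48, p_delete = 0, sparsity = 0.2,
                        normalize = FALSE)
    m$W
  })
  expect_true(abs(mean(refills != 0) - 0.2) < 0.03)
  vals <- refills[refills != 0]
  expect_true(all(vals >= -0.5 & vals <= 0.5))
})

test_that("a tiny evolution run keeps its accounting and is reproducible", {
  ser <- tiny_series(seed = 1, n_scenes = 4, n_clips = 10)
  cfg <- evolution_config(generations = 2, p_survivors = 5, q_offspring = 5)
  hb <- fast_hebb()

  fit <- evolve_wiring(ser, cfg, hebb = hb, seed = 11)
  expect_s3_class(fit, "wiring_evolution")
  expect_equal(nrow(fit$summary), 3)                  # gen 0..2
  expect_equal(length(fit$archive), pattern_count(2, 5, 5))
  expect_length(fit$survivors, 5)
  expect_length(fit$population, 10)
  expect_true(all(fit$summary$n == c(10, 5, 5)))

  # byte-identical reproduction under the same seed
  fit2 <- evolve_wiring(ser, cfg, hebb = hb, seed = 11)
  expect_identical(fit$summary, fit2$summary)
  expect_identical(fit$archive[[8]]$pattern$W, fit2$archive[[8]]$pattern$W)

  fit3 <- evolve_wiring(ser, cfg, hebb = hb, seed = 12)
  expect_false(identical(fit$summary, fit3$summary))

  # crossover + mutation preserved shape and metadata everywhere
  for (rec in fit$archive) {
    expect_equal(dim(rec$pattern$W), c(48, 48))
    expect_identical(rec$pattern$subtype, fit$archive[[1]]$pattern$subtype)
  }

  expect_error(evolution_config(objectives = "accuracy"), "objectives")
})

test_that("survivor selection is elitist on the first front", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    recs <- lapply(seq_len(n), function(j) {
      list(te = runif(1), cost = runif(1), density = runif(1))
    })
    objectives <- c("maximize_te", "minimize_cost")
    p <- sample(2:(n - 1), 1)
    chosen <- evowire:::select_survivors(recs, objectives, p)
    expect_length(chosen, p)
    rc <- evowire:::rank_and_crowding(recs, objectives)
    front1 <- rc$fronts[[1]]
    if (length(front1) <= p) {
      expect_true(all(front1 %in% chosen))   # never discard front 0
    }
    # no survivor has a worse rank than a discarded better-ranked pattern
    discarded <- setdiff(seq_len(n), chosen)
    if (length(discarded) > 0) {
      expect_lte(max(rc$rank[chosen]), min(rc$rank[discarded]) + 0L)
    }
  }
})

test_that("single-objective cost evolution drives the cost down in trend", {
  ser <- tiny_series(seed = 2, n_scenes = 4, n_clips = 10)
  cfg <- evolution_config(generations = 6, p_survivors = 6, q_offspring = 6,
                          objectives = "minimize_cost")
  fit <- evolve_wiring(ser, cfg, hebb = fast_hebb(), seed = 13)
  cost <- fit$summary$cost_mean
  # monotone-in-trend: the second half of the run is cheaper than the first
  expect_lt(mean(cost[5:7]), mean(cost[1:3]))
  expect_lt(cost[7], cost[1])
})
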