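test_that("PCA embedding standardizes, ranks and reports variance correctly", {
  set.seed(1)
  a <- rnorm(500); b <- rnorm(500)
  # data confined to a 2-plane in 5 dimensions stays rank 2
  M <- cbind(a, b, a + b, 2 * a - b, a - 3 * b)
  emb <- embed_pca3(M)
  expect_equal(emb$cumulative_contribution[2], 1, tolerance = 1e-9)
  expect_equal(emb$cumulative_contribution[3], 1, tolerance = 1e-9)
  expect_true(all(diff(emb$cumulative_contribution) >= -1e-12))

  # isotropic data spreads contributions evenly (~1/16 per component)
  iso <- matrix(rnorm(16 * 8000), ncol = 16)
  emb_iso <- embed_pca3(iso)
  expect_lt(abs(emb_iso$cumulative_contribution[1] - 1 / 16), 0.01)
  expect_lt(abs(emb_iso$cumulative_contribution[3] - 3 / 16), 0.02)

  # standardization identity: total variance = number of kept units
  Z <- scale(iso)
  expect_equal(sum(apply(Z, 2, stats::var)), 16)

  # constant units are dropped with a warning
  withconst <- cbind(M, 5)
  expect_warning(embed_pca3(withconst), "dropped")

  expect_error(embed_pca3(M[1:3, ]), "timesteps")
})

test_that("separation NMI scores clustered, shuffled and rotated embeddings", {
  set.seed(2)
  centers <- 20 * as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  pts <- do.call(rbind, lapply(1:8, function(k) {
    sweep(matrix(rnorm(40 * 3, sd = 0.5), 40, 3), 2, centers[k, ], "+")
  }))
  labs <- rep(paste0("S", 1:8), each = 40)
  emb <- structure(list(points = pts, labels = labs,
                        cumulative_contribution = c(.5, .8, 1)),
                   class = "embedded3d")
  expect_equal(separation_nmi(emb, seed = 3), 1)

  # blank timesteps are excluded from clustering
  emb_blank <- emb
  emb_blank$points <- rbind(pts, matrix(0, 20, 3))
  emb_blank$labels <- c(labs, rep("blank", 20))
  expect_equal(separation_nmi(emb_blank, seed = 3), 1)

  # shuffled labels carry no information
  set.seed(4)
  emb_shuf <- emb
  emb_shuf$labels <- sample(labs)
  expect_lt(separation_nmi(emb_shuf, seed = 3), 0.1)

  # rigid rotation leaves the score unchanged
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  emb_rot <- emb
  emb_rot$points <- pts %*% R
  expect_equal(separation_nmi(emb_rot, seed = 3),
               separation_nmi(emb, seed = 3))
})

test_that("box-counting recovers the dimension of line, plane and cube", {
  set.seed(5)
  t10k <- runif(10000)
  # an irrational direction avoids box-grid alignment artifacts
  line <- cbind(t10k, sqrt(2) * t10k, -sqrt(3) * t10k)
  expect_lt(abs(fractal_dimension(line) - 1), 0.1)

  # coarse ladders keep the box counts far from the sample-size ceiling
  coarse <- 2^-(1:4)
  plane <- cbind(runif(10000), runif(10000), 0)
  expect_lt(abs(fractal_dimension(plane, epsilons = coarse) - 2), 0.15)

  cube <- matrix(runif(30000), ncol = 3)
  expect_lt(abs(fractal_dimension(cube, epsilons = coarse) - 3), 0.2)

  # degenerate set
  expect_equal(fractal_dimension(matrix(1, 10, 3)), 0)
  expect_error(fractal_dimension(line, epsilons = c(0.5, 0.25)),
               "3 epsilon")
})

test_that("trajectory volume counts voxels and obeys the scaling law", {
  one <- matrix(0.5, 20, 3)
  expect_equal(trajectory_volume(one, voxel_size = 0.1), 0.1^3)

  set.seed(6)
  A <- matrix(runif(21000), ncol = 3)
  ctr <- colMeans(A)
  B <- sweep(sweep(A, 2, ctr), 2, c(2, 2, 2), "*")
  B <- sweep(B, 2, ctr, "+")
  ratio <- trajectory_volume(B, voxel_size = 0.2) /
    trajectory_volume(A, voxel_size = 0.2)
  expect_lt(abs(ratio - 8), 0.5)

  v <- normalize_volumes(c(0.2, 0.8, 0.4))
  expect_equal(max(v), 1)
  expect_equal(v, c(0.25, 1, 0.5))
})

test_that("the TE map vanishes without wiring and matches its aggregate", {
  params <- tiny_params()
  cfg <- info_config()
  probe <- make_probe_series(n_hold = 30, seed = 7)
  empty <- init_pattern(params, seed = 7)
  empty$W <- matrix(0, 48, 48)
  W_out <- init_readout(params, seed = 7)

  m0 <- te_map(empty, W_out, probe, params, cfg, seed = 8)
  # no pathway: per-pair transfer stays at the estimator's noise floor
  expect_lt(mean(m0), 0.05)
  expect_lt(max(m0), 0.2)
  expect_true(all(m0 >= 0 & m0 <= log2(cfg$n_bins)))

  p <- init_pattern(params, seed = 8)
  m1 <- te_map(p, W_out, probe, params, cfg, seed = 8)
  expect_equal(sum(m1), pattern_te(p, W_out, probe, params, cfg, seed = 8))
  expect_equal(mean(m1),
               pattern_te(p, W_out, probe, params, cfg, seed = 8,
                          aggregate = "mean"))
})

test_that("strength distributions partition every connection once", {
  # hand-built 6-unit pattern with known placements
  params6 <- reservoir_params(n_units = 6, n_per_subtype = 2, n_readout = 2)
  W <- matrix(0, 6, 6)
  W[1, 2] <- 0.4    # input <- input   (within, excitatory)
  W[3, 1] <- -0.2   # hidden <- input  (forward, inhibitory)
  W[1, 4] <- 0.1    # input <- hidden  (backward, excitatory)
  W[5, 3] <- 0.3    # rc_readout <- hidden (forward)
  W[6, 5] <- -0.5   # within rc_readout
  W[5, 2] <- 0.2    # rc_readout <- input (forward)
  pat <- structure(list(W = W,
                        subtype = rep(c("input", "hidden", "rc_readout"),
                                      each = 2),
                        coords = matrix(0, 6, 3), id = "hand"),
                   class = "wiring_pattern")
  sd6 <- strength_distributions(pat)
  df <- sd6$connections
  expect_equal(nrow(df), 6)                       # partition completeness
  expect_equal(sum(df$group == "within_input"), 1)
  expect_equal(sum(df$group == "within_rc_readout"), 1)
  expect_equal(sum(df$group == "input-hidden"), 2)
  expect_equal(sum(df$group == "hidden-rc_readout"), 1)
  expect_equal(sum(df$group == "input-rc_readout"), 1)
  expect_equal(sum(df$direction == "forward"), 3)
  expect_equal(sum(df$direction == "backward"), 1)
  expect_equal(sum(df$sign == "inhibitory"), 2)

  # all-positive weights leave the inhibitory side empty
  pos <- pat
  pos$W <- abs(W)
  expect_equal(sum(strength_distributions(pos)$connections$sign ==
                     "inhibitory"), 0)
})

test_that("characterize_pattern returns a coherent record", {
  params <- tiny_params()
  p <- init_pattern(params, seed = 10)
  ch <- characterize_pattern(p, probe = make_probe_series(n_hold = 10,
                                                          seed = 10),
                             params = params, seed = 10)
  expect_true(ch$fd > 0 && ch$fd < 3)
  expect_true(ch$separation_nmi >= 0 && ch$separation_nmi <= 1)
  expect_gt(ch$volume, 0)
  expect_equal(dim(ch$te_map), c(16, 16))
  expect_equal(nrow(ch$embedded$points), 160)
})
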