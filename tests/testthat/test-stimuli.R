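test_that("surrogate landscapes are rescaled, deterministic and seed-sensitive", {
  img <- generate_surrogate_landscape(1, 64, 64)
  expect_equal(dim(img$pixels), c(64, 64))
  expect_equal(min(img$pixels), 0)
  expect_equal(max(img$pixels), 1)

  img2 <- generate_surrogate_landscape(1, 64, 64)
  expect_identical(img$pixels, img2$pixels)

  img3 <- generate_surrogate_landscape(2, 64, 64)
  expect_true(any(img$pixels != img3$pixels))

  expect_error(generate_surrogate_landscape(1, 8, 64), "at least 16")
})

test_that("surrogate landscapes have decaying radial power spectra", {
  img <- generate_surrogate_landscape(3, 128, 128)
  p <- Mod(stats::fft(img$pixels - mean(img$pixels)))^2
  # power near DC (low spatial frequency) should dwarf high-frequency power
  low <- mean(p[2:5, 2:5])
  high <- mean(p[60:68, 60:68])
  expect_gt(low / high, 50)
})

test_that("saccade series have the documented length, shape and range", {
  imgs <- lapply(1:5, generate_surrogate_landscape, height = 32, width = 32)
  ser <- make_saccade_series(imgs, n_scenes = 100, n_clips = 40,
                             scene_size = 16, clip_size = 4, seed = 1)
  expect_equal(nrow(ser$vectors), 5 * 100 * 40)   # 20,000 timesteps
  expect_equal(ncol(ser$vectors), 16)             # 4x4 clip
  expect_true(all(ser$vectors >= 0 & ser$vectors <= 1))
  expect_true(all(ser$labels == "training"))

  # pure function of the seed
  ser2 <- make_saccade_series(imgs[1:2], n_scenes = 3, n_clips = 5, seed = 7)
  ser3 <- make_saccade_series(imgs[1:2], n_scenes = 3, n_clips = 5, seed = 7)
  expect_identical(ser2$vectors, ser3$vectors)
  ser4 <- make_saccade_series(imgs[1:2], n_scenes = 3, n_clips = 5, seed = 8)
  expect_false(identical(ser2$vectors, ser4$vectors))

  # an all-zero landscape yields all-zero clips
  blank <- structure(list(pixels = matrix(0, 32, 32), height = 32L,
                          width = 32L, seed = 0L),
                     class = "surrogate_image")
  ser0 <- make_saccade_series(list(blank), n_scenes = 2, n_clips = 3, seed = 1)
  expect_true(all(ser0$vectors == 0))

  expect_error(make_saccade_series(imgs, 2, 2, scene_size = 8,
                                   clip_size = 16), "clip_size")
})

test_that("clips are linearized row-major from the image", {
  # a landscape whose value encodes its (row, col) position uniquely
  px <- outer(seq(0, 1, length.out = 32), seq(0, 1, length.out = 32) / 100,
              "+")
  land <- structure(list(pixels = px, height = 32L, width = 32L, seed = 0L),
                    class = "surrogate_image")
  ser <- make_saccade_series(list(land), n_scenes = 1, n_clips = 1,
                             scene_size = 16, clip_size = 4, seed = 3)
  v <- ser$vectors[1, ]
  # row-major: elements 1..4 share a row (same large part, increasing small
  # part); elements 1, 5, 9, 13 share a column
  expect_equal(diff(v[1:4]), rep(1 / 3100, 3), tolerance = 1e-10)
  expect_equal(diff(v[c(1, 5, 9, 13)]), rep(1 / 31, 3), tolerance = 1e-10)
})

test_that("probe series structure matches the eight-stimulus protocol", {
  pr <- make_probe_series(n_hold = 20, seed = 1)
  expect_equal(nrow(pr$vectors), 320)             # 8x20 stimulus + 8x20 blank
  tab <- table(pr$labels)
  expect_equal(unname(tab[["blank"]]), 160)
  non_blank <- tab[names(tab) != "blank"]
  expect_length(non_blank, 8)
  expect_true(all(non_blank == 20))               # exactly equal counts

  # blank steps are all-zero; stimulus steps obey the noise bounds
  expect_true(all(pr$vectors[pr$labels == "blank", ] == 0))
  expect_true(all(pr$vectors >= 0 & pr$vectors <= 1))

  # fresh per-step noise: consecutive steps of one presentation differ
  s1 <- pr$vectors[pr$labels == "H1", ]
  expect_false(identical(s1[1, ], s1[2, ]))

  # without noise each presentation repeats the bar exactly
  pr0 <- make_probe_series(n_hold = 5, noise_high = 0, seed = 1)
  s <- pr0$vectors[pr0$labels == "V1", ]
  expect_true(all(apply(s, 2, function(col) length(unique(col)) == 1)))
  expect_equal(unname(rowSums(s)), rep(4, 5))     # width-1 bar of four ones

  expect_error(make_probe_series(n_hold = 0), "n_hold")
  expect_error(make_probe_series(noise_high = 1), "noise_high")
})

test_that("series generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(make_probe_series(n_hold = 3, seed = 9))
  invisible(generate_surrogate_landscape(4, 32, 32))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("stimulus series round-trip through the text format", {
  pr <- make_probe_series(n_hold = 2, seed = 1)
  path <- tempfile(fileext = ".csv")
  write_stimulus_series(pr, path)
  back <- read_stimulus_series(path)
  expect_equal(unname(back$vectors), unname(pr$vectors), tolerance = 1e-12)
  expect_identical(back$labels, pr$labels)
  unlink(path)
})
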