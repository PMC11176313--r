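#' Generate a synthetic natural-landscape image
#'
#' Produces a grayscale image with approximately 1/f-decaying spatial power
#' spectrum, the canonical second-order statistic of natural scenes, by
#' spectrally shaping Gaussian white noise and min-max rescaling the result
#' to \[0, 1\].  These surrogates stand in for photographic landscape images
#' when building saccadic stimulus series; no external database is required.
#'
#' @param seed Integer seed; identical seeds give bit-identical images.
#' @param height,width Image dimensions in pixels (at least 16).
#' @param exponent Spectral slope: amplitude falls as `1/f^exponent`.
#' @return An object of class `"surrogate_image"`: a list with `pixels`
#'   (`height` x `width` matrix in \[0, 1\]), `height`, `width`, `seed`.
#' @examples
#' img <- generate_surrogate_landscape(1, 64, 64)
#' range(img$pixels)
#' @export
generate_surrogate_landscape <- function(seed, height = 128L, width = 128L,
                                         exponent = 1) {
  if (!is.numeric(height) || !is.numeric(width) ||
      height < 16 || width < 16) {
    stop("'height' and 'width' must be at least 16 pixels")
  }
  height <- as.integer(height); width <- as.integer(width)
  pixels <- with_seed(seed, {
    white <- matrix(rnorm(height * width), height, width)
    ft <- stats::fft(white)
    # radial spatial frequency on the standard FFT grid (cycles/pixel)
    fy <- c(seq_len(height) - 1)
    fy <- ifelse(fy > height / 2, fy - height, fy) / height
    fx <- c(seq_len(width) - 1)
    fx <- ifelse(fx > width / 2, fx - width, fx) / width
    f <- sqrt(outer(fy^2, fx^2, "+"))
    amp <- ifelse(f > 0, 1 / f^exponent, 0)  # drop the DC component
    img <- Re(stats::fft(ft * amp, inverse = TRUE)) / (height * width)
    (img - min(img)) / (max(img) - min(img))
  })
  structure(list(pixels = pixels, height = height, width = width, seed = seed),
            class = "surrogate_image")
}

#' Build a saccade-style training stimulus series
#'
#' Emulates saccadic sampling of natural scenes: from each landscape image,
#' `n_scenes` square scene windows are extracted at random positions; within
#' each scene a `clip_size` x `clip_size` window performs a random walk
#' (integer shifts uniform on \[-scene_size/4, scene_size/4\] per axis,
#' clamped to the scene), emitting `n_clips` clips.  Each clip is linearized
#' row-major into a vector and occupies exactly one timestep.
#'
#' @param landscapes List of `"surrogate_image"` objects (or a single one).
#' @param n_scenes Scenes extracted per landscape.
#' @param n_clips Clips emitted per scene.
#' @param scene_size Side length of the square scene window.
#' @param clip_size Side length of the clip window; vectors have
#'   `clip_size^2` elements.
#' @param seed Integer seed; the series is a pure function of its arguments.
#' @return An object of class `"stimulus_series"`: list with `vectors`
#'   (T x `clip_size^2` matrix, values in \[0, 1\]), `labels` (character,
#'   all `"training"`), `clip_size`.
#' @examples
#' img <- generate_surrogate_landscape(1, 32, 32)
#' ser <- make_saccade_series(list(img), n_scenes = 2, n_clips = 3,
#'                            scene_size = 16, clip_size = 4, seed = 1)
#' dim(ser$vectors)
#' @export
make_saccade_series <- function(landscapes, n_scenes, n_clips,
                                scene_size = 16L, clip_size = 4L, seed = 1L) {
  if (inherits(landscapes, "surrogate_image")) landscapes <- list(landscapes)
  if (clip_size > scene_size) {
    stop("'clip_size' must not exceed 'scene_size'")
  }
  min_dim <- min(vapply(landscapes, function(l) min(l$height, l$width), 0))
  if (scene_size > min_dim) {
    stop("'scene_size' exceeds the smallest landscape dimension")
  }
  n_el <- clip_size^2
  total <- length(landscapes) * n_scenes * n_clips
  vectors <- matrix(0, total, n_el)
  shift_max <- max(1L, floor(scene_size / 4))
  row <- 0L
  with_seed(seed, {
    for (land in landscapes) {
      px <- land$pixels
      for (sc in seq_len(n_scenes)) {
        top <- sample.int(land$height - scene_size + 1L, 1L)
        left <- sample.int(land$width - scene_size + 1L, 1L)
        scene <- px[top:(top + scene_size - 1L), left:(left + scene_size - 1L)]
        # clip window random walk inside the scene
        lim <- scene_size - clip_size + 1L
        cy <- sample.int(lim, 1L); cx <- sample.int(lim, 1L)
        for (cl in seq_len(n_clips)) {
          cy <- min(max(cy + sample(-shift_max:shift_max, 1L), 1L), lim)
          cx <- min(max(cx + sample(-shift_max:shift_max, 1L), 1L), lim)
          clip <- scene[cy:(cy + clip_size - 1L), cx:(cx + clip_size - 1L)]
          row <- row + 1L
          vectors[row, ] <- as.vector(t(clip))  # row-major linearization
        }
      }
    }
  })
  structure(list(vectors = vectors,
                 labels = rep("training", total),
                 clip_size = as.integer(clip_size)),
            class = "stimulus_series")
}

# The eight oriented 4x4 probe patterns: two placements each of horizontal,
# vertical, diagonal-downward and diagonal-upward width-1 bars.
probe_patterns <- function() {
  mk <- function(f) {
    m <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4) if (f(i, j)) m[i, j] <- 1
    m
  }
  list(
    H1 = mk(function(i, j) i == 2),
    H2 = mk(function(i, j) i == 3),
    V1 = mk(function(i, j) j == 2),
    V2 = mk(function(i, j) j == 3),
    DD1 = mk(function(i, j) i == j),
    DD2 = mk(function(i, j) i == j + 1),
    DU1 = mk(function(i, j) i + j == 5),
    DU2 = mk(function(i, j) i + j == 4)
  )
}

#' Build the eight-stimulus oriented probe series
#'
#' Characterization stimuli: eight 4x4 oriented bar patterns (two horizontal,
#' two vertical, two diagonal-downward, two diagonal-upward placements), each
#' held for `n_hold` timesteps with fresh per-step uniform \[0, `noise_high`\]
#' noise added (then clamped to \[0, 1\]), followed by `n_hold` blank
#' (all-zero) timesteps.
#'
#' @param n_hold Steps each stimulus (and each blank interval) is held.
#' @param noise_high Upper bound of the per-step uniform noise.
#' @param seed Integer seed for the noise stream.
#' @return A `"stimulus_series"` whose labels are the stimulus ids
#'   (`"H1"`, ..., `"DU2"`) or `"blank"`; total length `16 * n_hold`.
#' @examples
#' pr <- make_probe_series(n_hold = 5, seed = 1)
#' table(pr$labels)
#' @export
make_probe_series <- function(n_hold = 20L, noise_high = 0.1, seed = 1L) {
  if (n_hold < 1) stop("'n_hold' must be at least 1")
  if (noise_high < 0 || noise_high >= 1) stop("'noise_high' must be in [0, 1)")
  pats <- probe_patterns()
  total <- 16L * as.integer(n_hold)
  vectors <- matrix(0, total, 16L)
  labels <- character(total)
  row <- 0L
  with_seed(seed, {
    for (nm in names(pats)) {
      base <- as.vector(t(pats[[nm]]))
      for (t in seq_len(n_hold)) {
        row <- row + 1L
        vectors[row, ] <- pmin(base + runif(16L, 0, noise_high), 1)
        labels[row] <- nm
      }
      for (t in seq_len(n_hold)) {       # blank interval
        row <- row + 1L
        labels[row] <- "blank"
      }
    }
  })
  structure(list(vectors = vectors, labels = labels, clip_size = 4L),
            class = "stimulus_series")
}

#' @export
print.stimulus_series <- function(x, ...) {
  cat("Stimulus series:", nrow(x$vectors), "timesteps,",
      ncol(x$vectors), "elements per vector\n")
  tab <- table(x$labels)
  cat("Labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a stimulus series as plain text
#'
#' One timestep per row: the label followed by the comma-separated vector.
#'
#' @param series A `"stimulus_series"`.
#' @param path File path.
#' @return `write_stimulus_series` returns `path` invisibly;
#'   `read_stimulus_series` returns the reconstructed series.
#' @export
write_stimulus_series <- function(series, path) {
  df <- data.frame(label = series$labels, series$vectors,
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_series
#' @param clip_size Clip side length recorded in the reconstructed series.
#' @export
read_stimulus_series <- function(path, clip_size = 4L) {
  df <- utils::read.table(path, sep = ",", stringsAsFactors = FALSE)
  structure(list(vectors = as.matrix(df[, -1, drop = FALSE]),
                 labels = as.character(df[[1]]),
                 clip_size = as.integer(clip_size)),
            class = "stimulus_series")
}
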