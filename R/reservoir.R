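#' Reservoir model parameters
#'
#' Parameter container for the leaky-integrator echo-state reservoir
#' `x(t+1) = x(t) + alpha * W r(t) + beta * u(t) + sigma * xi`, with
#' `r = tanh(x)` and `xi` i.i.d. standard normal per unit per step.
#'
#' @param alpha Recurrent coupling gain (default 0.1).
#' @param beta Input strength (default 1).
#' @param sigma Noise strength (default 0.01).
#' @param n_units Total reservoir units (default 48, three subtypes).
#' @param n_per_subtype Units per subtype (default 16);
#'   `n_units = 3 * n_per_subtype` is enforced.
#' @param sparsity Target nonzero fraction of the internal weight matrix
#'   (default 0.2).
#' @param n_readout Rows of the linear readout (default 16).
#' @param readout_activation `"tanh"` (readout reads the bounded activations
#'   of the RC-readout units, the default) or `"raw"` (reads their states).
#' @return A list of class `"reservoir_params"`.
#' @export
reservoir_params <- function(alpha = 0.1, beta = 1.0, sigma = 0.01,
                             n_units = 48L, n_per_subtype = 16L,
                             sparsity = 0.2, n_readout = 16L,
                             readout_activation = c("tanh", "raw")) {
  stopifnot(alpha >= 0, beta >= 0, sigma >= 0,
            sparsity > 0, sparsity <= 1,
            n_units == 3L * n_per_subtype)
  structure(list(alpha = alpha, beta = beta, sigma = sigma,
                 n_units = as.integer(n_units),
                 n_per_subtype = as.integer(n_per_subtype),
                 sparsity = sparsity, n_readout = as.integer(n_readout),
                 readout_activation = match.arg(readout_activation)),
            class = "reservoir_params")
}

# Unit indices per subtype: units are ordered input, hidden, rc_readout.
subtype_labels <- function(params) {
  rep(c("input", "hidden", "rc_readout"), each = params$n_per_subtype)
}

subtype_index <- function(pattern, which) which(pattern$subtype == which)

#' Normalize a weight matrix to unit spectral radius
#'
#' Divides `W` by its spectral radius (largest eigenvalue magnitude), the
#' standard echo-state scaling.
#'
#' @param W Square numeric matrix with at least one nonzero eigenvalue.
#' @return `W / rho(W)`, whose spectral radius is 1 within numerical
#'   tolerance.
#' @export
normalize_spectral_radius <- function(W) {
  rho <- spectral_radius(W)
  if (rho < 1e-12) {
    stop("spectral radius is zero (all-zero or nilpotent matrix); ",
         "cannot normalize")
  }
  W / rho
}

#' @rdname normalize_spectral_radius
#' @export
spectral_radius <- function(W) {
  max(Mod(eigen(W, only.values = TRUE)$values))
}

#' Initialize a random wiring pattern
#'
#' Nonzero entries are chosen independently with probability `sparsity` and
#' drawn from Uniform\[-0.5, 0.5\]; the matrix is then (optionally) rescaled
#' to spectral radius 1.  Subtype labels and fixed 3D grid coordinates are
#' attached.
#'
#' @param params A [reservoir_params()] object.
#' @param seed Integer seed; identical seeds give identical patterns.
#' @param layout A [build_layout()] object supplying coordinates (defaults to
#'   the 3-layer 4x4 grid for 48 units).
#' @param normalize Rescale to unit spectral radius (default `TRUE`).
#' @param id Pattern identifier.
#' @return An object of class `"wiring_pattern"`: list with `W`, `subtype`,
#'   `coords`, `id`.
#' @export
init_pattern <- function(params = reservoir_params(), seed = 1L,
                         layout = NULL, normalize = TRUE, id = NULL) {
  n <- params$n_units
  if (is.null(layout)) layout <- default_layout(params)
  W <- with_seed(seed, random_wiring_matrix(n, params$sparsity))
  if (normalize) W <- normalize_spectral_radius(W)
  structure(list(W = W,
                 subtype = subtype_labels(params),
                 coords = layout$coords,
                 id = if (is.null(id)) paste0("init-", seed) else id),
            class = "wiring_pattern")
}

# Raw sparse uniform matrix, drawn from the current RNG stream.
random_wiring_matrix <- function(n, sparsity) {
  W <- matrix(0, n, n)
  mask <- runif(n * n) < sparsity
  W[mask] <- runif(sum(mask), -0.5, 0.5)
  W
}

# Layout matching a params object (3 layers, one per subtype).
default_layout <- function(params = reservoir_params()) {
  side <- sqrt(params$n_per_subtype)
  if (side != round(side)) {
    stop("default layout requires a square number of units per subtype")
  }
  build_layout(n_layers = 3L, layer_rows = as.integer(side),
               layer_cols = as.integer(side))
}

#' Initialize readout weights
#'
#' Entries are drawn from a standard normal distribution.
#'
#' @param params A [reservoir_params()] object.
#' @param seed Integer seed.
#' @return An `n_readout` x `n_per_subtype` matrix.
#' @export
init_readout <- function(params = reservoir_params(), seed = 1L) {
  with_seed(seed, matrix(rnorm(params$n_readout * params$n_per_subtype),
                         params$n_readout, params$n_per_subtype))
}

#' Single reservoir update step
#'
#' Evaluates `x + alpha * W tanh(x) + beta * u + sigma * noise` exactly.
#'
#' @param x State vector.
#' @param W Internal weight matrix.
#' @param u Full-length input vector (zero outside the input subtype).
#' @param params A [reservoir_params()] object.
#' @param noise Per-unit standard-normal draws (default: a fresh draw from
#'   the current RNG stream).
#' @return The next state vector.
#' @export
reservoir_step <- function(x, W, u, params, noise = rnorm(length(x))) {
  if (length(x) != nrow(W) || length(u) != length(x) ||
      length(noise) != length(x)) {
    stop("dimension mismatch between state, weights, input or noise")
  }
  x + params$alpha * as.vector(W %*% tanh(x)) + params$beta * u +
    params$sigma * noise
}

# Core simulation loop shared by run_reservoir(), train_readout() and the
# evolutionary evaluation: iterates the state update over a series from
# x(0) = 0, optionally applying the online Hebbian readout update, and
# records states, activations and readout outputs.
run_core <- function(pattern, W_out, series, params, seed,
                     hebb = NULL, learn_readout = FALSE) {
  n <- params$n_units
  if (nrow(pattern$W) != n) stop("pattern size does not match params")
  Tn <- nrow(series$vectors)
  if (Tn > 0 && ncol(series$vectors) != params$n_per_subtype) {
    stop("series vector length must equal the number of input units")
  }
  inp <- which(pattern$subtype == "input")
  rco <- which(pattern$subtype == "rc_readout")
  X <- matrix(0, Tn, n)
  R <- matrix(0, Tn, n)
  Z <- matrix(0, Tn, params$n_readout)
  x <- numeric(n)
  W <- pattern$W
  rate <- if (!is.null(hebb)) hebb$dt / hebb$tau else 0
  with_seed(seed, {
    for (t in seq_len(Tn)) {
      u <- numeric(n)
      u[inp] <- series$vectors[t, ]
      x <- x + params$alpha * as.vector(W %*% tanh(x)) + params$beta * u +
        params$sigma * rnorm(n)
      r <- tanh(x)
      rhat <- if (params$readout_activation == "tanh") r[rco] else x[rco]
      z <- as.vector(W_out %*% rhat)
      if (learn_readout) {
        # subtractive-normalized Hebbian update of each readout row
        W_out <- W_out + rate * z %o% (rhat - mean(rhat))
      }
      X[t, ] <- x; R[t, ] <- r; Z[t, ] <- z
    }
  })
  list(trajectory = structure(list(x = X, r = R, z = Z,
                                   labels = series$labels),
                              class = "reservoir_trajectory"),
       W_out = W_out)
}

#' Run the reservoir over a stimulus series
#'
#' Iterates the state update from `x(0) = 0`, feeding each series vector to
#' the input subtype (all other units receive zero input) and computing the
#' linear readout from the RC-readout units at every step.
#'
#' @param pattern A `"wiring_pattern"`.
#' @param W_out Readout weight matrix ([init_readout()]).
#' @param series A `"stimulus_series"`.
#' @param params A [reservoir_params()] object.
#' @param seed Integer seed for the noise stream.
#' @return An object of class `"reservoir_trajectory"`: list with `x`
#'   (T x n states), `r` (activations `tanh(x)`), `z` (T x n_readout
#'   outputs) and `labels` carried from the series.
#' @export
run_reservoir <- function(pattern, W_out, series, params = reservoir_params(),
                          seed = 1L) {
  run_core(pattern, W_out, series, params, seed)$trajectory
}

#' @export
print.wiring_pattern <- function(x, ...) {
  nz <- mean(x$W != 0)
  cat("Wiring pattern", x$id, ":", nrow(x$W), "units,",
      sprintf("density %.3f, spectral radius %.4f", nz, spectral_radius(x$W)),
      "\n")
  invisible(x)
}

#' Write / read a wiring pattern as plain text
#'
#' A small sidecar-annotated text format: header lines (`# id`, `# subtype`,
#' `# coords`) followed by the dense weight matrix, one row per line.
#'
#' @param pattern A `"wiring_pattern"`.
#' @param path File path.
#' @export
write_wiring_pattern <- function(pattern, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# id: ", pattern$id), con)
  writeLines(paste0("# subtype: ", paste(pattern$subtype, collapse = ",")), con)
  writeLines(paste0("# coords: ",
                    paste(apply(pattern$coords, 1, paste, collapse = ":"),
                          collapse = ",")), con)
  utils::write.table(pattern$W, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_wiring_pattern
#' @export
read_wiring_pattern <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  id <- sub("^# id: ", "", hdr[1])
  subtype <- strsplit(sub("^# subtype: ", "", hdr[2]), ",")[[1]]
  coords <- do.call(rbind, lapply(
    strsplit(strsplit(sub("^# coords: ", "", hdr[3]), ",")[[1]], ":"),
    as.numeric))
  W <- as.matrix(utils::read.table(text = lines[!startsWith(lines, "# ")]))
  dimnames(W) <- NULL
  structure(list(W = W, subtype = subtype, coords = coords, id = id),
            class = "wiring_pattern")
}
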