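#' Hebbian plasticity parameters
#'
#' Parameters of the subtractive-normalized Hebbian rule
#' `tau dw/dt = v u - v (n . u) n / N`, discretized with Euler step `dt`
#' (one update per model timestep).  Subtracting the mean co-activity makes
#' every increment vector sum to zero, conserving total incoming weight.
#'
#' @param tau Time constant (default 0.1).
#' @param dt Euler step per model timestep (default 1e-4).  The per-step
#'   learning rate is `dt / tau`; because the reservoir state equation has
#'   no leak term, rates of order 0.1 or larger drive a self-reinforcing
#'   weight runaway during spontaneous tuning (states saturate and the
#'   weight scale inflates by orders of magnitude), so the default keeps the
#'   update a small per-timestep refinement.
#' @param t_tune Duration (steps) of spontaneous-activity tuning of the
#'   reservoir (default 100).
#' @param mask_preserving During reservoir tuning, update only connections
#'   that already exist (default `TRUE`), so density is invariant.
#' @return A list of class `"hebb_params"`.
#' @export
hebb_params <- function(tau = 0.1, dt = 1e-4, t_tune = 100L,
                        mask_preserving = TRUE) {
  stopifnot(tau > 0, dt > 0, t_tune >= 0)
  structure(list(tau = tau, dt = dt, t_tune = as.integer(t_tune),
                 mask_preserving = isTRUE(mask_preserving)),
            class = "hebb_params")
}

#' Subtractive-normalized Hebbian increment
#'
#' For downstream activity `v` and upstream activity vector `u` of length N,
#' returns `(dt/tau) * (v u - v mean(u))`, the Euler increment of the
#' subtractive-normalized Hebbian rule.  The increment sums to zero over
#' upstream units.
#'
#' @param v Downstream activity (scalar).
#' @param u Upstream activity vector.
#' @param hebb A [hebb_params()] object.
#' @return Weight-increment vector of the same length as `u`.
#' @examples
#' hebb_delta(1, c(1, 0), hebb_params(tau = 1, dt = 1))  # (0.5, -0.5)
#' @export
hebb_delta <- function(v, u, hebb = hebb_params()) {
  if (length(u) == 0) stop("'u' must contain at least one upstream unit")
  (hebb$dt / hebb$tau) * (v * u - v * mean(u))
}

#' Tune a wiring pattern by spontaneous-activity Hebbian plasticity
#'
#' Runs `t_tune` timesteps with zero external input but active state noise
#' (prenatal-style spontaneous firing); after each step every unit's
#' incoming weights are updated with the subtractive-normalized Hebbian rule
#' (downstream activity = the unit's activation, upstream activity = all
#' units' activations, N = number of reservoir units).  By default only
#' entries that were nonzero before tuning are modified, so the connection
#' mask — and hence the density — is preserved.
#'
#' @param pattern A `"wiring_pattern"` (spectral radius already normalized).
#' @param params A [reservoir_params()] object.
#' @param hebb A [hebb_params()] object.
#' @param seed Integer seed for the noise stream.
#' @return The tuned `"wiring_pattern"`.
#' @export
tune_reservoir <- function(pattern, params = reservoir_params(),
                           hebb = hebb_params(), seed = 1L) {
  n <- params$n_units
  W <- pattern$W
  mask <- W != 0
  rate <- hebb$dt / hebb$tau
  x <- numeric(n)
  with_seed(seed, {
    for (t in seq_len(hebb$t_tune)) {
      x <- x + params$alpha * as.vector(W %*% tanh(x)) +
        params$sigma * rnorm(n)
      r <- tanh(x)
      dW <- rate * r %o% (r - mean(r))  # rows: downstream; cols: upstream
      if (hebb$mask_preserving) {
        W[mask] <- W[mask] + dW[mask]
      } else {
        W <- W + dW
      }
    }
  })
  pattern$W <- W
  pattern
}

#' Train readout weights by Hebbian learning on a stimulus series
#'
#' Drives the reservoir with the series (the training signal); at every step
#' each readout row is updated with the subtractive-normalized Hebbian rule,
#' with downstream activity = that readout output and upstream activity =
#' the RC-readout unit activations (N = number of RC-readout units).  No
#' supervised target is involved.
#'
#' @param pattern A `"wiring_pattern"`.
#' @param W_out Initial readout weights ([init_readout()]).
#' @param series Training `"stimulus_series"`.
#' @param params A [reservoir_params()] object.
#' @param hebb A [hebb_params()] object.
#' @param seed Integer seed for the noise stream.
#' @return The trained readout weight matrix.
#' @export
train_readout <- function(pattern, W_out, series, params = reservoir_params(),
                          hebb = hebb_params(), seed = 1L) {
  run_core(pattern, W_out, series, params, seed,
           hebb = hebb, learn_readout = TRUE)$W_out
}
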