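#' Information-estimator configuration
#'
#' Settings of the plug-in binned estimators used for transfer entropy and
#' mutual information: each series is discretized into `n_bins` equal-width
#' bins over its own range, joint frequencies are estimated by counting, and
#' all quantities are reported in bits (log base 2).
#'
#' @param n_bins Number of equal-width bins per series (default 8).
#' @param k Target (Y) history length for transfer entropy (default 1).
#' @param l Source (X) history length for transfer entropy (default 1).
#' @return A list of class `"info_config"`.
#' @export
info_config <- function(n_bins = 8L, k = 1L, l = 1L) {
  stopifnot(n_bins >= 2, k >= 1, l >= 1)
  structure(list(n_bins = as.integer(n_bins), k = as.integer(k),
                 l = as.integer(l)),
            class = "info_config")
}

# Equal-width discretization over the series' own range; a constant series
# collapses to a single bin.
discretize_series <- function(x, n_bins) {
  rng <- range(x)
  if (!is.finite(rng[1]) || !is.finite(rng[2]) || rng[1] == rng[2]) {
    return(rep(1L, length(x)))
  }
  b <- floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L
  pmin(as.integer(b), n_bins)
}

# History code at times t = h..(n-1) for history length `len`:
# sum_{j=0..len-1} (b[t-j]-1) * n_bins^j, where h = max history needed.
history_codes <- function(b, len, n_bins, h, n) {
  ts <- h:(n - 1L)
  code <- integer(length(ts))
  for (j in 0:(len - 1L)) {
    code <- code + (b[ts - j] - 1L) * n_bins^j
  }
  code
}

# Shared plug-in TE computation from pre-discretized series.
te_from_bins <- function(bx, by, cfg) {
  n <- length(bx)
  nb <- cfg$n_bins
  h <- max(cfg$k, cfg$l)
  y1 <- by[(h + 1L):n]
  yh <- history_codes(by, cfg$k, nb, h, n)
  xh <- history_codes(bx, cfg$l, nb, h, n)
  nbk <- nb^cfg$k
  nbl <- nb^cfg$l
  code <- (y1 - 1L) + nb * (yh + nbk * xh)
  counts <- tabulate(code + 1L, nbins = nb * nbk * nbl)
  N <- sum(counts)
  # marginals: c(y1, yh) over xh; c(yh, xh) over y1; c(yh) over both
  c_y1yh <- rowSums(matrix(counts, nrow = nb * nbk))
  c_yhxh <- colSums(matrix(counts, nrow = nb))
  c_yh <- rowSums(matrix(c_yhxh, nrow = nbk))
  # broadcast marginals to the full (y1, yh, xh) grid
  m_y1yh <- rep(c_y1yh, times = nbl)
  m_yhxh <- rep(c_yhxh, each = nb)
  m_yh <- rep(rep(c_yh, each = nb), times = nbl)
  pos <- counts > 0
  sum(counts[pos] / N *
        log2(counts[pos] * m_yh[pos] / (m_yhxh[pos] * m_y1yh[pos])))
}

#' Binned transfer entropy (bits)
#'
#' Plug-in estimate of the transfer entropy from source series `x` to target
#' series `y`: the expected log-ratio of the target's transition probability
#' conditioned on its own history (length `k`) with versus without the
#' source history (length `l`).  Each series is discretized into equal-width
#' bins over its own range; a constant series occupies a single bin, making
#' the transfer entropy zero.
#'
#' @param x Source time series (numeric).
#' @param y Target time series, same length as `x`.
#' @param cfg An [info_config()] object.
#' @return Transfer entropy in bits, in `[0, log2(n_bins)]` up to estimator
#'   noise.
#' @examples
#' set.seed(1)
#' x <- sample(0:1, 500, replace = TRUE)
#' y <- c(0, x[-500])                 # y copies x with one-step lag
#' transfer_entropy(x, y, info_config(n_bins = 2))
#' @export
transfer_entropy <- function(x, y, cfg = info_config()) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < cfg$k + cfg$l + 2) {
    stop("series too short for the requested history lengths")
  }
  te_from_bins(discretize_series(x, cfg$n_bins),
               discretize_series(y, cfg$n_bins), cfg)
}

#' Binned mutual information (bits)
#'
#' Symmetric plug-in estimate on equal-width bins.
#'
#' @inheritParams transfer_entropy
#' @return Mutual information in bits (non-negative).
#' @export
mutual_information <- function(x, y, cfg = info_config()) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  nb <- cfg$n_bins
  bx <- discretize_series(x, nb)
  by <- discretize_series(y, nb)
  counts <- tabulate((bx - 1L) + nb * (by - 1L) + 1L, nbins = nb * nb)
  N <- sum(counts)
  cx <- rowSums(matrix(counts, nrow = nb))
  cy <- colSums(matrix(counts, nrow = nb))
  mx <- rep(cx, times = nb)
  my <- rep(cy, each = nb)
  pos <- counts > 0
  sum(counts[pos] / N * log2(counts[pos] * N / (mx[pos] * my[pos])))
}

#' Normalized mutual information between two labelings
#'
#' Discrete mutual information normalized by the geometric mean of the two
#' labelings' entropies, computed directly from label frequencies (no
#' binning).  Used as the separation score between true stimulus labels and
#' k-means cluster labels; invariant to label permutations.
#'
#' @param labels_a,labels_b Equal-length discrete label vectors.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("labelings must have equal length")
  }
  if (length(labels_a) < 2) stop("need at least 2 samples")
  tab <- table(labels_a, labels_b)
  N <- sum(tab)
  pa <- rowSums(tab) / N
  pb <- colSums(tab) / N
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 || hb == 0) {
    stop("a labeling with a single class has zero entropy; NMI is undefined")
  }
  p <- tab / N
  e <- outer(pa, pb)
  pos <- p > 0
  mi <- sum(p[pos] * log(p[pos] / e[pos]))
  mi / sqrt(ha * hb)
}

# TE matrix between the columns of X (sources) and Y (targets); bins are
# computed once per column.
te_matrix <- function(X, Y, cfg) {
  bx <- lapply(seq_len(ncol(X)), function(j) {
    discretize_series(X[, j], cfg$n_bins)
  })
  by <- lapply(seq_len(ncol(Y)), function(j) {
    discretize_series(Y[, j], cfg$n_bins)
  })
  out <- matrix(0, ncol(X), ncol(Y))
  for (i in seq_len(ncol(X))) {
    for (j in seq_len(ncol(Y))) {
      out[i, j] <- te_from_bins(bx[[i]], by[[j]], cfg)
    }
  }
  out
}

#' Transfer-entropy objective of a wiring pattern
#'
#' Runs the reservoir on a stimulus series and measures the transfer entropy
#' from every input unit's driving signal to every RC-readout unit's
#' activation, aggregating the resulting `n_input` x `n_rc_readout` map by
#' summation (default) or averaging.  This is the information-transfer
#' objective maximized during evolution.
#'
#' @param pattern A `"wiring_pattern"`.
#' @param W_out Readout weights (do not influence reservoir states; kept for
#'   interface symmetry with the full pipeline).
#' @param series A `"stimulus_series"`.
#' @param params A [reservoir_params()] object.
#' @param cfg An [info_config()] object.
#' @param seed Integer seed for the reservoir noise stream.
#' @param aggregate `"sum"` (default) or `"mean"` over the input x readout
#'   pairs.
#' @return Aggregate transfer entropy in bits.
#' @export
pattern_te <- function(pattern, W_out, series, params = reservoir_params(),
                       cfg = info_config(), seed = 1L,
                       aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  traj <- run_reservoir(pattern, W_out, series, params, seed)
  m <- te_matrix(series$vectors,
                 traj$r[, subtype_index(pattern, "rc_readout"), drop = FALSE],
                 cfg)
  if (aggregate == "sum") sum(m) else mean(m)
}
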