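#' Transfer-entropy map of a wiring pattern
#'
#' Runs the reservoir on a stimulus series and returns the matrix of binned
#' transfer entropies from each input unit's driving signal (rows) to each
#' RC-readout unit's activation (columns).
#'
#' @inheritParams pattern_te
#' @return An `n_input` x `n_rc_readout` matrix of transfer entropies
#'   (bits); its sum equals [pattern_te()] under sum aggregation.
#' @export
te_map <- function(pattern, W_out, series, params = reservoir_params(),
                   cfg = info_config(), seed = 1L) {
  traj <- run_reservoir(pattern, W_out, series, params, seed)
  te_matrix(series$vectors,
            traj$r[, subtype_index(pattern, "rc_readout"), drop = FALSE],
            cfg)
}

#' Connection-strength distributions by subtype group
#'
#' Partitions the nonzero connections of a pattern into within-subtype
#' groups (input, hidden, rc_readout) and between-subtype groups
#' (input-hidden, hidden-rc_readout, input-rc_readout), splitting the
#' between groups by direction — forward (towards the readout side) versus
#' backward — and every group by sign (excitatory `w > 0` versus inhibitory
#' `w < 0`).
#'
#' @param pattern A `"wiring_pattern"`.
#' @return List with `connections` (data frame: `from`, `to`, `group`,
#'   `direction`, `sign`, `weight`, `abs_weight`) and `counts` (table of
#'   connection counts per group/direction/sign).
#' @export
strength_distributions <- function(pattern) {
  W <- pattern$W
  nz <- which(W != 0, arr.ind = TRUE)
  # W[i, j] couples upstream j to downstream i
  from <- pattern$subtype[nz[, 2]]
  to <- pattern$subtype[nz[, 1]]
  w <- W[nz]
  order_rank <- c(input = 1L, hidden = 2L, rc_readout = 3L)
  group <- ifelse(from == to, paste0("within_", from),
                  paste0(pmin(order_rank[from], order_rank[to]), "-",
                         pmax(order_rank[from], order_rank[to])))
  pair_names <- c("1-2" = "input-hidden", "2-3" = "hidden-rc_readout",
                  "1-3" = "input-rc_readout")
  group <- ifelse(group %in% names(pair_names), pair_names[group], group)
  direction <- ifelse(from == to, "lateral",
                      ifelse(order_rank[from] < order_rank[to],
                             "forward", "backward"))
  df <- data.frame(from = from, to = to, group = group,
                   direction = direction,
                   sign = ifelse(w > 0, "excitatory", "inhibitory"),
                   weight = w, abs_weight = abs(w),
                   stringsAsFactors = FALSE)
  list(connections = df,
       counts = table(group = df$group, direction = df$direction,
                      sign = df$sign))
}

#' Embed dynamics into the top three principal components
#'
#' Standardizes each selected unit's time series to zero mean and unit
#' variance (constant units are dropped with a warning), then projects onto
#' the leading three principal components of the covariance.
#'
#' @param trajectory A `"reservoir_trajectory"`, or a plain T x p numeric
#'   matrix (then `labels` may be supplied).
#' @param units Which dynamics to embed when a trajectory is given:
#'   `"reservoir"` (all units' activations), `"rc_readout"` (RC-readout
#'   activations) or `"readout"` (readout outputs `z`).
#' @param labels Optional per-timestep labels when `trajectory` is a matrix.
#' @return An object of class `"embedded3d"`: list with `points` (T x 3
#'   scores), `cumulative_contribution` (explained-variance fractions of
#'   PCs 1..3, non-decreasing) and `labels`.
#' @export
embed_pca3 <- function(trajectory,
                       units = c("reservoir", "rc_readout", "readout"),
                       labels = NULL) {
  if (inherits(trajectory, "reservoir_trajectory")) {
    units <- match.arg(units)
    rco <- NULL
    M <- switch(units,
                reservoir = trajectory$r,
                rc_readout = {
                  n <- ncol(trajectory$r)
                  trajectory$r[, (2 * n / 3 + 1):n, drop = FALSE]
                },
                readout = trajectory$z)
    labels <- trajectory$labels
  } else {
    M <- as.matrix(trajectory)
  }
  if (nrow(M) <= 3) stop("need more than 3 timesteps for a 3D embedding")
  sds <- apply(M, 2, sd)
  keep <- sds > 0 & is.finite(sds)
  if (!all(keep)) {
    warning(sum(!keep), " constant or non-finite unit(s) dropped before PCA")
  }
  M <- M[, keep, drop = FALSE]
  if (ncol(M) < 3) stop("need at least 3 non-constant units")
  Z <- scale(M)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1:3, drop = FALSE]
  contrib <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  structure(list(points = scores,
                 cumulative_contribution = contrib[1:3],
                 labels = labels),
            class = "embedded3d")
}

#' Stimulus-separation score of an embedding
#'
#' Clusters the non-blank embedded points with k-means (k = number of
#' distinct stimulus labels, 10 restarts) and returns the normalized mutual
#' information between the true stimulus labels and the cluster labels.
#'
#' @param embedded An [embed_pca3()] object (with labels).
#' @param n_clusters Number of clusters; defaults to the number of distinct
#'   non-blank labels.
#' @param seed Integer seed for the k-means restarts.
#' @param nstart k-means restarts (default 10).
#' @return NMI in `[0, 1]`.
#' @export
separation_nmi <- function(embedded, n_clusters = NULL, seed = 1L,
                           nstart = 10L) {
  keep <- embedded$labels != "blank"
  pts <- embedded$points[keep, , drop = FALSE]
  labs <- embedded$labels[keep]
  k <- if (is.null(n_clusters)) length(unique(labs)) else n_clusters
  if (sum(keep) < k) stop("fewer labelled points than clusters")
  cl <- with_seed(seed, kmeans(pts, centers = k, nstart = nstart))
  nmi(labs, cl$cluster)
}

#' Box-counting fractal dimension of a 3D point set
#'
#' Overlays the points' bounding cube with an axis-aligned grid of boxes of
#' side `epsilon`, counts occupied boxes at each ladder value, and returns
#' the least-squares slope of `log N(epsilon)` against `log(1/epsilon)`.
#' For finite trajectories this is a slope fit, not a limit; clustered
#' attractor-like sets yield fractional values below 1.
#'
#' @param points T x 3 numeric matrix.
#' @param epsilons Decreasing box sizes; default: 8 logarithmically spaced
#'   values between half and 1/64 of the bounding-cube edge.
#' @return The estimated fractal dimension (0 for a degenerate point set).
#' @export
fractal_dimension <- function(points, epsilons = NULL) {
  points <- as.matrix(points)
  mins <- apply(points, 2, min)
  edge <- max(apply(points, 2, max) - mins)
  if (edge == 0) return(0)
  if (is.null(epsilons)) {
    epsilons <- exp(seq(log(edge / 2), log(edge / 64), length.out = 8))
  }
  if (length(epsilons) < 3) stop("need at least 3 epsilon values")
  counts <- vapply(epsilons, function(eps) {
    idx <- floor(sweep(points, 2, mins) / eps)
    nrow(unique(idx))
  }, 0L)
  unname(coef(lm(log(counts) ~ log(1 / epsilons)))[2])
}

#' Voxel-occupancy volume of a 3D trajectory
#'
#' Counts the distinct voxels of side `voxel_size` visited by the points and
#' returns `count * voxel_size^3`, a discretized measure of the region of
#' state space the trajectory occupies.  Use [normalize_volumes()] to scale
#' a comparison set so its maximum is 1.
#'
#' @param points T x 3 numeric matrix.
#' @param voxel_size Voxel side length; default: bounding-cube edge / 50
#'   (or 1 for a degenerate single-point set).
#' @return Occupied volume (positive; a single repeated point occupies one
#'   voxel).
#' @export
trajectory_volume <- function(points, voxel_size = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 1) stop("need at least one point")
  mins <- apply(points, 2, min)
  if (is.null(voxel_size)) {
    edge <- max(apply(points, 2, max) - mins)
    voxel_size <- if (edge > 0) edge / 50 else 1
  }
  idx <- floor(sweep(points, 2, mins) / voxel_size)
  nrow(unique(idx)) * voxel_size^3
}

#' @rdname trajectory_volume
#' @param volumes Numeric vector of volumes from a comparison set.
#' @export
normalize_volumes <- function(volumes) {
  volumes / max(volumes)
}

#' Characterize one pattern under the oriented probe stimuli
#'
#' The full per-entity characterization pipeline: drive the pattern with the
#' eight-stimulus probe series, embed the reservoir activations into three
#' principal components, and measure the box-counting fractal dimension, the
#' k-means stimulus-separation NMI and the voxel trajectory volume, together
#' with the input-to-readout transfer-entropy map.
#'
#' @param pattern A `"wiring_pattern"`.
#' @param W_out Readout weights (defaults to a fresh standard-normal draw).
#' @param probe A probe `"stimulus_series"` (default [make_probe_series()]).
#' @param params A [reservoir_params()] object.
#' @param info An [info_config()] object.
#' @param seed Integer seed.
#' @return List with `fd`, `separation_nmi`, `volume` (unnormalized),
#'   `te_map`, `embedded` and `cumulative_contribution`.
#' @export
characterize_pattern <- function(pattern, W_out = NULL,
                                 probe = NULL,
                                 params = reservoir_params(),
                                 info = info_config(), seed = 1L) {
  if (is.null(probe)) probe <- make_probe_series(seed = derive_seed(seed, 4L))
  if (is.null(W_out)) W_out <- init_readout(params, derive_seed(seed, 5L))
  traj <- run_reservoir(pattern, W_out, probe, params,
                        seed = derive_seed(seed, 6L))
  emb <- embed_pca3(traj, units = "reservoir")
  tm <- te_matrix(probe$vectors,
                  traj$r[, subtype_index(pattern, "rc_readout"),
                         drop = FALSE],
                  info)
  list(fd = fractal_dimension(emb$points),
       separation_nmi = separation_nmi(emb, seed = derive_seed(seed, 7L)),
       volume = trajectory_volume(emb$points),
       te_map = tm,
       embedded = emb,
       cumulative_contribution = emb$cumulative_contribution)
}
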