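# Independent oracles used to cross-check package computations.

# Spectral radius by power iteration: the geometric-mean growth rate of
# ||W^k v|| converges to the largest eigenvalue magnitude even when the
# leading eigenvalues form a complex pair.
power_iteration_radius <- function(W, iters = 5000L, burn = 500L) {
  set.seed(99)
  v <- rnorm(nrow(W))
  v <- v / sqrt(sum(v^2))
  lg <- numeric(iters)
  for (k in seq_len(iters)) {
    w <- as.vector(W %*% v)
    nw <- sqrt(sum(w^2))
    lg[k] <- log(nw)
    v <- w / nw
  }
  exp(mean(lg[(burn + 1L):iters]))
}

# Brute-force plug-in transfer entropy: explicit probability tables over all
# observed (y_{t+1}, y-history, x-history) tuples, written independently of
# the package's tabulate/array path.
brute_te <- function(x, y, n_bins, k = 1L, l = 1L) {
  disc <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) return(rep(1L, length(v)))
    pmin(floor((v - r[1]) / (r[2] - r[1]) * n_bins) + 1L, n_bins)
  }
  bx <- disc(x); by <- disc(y)
  h <- max(k, l)
  n <- length(x)
  tup <- data.frame(
    y1 = by[(h + 1):n],
    yh = sapply((h:(n - 1)), function(t) {
      paste(by[(t - k + 1):t], collapse = ",")
    }),
    xh = sapply((h:(n - 1)), function(t) {
      paste(bx[(t - l + 1):t], collapse = ",")
    }),
    stringsAsFactors = FALSE)
  N <- nrow(tup)
  te <- 0
  for (key in unique(paste(tup$y1, tup$yh, tup$xh, sep = "|"))) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    n_xyy1 <- sum(tup$y1 == parts[1] & tup$yh == parts[2] &
                    tup$xh == parts[3])
    n_yhxh <- sum(tup$yh == parts[2] & tup$xh == parts[3])
    n_y1yh <- sum(tup$y1 == parts[1] & tup$yh == parts[2])
    n_yh <- sum(tup$yh == parts[2])
    te <- te + (n_xyy1 / N) *
      log2((n_xyy1 / n_yhxh) / (n_y1yh / n_yh))
  }
  te
}

# Brute-force plug-in mutual information over explicit joint tables.
brute_mi <- function(x, y, n_bins) {
  disc <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) return(rep(1L, length(v)))
    pmin(floor((v - r[1]) / (r[2] - r[1]) * n_bins) + 1L, n_bins)
  }
  bx <- disc(x); by <- disc(y)
  N <- length(x)
  mi <- 0
  for (a in unique(bx)) for (b in unique(by)) {
    nab <- sum(bx == a & by == b)
    if (nab == 0) next
    mi <- mi + (nab / N) * log2(nab * N / (sum(bx == a) * sum(by == b)))
  }
  mi
}

# Brute-force non-dominated fronts by repeated scans of the full pairwise
# dominance relation.
brute_fronts <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  dominated_by <- function(i, alive) {
    for (j in alive) {
      if (j != i && all(points[j, ] <= points[i, ]) &&
          any(points[j, ] < points[i, ])) {
        return(TRUE)
      }
    }
    FALSE
  }
  fronts <- list()
  alive <- seq_len(n)
  while (length(alive) > 0) {
    f <- alive[!vapply(alive, dominated_by, TRUE, alive = alive)]
    fronts[[length(fronts) + 1L]] <- f
    alive <- setdiff(alive, f)
  }
  fronts
}

# BFS distances on the lattice graph via igraph.
bfs_distances <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  D <- igraph::distances(g)
  dimnames(D) <- NULL
  D
}

# Tiny reusable fixtures.
tiny_params <- function() reservoir_params()
fast_hebb <- function() hebb_params(t_tune = 20L)

# A short training series used by simulation-heavy unit tests.
tiny_series <- function(seed = 1L, n_scenes = 4L, n_clips = 10L) {
  img <- generate_surrogate_landscape(seed, 32, 32)
  make_saccade_series(list(img), n_scenes = n_scenes, n_clips = n_clips,
                      scene_size = 16, clip_size = 4, seed = seed)
}

# The scaled baseline evolution run shared by the acceptance tests; computed
# once per test session.
.run_cache <- new.env(parent = emptyenv())
get_desk_manifest <- function() {
  if (is.null(.run_cache$manifest)) {
    .run_cache$manifest <- run_condition(1L, scale = "desk", seed = 1L)
  }
  .run_cache$manifest
}
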