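#' Non-dominated sorting (minimization convention)
#'
#' Partitions objective vectors into Pareto fronts: front 1 contains points
#' dominated by none; front k contains points dominated only by earlier
#' fronts.  A point dominates another when it is no worse in every objective
#' and strictly better in at least one.
#'
#' @param points Numeric matrix, one objective vector per row (all
#'   objectives minimized).
#' @return List of integer vectors of row indices, one per front; empty
#'   input gives an empty list.
#' @export
non_dominated_sort <- function(points) {
  points <- as.matrix(points)
  N <- nrow(points)
  if (N == 0) return(list())
  leq <- matrix(TRUE, N, N)
  lt <- matrix(FALSE, N, N)
  for (m in seq_len(ncol(points))) {
    leq <- leq & outer(points[, m], points[, m], "<=")
    lt <- lt | outer(points[, m], points[, m], "<")
  }
  dominates <- leq & lt          # [i, j]: i dominates j
  counts <- colSums(dominates)
  fronts <- list()
  assigned <- logical(N)
  while (!all(assigned)) {
    f <- which(!assigned & counts == 0)
    fronts[[length(fronts) + 1L]] <- f
    assigned[f] <- TRUE
    counts <- counts - colSums(dominates[f, , drop = FALSE])
    counts[assigned] <- Inf
  }
  fronts
}

#' Crowding distance within a front
#'
#' The standard NSGA-II diversity measure: per objective, boundary points
#' get infinite distance and interior points accumulate the gap between
#' their neighbours normalized by the objective's range (objectives with
#' zero range contribute nothing).
#'
#' @param front Numeric matrix of the front's objective vectors (one row per
#'   point).
#' @return Numeric vector of crowding distances.
#' @export
crowding_distance <- function(front) {
  front <- as.matrix(front)
  N <- nrow(front)
  if (N == 0) return(numeric(0))
  d <- numeric(N)
  for (m in seq_len(ncol(front))) {
    ord <- order(front[, m])
    rng <- front[ord[N], m] - front[ord[1], m]
    d[ord[1]] <- Inf
    d[ord[N]] <- Inf
    if (rng > 0 && N > 2) {
      for (i in 2:(N - 1)) {
        d[ord[i]] <- d[ord[i]] +
          (front[ord[i + 1], m] - front[ord[i - 1], m]) / rng
      }
    }
  }
  d
}

#' Block crossover of two wiring patterns
#'
#' Tiles the weight matrix into aligned `block_size` x `block_size` regions;
#' each tile is copied whole from one parent or the other with probability
#' one half.  The child is rescaled to unit spectral radius and inherits the
#' (shared) subtype labels and grid coordinates.
#'
#' @param parent_a,parent_b `"wiring_pattern"` objects of identical
#'   dimensions.
#' @param block_size Side of the square tiles (default 2).
#' @param id Identifier for the child pattern.
#' @param normalize Rescale the child to spectral radius 1 (default `TRUE`).
#' @return The child `"wiring_pattern"`.
#' @export
crossover <- function(parent_a, parent_b, block_size = 2L,
                      id = "child", normalize = TRUE) {
  n <- nrow(parent_a$W)
  if (!all(dim(parent_a$W) == dim(parent_b$W))) {
    stop("parents must have identical dimensions")
  }
  nt <- ceiling(n / block_size)
  pick <- matrix(runif(nt * nt) < 0.5, nt, nt)
  mask <- kronecker(pick, matrix(TRUE, block_size, block_size))[1:n, 1:n]
  W <- ifelse(mask, parent_a$W, parent_b$W)
  child <- parent_a
  child$W <- if (normalize) safe_normalize(W) else W
  child$id <- id
  child
}

#' Block mutation of a wiring pattern
#'
#' Selects one aligned `block_size` x `block_size` region at random; with
#' probability `p_delete` the region is zeroed (connection removal),
#' otherwise it is refilled with fresh entries that are nonzero with
#' probability `sparsity` and valued Uniform\[-0.5, 0.5\] (connection
#' introduction at the initial sparsity rate).  The result is rescaled to
#' unit spectral radius.
#'
#' @param pattern A `"wiring_pattern"`.
#' @param block_size Side of the mutated square region (default 2).
#' @param p_delete Probability the mutation deletes rather than adds
#'   (default 0.5).
#' @param sparsity Nonzero fraction used when refilling (default 0.2).
#' @param n_regions Number of regions mutated per event (default 1).
#' @param normalize Rescale to spectral radius 1 (default `TRUE`).
#' @return The mutated `"wiring_pattern"`.
#' @export
mutate_pattern <- function(pattern, block_size = 2L, p_delete = 0.5,
                           sparsity = 0.2, n_regions = 1L, normalize = TRUE) {
  n <- nrow(pattern$W)
  nt <- ceiling(n / block_size)
  W <- pattern$W
  for (k in seq_len(n_regions)) {
    ti <- sample.int(nt, 1L)
    tj <- sample.int(nt, 1L)
    rows <- (block_size * (ti - 1L) + 1L):min(block_size * ti, n)
    cols <- (block_size * (tj - 1L) + 1L):min(block_size * tj, n)
    if (runif(1) < p_delete) {
      W[rows, cols] <- 0
    } else {
      nb <- length(rows) * length(cols)
      block <- numeric(nb)
      nz <- runif(nb) < sparsity
      block[nz] <- runif(sum(nz), -0.5, 0.5)
      W[rows, cols] <- block
    }
  }
  pattern$W <- if (normalize) safe_normalize(W) else W
  pattern
}

# Normalization guard for GA operators: a child whose spectral radius
# vanishes (all-zero or nilpotent after deletion) cannot be rescaled and is
# replaced by a fresh random pattern drawn from the current RNG stream.
safe_normalize <- function(W, sparsity = 0.2) {
  rho <- spectral_radius(W)
  if (rho < 1e-12) {
    W <- random_wiring_matrix(nrow(W), sparsity)
    rho <- spectral_radius(W)
  }
  W / rho
}
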