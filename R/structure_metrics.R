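#' Build the 3D grid layout of reservoir units
#'
#' Units are placed on an integer lattice of `n_layers` stacked
#' `layer_rows` x `layer_cols` layers, one subtype per layer (input, hidden,
#' RC-readout from bottom to top).  Lattice edges connect neighbouring units
#' at uniform distance 1; by default the neighbourhood includes diagonal
#' neighbours (all units within one grid step on every axis, the
#' 26-neighbourhood), so the resulting Floyd-Warshall distance equals the
#' Chebyshev distance.  `neighbourhood = "vonneumann"` restricts edges to
#' axis-aligned neighbours (Manhattan distance).
#'
#' @param n_layers,layer_rows,layer_cols Grid dimensions; their product is
#'   the number of units.
#' @param neighbourhood `"moore"` (default, includes diagonals) or
#'   `"vonneumann"` (axis-aligned only).
#' @return An object of class `"grid_layout"`: list with `coords`
#'   (n x 3 integer matrix), `lattice_edges` (n x n 0/1 adjacency) and `D`
#'   (n x n shortest-distance matrix from Floyd-Warshall).
#' @export
build_layout <- function(n_layers = 3L, layer_rows = 4L, layer_cols = 4L,
                         neighbourhood = c("moore", "vonneumann")) {
  neighbourhood <- match.arg(neighbourhood)
  if (n_layers < 1 || layer_rows < 1 || layer_cols < 1) {
    stop("grid dimensions must be positive")
  }
  coords <- as.matrix(expand.grid(col = seq_len(layer_cols) - 1L,
                                  row = seq_len(layer_rows) - 1L,
                                  layer = seq_len(n_layers) - 1L))
  dimnames(coords) <- NULL
  n <- nrow(coords)
  d1 <- abs(outer(coords[, 1], coords[, 1], "-"))
  d2 <- abs(outer(coords[, 2], coords[, 2], "-"))
  d3 <- abs(outer(coords[, 3], coords[, 3], "-"))
  adj <- if (neighbourhood == "moore") {
    (pmax(d1, d2, d3) == 1) * 1
  } else {
    (d1 + d2 + d3 == 1) * 1
  }
  A <- ifelse(adj == 1, 1, Inf)
  diag(A) <- 0
  structure(list(coords = coords, lattice_edges = adj,
                 D = floyd_warshall(A), neighbourhood = neighbourhood),
            class = "grid_layout")
}

#' All-pairs shortest paths by Floyd-Warshall
#'
#' @param A n x n matrix of direct edge lengths (`Inf` for no edge, 0 on the
#'   diagonal).
#' @return The n x n shortest-distance matrix.
#' @export
floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- A
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

#' Coupling cost of a wiring matrix on a grid layout
#'
#' The total wiring cost `C = sum_ij |W_ij| D_ij`, where `D` holds the
#' shortest grid distances of the layout.  The absolute value keeps the cost
#' non-negative so that inhibitory connections cannot cancel it; the literal
#' signed sum is available with `signed = TRUE` for audit.
#'
#' @param W Square weight matrix.
#' @param layout A [build_layout()] object (or any list with a matching
#'   `D` matrix).
#' @param signed Use the raw signed weights instead of `|W|`.
#' @return Total coupling cost (non-negative unless `signed`).
#' @export
coupling_cost <- function(W, layout, signed = FALSE) {
  if (!all(dim(W) == dim(layout$D))) {
    stop("weight matrix and layout dimensions do not match")
  }
  if (signed) sum(W * layout$D) else sum(abs(W) * layout$D)
}

#' Connection density
#'
#' Fraction of nonzero entries among all `n^2` entries of the internal
#' weight matrix (the diagonal counts unless `exclude_diagonal`).
#'
#' @param W Square weight matrix.
#' @param exclude_diagonal Drop the diagonal from the denominator and count.
#' @return Density in `[0, 1]`.
#' @export
connection_density <- function(W, exclude_diagonal = FALSE) {
  if (nrow(W) != ncol(W)) stop("'W' must be square")
  if (exclude_diagonal) {
    off <- row(W) != col(W)
    mean(W[off] != 0)
  } else {
    mean(W != 0)
  }
}

#' Newman modularity of a wiring matrix
#'
#' Builds the undirected weighted graph with edge weights
#' `|W_ij| + |W_ji|` and maximizes Newman modularity with the fast greedy
#' agglomerative algorithm, returning the best Q and the unit-to-module
#' assignment.
#'
#' @param W Square weight matrix.
#' @return List with `Q` (modularity of the best partition; 0 for an empty
#'   graph) and `membership` (integer module id per unit).
#' @export
modularity_q <- function(W) {
  n <- nrow(W)
  S <- abs(W) + t(abs(W))
  diag(S) <- 0
  if (all(S == 0)) {
    return(list(Q = 0, membership = rep(1L, n)))
  }
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  fc <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  list(Q = max(fc$modularity), membership = as.integer(fc$membership))
}

#' Clustering coefficient and mean shortest path of a binarized pattern
#'
#' Binarizes the nonzero connections into a graph and reports the average
#' local clustering coefficient and the mean shortest path length over
#' connected ordered pairs.  By default the graph is kept directed (each
#' nonzero `W_ij` is an arc `j -> i` in dynamics terms; for these statistics
#' only the arc set matters): the clustering coefficient is the directed
#' (Fagiolo) local coefficient and path lengths follow arc direction.  Set
#' `directed = FALSE` for the undirected union graph.
#'
#' @param W Square weight matrix.
#' @param directed Use directed clustering and paths (default `TRUE`).
#' @return List with `clustering` and `avg_path`.
#' @export
clustering_and_path <- function(W, directed = TRUE) {
  n <- nrow(W)
  A <- (W != 0) * 1
  diag(A) <- 0
  if (!directed) A <- ((A + t(A)) > 0) * 1
  g <- igraph::graph_from_adjacency_matrix(A, mode = if (directed)
    "directed" else "undirected")
  dmat <- igraph::distances(g, mode = "out")
  finite <- is.finite(dmat) & row(dmat) != col(dmat)
  if (sum(finite) < 2) stop("fewer than 2 reachable ordered pairs")
  avg_path <- mean(dmat[finite])
  if (directed) {
    # Fagiolo directed local clustering (total), isolates counted as 0
    S <- A + t(A)
    num <- diag(S %*% S %*% S)
    d_tot <- rowSums(A) + colSums(A)
    d_bi <- diag(A %*% A)
    denom <- 2 * (d_tot * (d_tot - 1) - 2 * d_bi)
    cl <- ifelse(denom > 0, num / denom, 0)
  } else {
    cl <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  }
  list(clustering = mean(cl), avg_path = avg_path)
}

#' Structural metric record of a wiring pattern
#'
#' Convenience wrapper computing the full structural description used per
#' pattern: coupling cost, density, modularity, clustering and average
#' shortest path length.
#'
#' @param pattern A `"wiring_pattern"`.
#' @param layout A [build_layout()] object.
#' @return List with `cost`, `density`, `modularity`, `module_assignment`,
#'   `clustering`, `avg_path`.
#' @export
structure_record <- function(pattern, layout) {
  mod <- modularity_q(pattern$W)
  cp <- clustering_and_path(pattern$W)
  list(cost = coupling_cost(pattern$W, layout),
       density = connection_density(pattern$W),
       modularity = mod$Q,
       module_assignment = mod$membership,
       clustering = cp$clustering,
       avg_path = cp$avg_path)
}
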