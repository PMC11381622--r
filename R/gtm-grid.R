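#' Build the latent lattice
#'
#' A regular `side` x `side` grid of latent nodes spanning `[-1, 1]^2`.
#' Nodes are indexed row-major from the top-left corner (row 1 is the top of
#' the map, columns run left to right), and this indexing is shared by all
#' map layers so different layers are directly comparable.
#'
#' @param side lattice side length (>= 2); the model has `K = side^2` nodes.
#' @return A list of class `latent_grid` with `side`, `K`, `nodes` (K x 2
#'   matrix of latent coordinates), and `row`/`col` lattice indices per node.
#' @export
#' @examples
#' g <- build_latent_grid(15)
#' g$K  # 225 micro-cluster centres
build_latent_grid <- function(side) {
  side <- as.integer(side)
  if (is.na(side) || side < 2L) {
    stop("side must be an integer >= 2")
  }
  xs <- seq(-1, 1, length.out = side)
  ys <- seq(1, -1, length.out = side)  # row 1 at the top
  row <- rep(seq_len(side), each = side)
  col <- rep(seq_len(side), times = side)
  nodes <- cbind(u1 = xs[col], u2 = ys[row])
  structure(list(side = side, K = side * side, nodes = nodes,
                 row = row, col = col),
            class = "latent_grid")
}

# Degenerate single-node grid (internal; used for the K = 1 limit).
single_node_grid <- function() {
  structure(list(side = 1L, K = 1L,
                 nodes = matrix(0, 1L, 2L, dimnames = list(NULL, c("u1", "u2"))),
                 row = 1L, col = 1L),
            class = "latent_grid")
}

#' Build the radial-basis-function mapping basis
#'
#' `M = rbf_side^2` isotropic Gaussian basis functions centred on a regular
#' `rbf_side` x `rbf_side` lattice over `[-1, 1]^2`, with common width
#' `width_factor` times the spacing between adjacent centres, plus a constant
#' bias column. The design matrix `Phi` (`K x (M + 1)`) evaluates the basis at
#' every latent node and parameterises the nonlinear map from latent to data
#' space.
#'
#' @param grid a [build_latent_grid()] object.
#' @param rbf_side side of the RBF centre lattice (>= 1).
#' @param width_factor positive multiple of the centre spacing (default 1).
#' @return A list of class `rbf_basis` with `rbf_side`, `M`, `centres`,
#'   `width`, `width_factor` and `Phi`.
#' @export
#' @examples
#' b <- build_rbf_basis(build_latent_grid(15), 14)
#' b$M          # 196 basis functions
#' ncol(b$Phi)  # 197 columns including the bias
build_rbf_basis <- function(grid, rbf_side, width_factor = 1.0) {
  stopifnot(inherits(grid, "latent_grid"))
  rbf_side <- as.integer(rbf_side)
  if (is.na(rbf_side) || rbf_side < 1L) {
    stop("rbf_side must be an integer >= 1")
  }
  if (!is.finite(width_factor) || width_factor <= 0) {
    stop("width_factor must be positive")
  }
  if (rbf_side > 1L) {
    cs <- seq(-1, 1, length.out = rbf_side)
    spacing <- cs[2] - cs[1]
  } else {
    cs <- 0
    spacing <- 2
  }
  centres <- as.matrix(expand.grid(c1 = cs, c2 = cs))
  width <- width_factor * spacing
  d2 <- squared_distances(grid$nodes, centres)
  phi <- exp(-d2 / (2 * width^2))
  dimnames(phi) <- NULL
  phi <- cbind(phi, 1)  # bias column last
  structure(list(rbf_side = rbf_side, M = rbf_side^2, centres = centres,
                 width = width, width_factor = width_factor, Phi = phi),
            class = "rbf_basis")
}

# Bias-only basis (internal): constant map, one effective component shape.
bias_basis <- function(grid) {
  structure(list(rbf_side = 0L, M = 0L,
                 centres = matrix(numeric(0), 0L, 2L),
                 width = NA_real_, width_factor = NA_real_,
                 Phi = matrix(1, grid$K, 1L, dimnames = list(NULL, "bias"))),
            class = "rbf_basis")
}
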