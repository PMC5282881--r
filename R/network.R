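#' Build an all-atom elastic network
#'
#' Connects every pair of nodes whose equilibrium separation is at most the
#' cutoff \code{Rc} by a Hookean spring of uniform force constant
#' \code{gamma}. The potential of the network is
#' \deqn{V = \sum_{j<l} \tfrac{1}{2} K_{jl} (r_{jl} - r^0_{jl})^2,}
#' with \eqn{K_{jl} = \gamma} when \eqn{r^0_{jl} \le R_c} and 0 otherwise.
#' The cutoff boundary is inclusive. Pair enumeration is an exact all-pairs
#' distance search.
#'
#' @param x An \code{"anm_selection"} or an N x 3 coordinate matrix
#'   (Angstrom).
#' @param cutoff Interaction cutoff \code{Rc} in Angstrom (> 0).
#' @param gamma Spring force constant in kcal/mol/A^2 (> 0); the model's
#'   single energy scale.
#' @return An object of class \code{"elastic_network"}: list with
#'   \code{coords} (N x 3), \code{pairs} (M x 2 integer matrix, j < l),
#'   \code{r0} (length-M equilibrium distances), \code{gamma},
#'   \code{cutoff}.
#' @export
#' @examples
#' net <- build_network(make_fixture("tetrahedron", spacing = 3), cutoff = 5)
#' nrow(net$pairs)  # all 6 edges of the tetrahedron
build_network <- function(x, cutoff, gamma = 1) {
  xyz <- if (inherits(x, "anm_selection")) coords(x) else as.matrix(x)
  stopifnot(is.numeric(xyz), ncol(xyz) == 3L)
  if (nrow(xyz) < 2L) {
    stop("need at least 2 atoms to define a network", call. = FALSE)
  }
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0",
                                              call. = FALSE)
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0",
                                             call. = FALSE)
  d <- as.matrix(dist(xyz))
  sel <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  ord <- order(sel[, 1L], sel[, 2L])
  sel <- sel[ord, , drop = FALSE]
  pairs <- cbind(j = as.integer(sel[, 1L]), l = as.integer(sel[, 2L]))
  structure(
    list(coords = unname(xyz), pairs = pairs,
         r0 = d[sel], gamma = gamma, cutoff = cutoff),
    class = "elastic_network"
  )
}

#' @export
print.elastic_network <- function(x, ...) {
  cat("Elastic network: ", nrow(x$coords), " nodes, ", nrow(x$pairs),
      " springs (Rc = ", x$cutoff, " A, gamma = ", x$gamma,
      " kcal/mol/A^2)\n", sep = "")
  invisible(x)
}

#' Harmonic potential energy of a displaced configuration
#'
#' Evaluates the network potential
#' \eqn{V = \sum \tfrac{1}{2}\gamma (r_{jl} - r^0_{jl})^2} over the stored
#' spring pairs at an arbitrary configuration. Zero at the equilibrium
#' coordinates by construction.
#'
#' @param network An \code{"elastic_network"}.
#' @param displaced_coords N x 3 matrix, same shape as the network
#'   coordinates.
#' @return Energy in kcal/mol.
#' @export
potential_energy <- function(network, displaced_coords) {
  stopifnot(inherits(network, "elastic_network"))
  xyz <- as.matrix(displaced_coords)
  if (!identical(dim(xyz), dim(network$coords))) {
    stop("displaced_coords must match the network coordinates in shape",
         call. = FALSE)
  }
  if (nrow(network$pairs) == 0L) return(0)
  dvec <- xyz[network$pairs[, 2L], , drop = FALSE] -
    xyz[network$pairs[, 1L], , drop = FALSE]
  r <- sqrt(rowSums(dvec^2))
  sum(0.5 * network$gamma * (r - network$r0)^2)
}

#' Analytic Hessian of the network potential
#'
#' Assembles the 3N x 3N second-derivative matrix of the harmonic network
#' potential at the equilibrium coordinates. For a spring between nodes j
#' and l with equilibrium bond vector \eqn{b = x_l - x_j}, the off-diagonal
#' 3 x 3 super-element is \eqn{-(\gamma / |b|^2)\, b b^T}; diagonal
#' super-elements are the negated sums of the off-diagonal blocks in their
#' row, which puts uniform translations in the null space to machine
#' precision.
#'
#' @param network An \code{"elastic_network"}.
#' @return Symmetric 3N x 3N numeric matrix, units kcal/mol/A^2.
#' @export
build_hessian <- function(network) {
  stopifnot(inherits(network, "elastic_network"))
  n <- nrow(network$coords)
  H <- matrix(0, 3L * n, 3L * n)
  if (nrow(network$pairs) == 0L) return(H)
  if (any(network$r0 == 0)) {
    stop("contact pair with zero equilibrium distance (duplicate ",
         "coordinates)", call. = FALSE)
  }
  g <- network$gamma
  for (p in seq_len(nrow(network$pairs))) {
    j <- network$pairs[p, 1L]
    l <- network$pairs[p, 2L]
    b <- network$coords[l, ] - network$coords[j, ]
    K <- (-g / sum(b * b)) * tcrossprod(b)
    jj <- (3L * (j - 1L) + 1L):(3L * j)
    ll <- (3L * (l - 1L) + 1L):(3L * l)
    H[jj, ll] <- H[jj, ll] + K
    H[ll, jj] <- H[ll, jj] + K
    H[jj, jj] <- H[jj, jj] - K
    H[ll, ll] <- H[ll, ll] - K
  }
  H
}
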