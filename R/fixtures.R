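# Run a block with a private, seeded RNG stream; the caller's global
# .Random.seed is untouched, so fixture generation is pure.
.with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

#' Deterministic toy structures for testing
#'
#' Generates small synthetic coordinate sets so that every operation in the
#' package can be exercised without any structure download. Atoms are
#' labeled as pseudo-residues (one CA atom per residue, glycine names) so
#' that the pulling-pair machinery works on them unchanged. Identical
#' arguments always produce bit-identical coordinates; optional jitter from
#' a seeded generator breaks the geometric symmetry of the exact solids,
#' avoiding degenerate eigenvalues whose eigenbasis is solver-dependent.
#'
#' Kinds:
#' \describe{
#'   \item{pair}{two atoms \code{spacing} apart (no internal modes on its
#'     own; useful for network/Hessian checks).}
#'   \item{triangle}{equilateral triangle of side \code{spacing}.}
#'   \item{tetrahedron}{regular tetrahedron of edge \code{spacing}.}
#'   \item{lattice}{\code{n_atoms} points of a cubic lattice with
#'     lattice constant \code{spacing}.}
#'   \item{helix}{\code{n_atoms} points on a helix with consecutive-point
#'     distance approximately \code{spacing} (alpha-helix-like geometry).}
#'   \item{two_clusters}{two jittered lattices of \code{n_atoms/2} points
#'     each, separated so the minimum inter-cluster distance is at least
#'     \code{gap} — a disconnected network at any cutoff below \code{gap}.}
#'   \item{linear_chain}{collinear points \code{spacing} apart; note a
#'     straight chain has a seventh zero mode (rotation about its axis).}
#' }
#'
#' @param kind One of \code{"pair"}, \code{"triangle"},
#'   \code{"tetrahedron"}, \code{"lattice"}, \code{"helix"},
#'   \code{"two_clusters"}, \code{"linear_chain"}.
#' @param n_atoms Number of atoms (fixed at 2/3/4 for pair, triangle,
#'   tetrahedron).
#' @param spacing Characteristic length in Angstrom (default 3.0, a typical
#'   heavy-atom contact distance).
#' @param jitter Amplitude of uniform coordinate jitter in Angstrom
#'   (default 0).
#' @param seed Seed for the jitter stream (default 1).
#' @param gap Minimum inter-cluster distance for \code{two_clusters}
#'   (default 20).
#' @return An \code{"anm_selection"} whose pseudo-residues are numbered
#'   1..n.
#' @export
#' @examples
#' make_fixture("helix", n_atoms = 30, jitter = 0.2, seed = 7)
make_fixture <- function(kind, n_atoms = NULL, spacing = 3.0, jitter = 0,
                         seed = 1L, gap = 20) {
  kind <- match.arg(kind, c("pair", "triangle", "tetrahedron", "lattice",
                            "helix", "two_clusters", "linear_chain"))
  fixed_n <- c(pair = 2L, triangle = 3L, tetrahedron = 4L)
  if (kind %in% names(fixed_n)) {
    if (is.null(n_atoms)) n_atoms <- fixed_n[[kind]]
    if (n_atoms != fixed_n[[kind]]) {
      stop("kind '", kind, "' has exactly ", fixed_n[[kind]], " atoms",
           call. = FALSE)
    }
  } else if (is.null(n_atoms)) {
    stop("n_atoms is required for kind '", kind, "'", call. = FALSE)
  }
  n_atoms <- as.integer(n_atoms)
  xyz <- switch(kind,
    pair = rbind(c(0, 0, 0), c(spacing, 0, 0)),
    triangle = spacing * rbind(c(0, 0, 0), c(1, 0, 0),
                               c(0.5, sqrt(3) / 2, 0)),
    tetrahedron = (spacing / (2 * sqrt(2))) *
      rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
    lattice = .lattice_coords(n_atoms, spacing),
    helix = .helix_coords(n_atoms, spacing),
    two_clusters = .two_cluster_coords(n_atoms, spacing, gap),
    linear_chain = cbind(spacing * (seq_len(n_atoms) - 1L), 0, 0)
  )
  if (jitter > 0) {
    j <- .with_local_seed(seed,
      matrix(runif(3L * n_atoms, -jitter, jitter), n_atoms, 3L))
    xyz <- xyz + j
  }
  .selection_from_coords(xyz, label = paste0("fixture:", kind))
}

.lattice_coords <- function(n, spacing) {
  k <- ceiling(n^(1 / 3))
  g <- expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k))
  spacing * as.matrix(g[seq_len(n), , drop = FALSE])
}

# Alpha-helix-like geometry scaled so consecutive points sit ~`spacing`
# apart (native CA helix: radius 2.3 A, rise 1.5 A, 100 deg per residue,
# consecutive CA distance 3.8 A).
.helix_coords <- function(n, spacing) {
  s <- spacing / 3.8
  r <- 2.3 * s
  rise <- 1.5 * s
  th <- (seq_len(n) - 1L) * 100 * pi / 180
  cbind(r * cos(th), r * sin(th), rise * (seq_len(n) - 1L))
}

.two_cluster_coords <- function(n, spacing, gap) {
  n1 <- n %/% 2L
  n2 <- n - n1
  a <- .lattice_coords(n1, spacing)
  b <- .lattice_coords(n2, spacing)
  shift <- max(a[, 1L]) - min(b[, 1L]) + gap
  rbind(a, cbind(b[, 1L] + shift, b[, 2L], b[, 3L]))
}

.selection_from_coords <- function(xyz, label) {
  n <- nrow(xyz)
  at <- data.frame(
    serial = seq_len(n),
    atom_name = "CA",
    alt_loc = "",
    residue_name = "GLY",
    chain_id = "A",
    residue_number = seq_len(n),
    insertion_code = "",
    occupancy = 1,
    element = "C",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    stringsAsFactors = FALSE
  )
  structure(
    list(label = label, atoms = at,
         calpha = setNames(seq_len(n), paste("A", seq_len(n), "",
                                             sep = ":")),
         missing_calpha = character(0)),
    class = "anm_selection"
  )
}

#' Finite-difference Hessian oracle
#'
#' Central-difference second derivatives of \code{\link{potential_energy}},
#' symmetrized. Entirely independent of the analytic assembly in
#' \code{\link{build_hessian}}, so the two can cross-validate each other on
#' small fixtures; agreement is O(step^2).
#'
#' @param network An \code{"elastic_network"} with at most 50 atoms.
#' @param step Displacement step in Angstrom (default \code{1e-4}).
#' @return Symmetric 3N x 3N matrix.
#' @export
finite_difference_hessian <- function(network, step = 1e-4) {
  stopifnot(inherits(network, "elastic_network"), step > 0)
  n <- nrow(network$coords)
  if (n > 50L) {
    stop("finite-difference oracle is limited to 50 atoms", call. = FALSE)
  }
  m <- 3L * n
  H <- matrix(0, m, m)
  bump <- function(a, s) {
    x <- network$coords
    x[(a - 1L) %/% 3L + 1L, (a - 1L) %% 3L + 1L] <-
      x[(a - 1L) %/% 3L + 1L, (a - 1L) %% 3L + 1L] + s
    x
  }
  for (a in seq_len(m)) {
    for (b in a:m) {
      xpp <- bump(a, step); xpp <- .bump_at(xpp, b, step)
      xpm <- bump(a, step); xpm <- .bump_at(xpm, b, -step)
      xmp <- bump(a, -step); xmp <- .bump_at(xmp, b, step)
      xmm <- bump(a, -step); xmm <- .bump_at(xmm, b, -step)
      H[a, b] <- (potential_energy(network, xpp) -
                    potential_energy(network, xpm) -
                    potential_energy(network, xmp) +
                    potential_energy(network, xmm)) / (4 * step^2)
      H[b, a] <- H[a, b]
    }
  }
  (H + t(H)) / 2
}

.bump_at <- function(x, a, s) {
  x[(a - 1L) %/% 3L + 1L, (a - 1L) %% 3L + 1L] <-
    x[(a - 1L) %/% 3L + 1L, (a - 1L) %% 3L + 1L] + s
  x
}

#' Independent brute-force stiffness oracle
#'
#' Recomputes both stiffness observables through a deliberately different
#' route than the main path: the Hessian is assembled by a literal
#' second-derivative loop, diagonalized by singular value decomposition
#' (a different LAPACK driver than the symmetric eigensolver used by
#' \code{\link{compute_modes}}), and the observables are evaluated as
#' straight scalar loops over the defining formulas. Intended purely as a
#' cross-check in tests on fixtures of at most 50 atoms.
#'
#' @param network An \code{"elastic_network"} (at most 50 atoms).
#' @param pair A \code{"pulling_pair"} for the directional measure.
#' @param units A \code{"unit_system"}.
#' @param n_modes Optional truncation (default: all internal modes).
#' @param zero_tol_rel Relative zero-mode threshold.
#' @return List with \code{k_protein} and \code{k_direct} in model units,
#'   plus \code{n_modes} used.
#' @export
reference_stiffness <- function(network, pair, units = unit_system(),
                                n_modes = NULL, zero_tol_rel = 1e-6) {
  stopifnot(inherits(network, "elastic_network"),
            inherits(pair, "pulling_pair"))
  n <- nrow(network$coords)
  if (n > 50L) {
    stop("reference oracle is limited to 50 atoms", call. = FALSE)
  }
  # independent Hessian assembly: literal loop over springs
  m <- 3L * n
  H <- matrix(0, m, m)
  for (p in seq_len(nrow(network$pairs))) {
    j <- network$pairs[p, 1L]
    l <- network$pairs[p, 2L]
    b <- network$coords[l, ] - network$coords[j, ]
    r2 <- sum(b^2)
    for (a in 1:3) {
      for (bb in 1:3) {
        kab <- -network$gamma * b[a] * b[bb] / r2
        H[3 * (j - 1) + a, 3 * (l - 1) + bb] <-
          H[3 * (j - 1) + a, 3 * (l - 1) + bb] + kab
        H[3 * (l - 1) + a, 3 * (j - 1) + bb] <-
          H[3 * (l - 1) + a, 3 * (j - 1) + bb] + kab
        H[3 * (j - 1) + a, 3 * (j - 1) + bb] <-
          H[3 * (j - 1) + a, 3 * (j - 1) + bb] - kab
        H[3 * (l - 1) + a, 3 * (l - 1) + bb] <-
          H[3 * (l - 1) + a, 3 * (l - 1) + bb] - kab
      }
    }
  }
  # different diagonalization route: SVD of the symmetric PSD matrix
  s <- svd(H)
  ord <- order(s$d)            # ascending
  d <- s$d[ord]
  U <- s$u[, ord, drop = FALSE]
  tol <- zero_tol_rel * max(d)
  keep <- which(d > tol)
  kappa <- d[keep]
  V <- U[, keep, drop = FALSE]
  nm <- if (is.null(n_modes)) length(kappa) else n_modes
  stopifnot(nm >= 1L, nm <= length(kappa))

  # straight scalar loops over the defining formulas
  kBT <- units$kBT
  sigma2 <- 0
  for (i in seq_len(nm)) sigma2 <- sigma2 + kBT / kappa[i]
  kp <- kBT / sigma2

  r0 <- pair$r0_mn
  r0n <- sqrt(sum(r0^2))
  num <- 0
  den <- 0
  for (i in seq_len(nm)) {
    u <- V[(3 * (pair$index_n - 1) + 1):(3 * pair$index_n), i] -
      V[(3 * (pair$index_m - 1) + 1):(3 * pair$index_m), i]
    un <- sqrt(sum(u^2))
    if (un == 0) next
    ct <- sum(r0 * u) / (r0n * un)
    d_i <- sqrt(kBT / kappa[i]) * abs(ct) * un
    num <- num + kappa[i] * d_i
    den <- den + d_i
  }
  kd <- if (den > 0) num / den else NA_real_
  list(k_protein = kp, k_direct = kd, n_modes = nm)
}
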