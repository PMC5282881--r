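#' Normal modes of an elastic-network Hessian
#'
#' Performs a full dense symmetric eigendecomposition of the Hessian,
#' discards the near-zero rigid-body eigenvalues, and returns the remaining
#' modes sorted in ascending order of their eigenvalues (mode spring
#' constants). For a connected three-dimensional network exactly six zero
#' modes (three translations, three rotations) are removed, leaving
#' \eqn{3N - 6} internal modes; more than six near-zero eigenvalues signal a
#' network that is disconnected at the chosen cutoff.
#'
#' The zero threshold is relative: eigenvalues below
#' \code{zero_tol_rel * max(eigenvalue)} are treated as rigid-body modes.
#' A relative threshold survives rescaling of \code{gamma}, under which the
#' whole spectrum scales linearly.
#'
#' @param hessian Symmetric 3N x 3N matrix from \code{\link{build_hessian}}.
#' @param zero_tol_rel Relative zero-mode threshold (default \code{1e-6}).
#' @return An object of class \code{"anm_modes"}: list with
#'   \code{values} (ascending eigenvalues, kcal/mol/A^2),
#'   \code{vectors} (3N x n_modes orthonormal eigenvectors, columns aligned
#'   with \code{values}), \code{n_modes}, \code{n_zero} (count of discarded
#'   near-zero eigenvalues), \code{zero_tol} (absolute threshold applied)
#'   and \code{degenerate} (indices of retained eigenvalues whose gap to the
#'   next one is below 1e-9 relative; directional stiffness can depend on
#'   the eigenbasis within such subspaces).
#' @export
compute_modes <- function(hessian, zero_tol_rel = 1e-6) {
  .check_hessian(hessian)
  e <- eigen(hessian, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- e$vectors[, rev(seq_along(e$values)), drop = FALSE]
  lmax <- max(abs(vals))
  tol <- zero_tol_rel * lmax
  if (any(vals < -tol)) {
    stop("Hessian not positive semidefinite (eigenvalue ",
         format(min(vals)), " below -", format(tol), ")", call. = FALSE)
  }
  keep <- vals > tol
  values <- vals[keep]
  vectors <- vecs[, keep, drop = FALSE]
  deg <- integer(0)
  if (length(values) > 1L) {
    gap <- diff(values) / pmax(values[-length(values)], .Machine$double.xmin)
    deg <- which(gap < 1e-9)
  }
  structure(
    list(values = values, vectors = vectors,
         n_modes = length(values), n_zero = sum(!keep),
         zero_tol = tol, zero_tol_rel = zero_tol_rel,
         degenerate = deg),
    class = "anm_modes"
  )
}

.check_hessian <- function(hessian) {
  stopifnot(is.matrix(hessian), nrow(hessian) == ncol(hessian))
  if (nrow(hessian) %% 3L != 0L) {
    stop("Hessian dimension must be a multiple of 3", call. = FALSE)
  }
  if (max(abs(hessian - t(hessian))) > 1e-10 * max(1, max(abs(hessian)))) {
    stop("Hessian is not symmetric", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.anm_modes <- function(x, ...) {
  cat("Normal modes: ", x$n_modes, " internal modes (", x$n_zero,
      " zero modes removed)\n", sep = "")
  if (x$n_modes) {
    cat("  eigenvalue range: ", format(x$values[1L], digits = 4), " .. ",
        format(x$values[x$n_modes], digits = 4), " kcal/mol/A^2\n",
        sep = "")
  }
  if (length(x$degenerate)) {
    cat("  note: ", length(x$degenerate),
        " near-degenerate eigenvalue gaps (< 1e-9 relative)\n", sep = "")
  }
  invisible(x)
}

#' Count near-zero (rigid-body) eigenvalues
#'
#' Six near-zero eigenvalues mean the network moves as one connected rigid
#' body; every additional rigidly separated component adds six more, so a
#' count above six diagnoses a disconnected network at the chosen cutoff.
#'
#' @inheritParams compute_modes
#' @return Integer count of eigenvalues at or below the zero threshold.
#' @export
count_zero_modes <- function(hessian, zero_tol_rel = 1e-6) {
  .check_hessian(hessian)
  vals <- eigen(hessian, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(abs(vals))
  sum(vals <= zero_tol_rel * lmax)
}

#' Minimum cutoff giving a connected network
#'
#' Scans an ascending grid of cutoff values and returns the smallest one at
#' which the elastic network has exactly six zero modes, i.e. forms a single
#' connected rigid body. Reported to the grid resolution.
#'
#' Collinear structures are a documented exception: a straight chain has a
#' rotational zero mode about its own axis, so its zero-mode count never
#' drops to six at any cutoff.
#'
#' @param selection An \code{"anm_selection"} or coordinate matrix.
#' @param grid_start,grid_stop Grid limits in Angstrom.
#' @param grid_step Grid spacing in Angstrom (> 0).
#' @param gamma Force constant (its value does not affect connectivity).
#' @param zero_tol_rel Relative zero-mode threshold.
#' @return Smallest grid cutoff (Angstrom) with exactly six zero modes.
#' @export
min_connected_cutoff <- function(selection, grid_start, grid_stop,
                                 grid_step, gamma = 1,
                                 zero_tol_rel = 1e-6) {
  if (grid_step <= 0) stop("grid_step must be > 0", call. = FALSE)
  grid <- seq(grid_start, grid_stop, by = grid_step)
  nz <- NA_integer_
  for (rc in grid) {
    net <- build_network(selection, cutoff = rc, gamma = gamma)
    nz <- count_zero_modes(build_hessian(net), zero_tol_rel)
    if (nz == 6L) return(rc)
  }
  stop("network never reaches exactly 6 zero modes on the grid (",
       nz, " zero modes at cutoff ", grid[length(grid)], " A)",
       call. = FALSE)
}
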