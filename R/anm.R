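#' Fit an all-atom anisotropic network model
#'
#' The main fitting function of the package. Takes a heavy-atom selection
#' (from \code{\link{select_heavy_atoms}} or \code{\link{make_fixture}}),
#' connects every atom pair within the cutoff \code{Rc} by a spring of
#' constant \code{gamma}, assembles the 3N x 3N Hessian of the harmonic
#' potential and diagonalizes it. The returned object holds the elastic
#' network and the sorted internal normal modes, and is the input to the
#' stiffness observables \code{\link{k_protein}} and \code{\link{k_direct}}.
#'
#' @param structure An \code{"anm_selection"} or an N x 3 coordinate matrix
#'   (Angstrom).
#' @param cutoff Interaction cutoff \code{Rc} in Angstrom (default 5.0, the
#'   usual choice for heavy-atom networks).
#' @param gamma Uniform spring constant in kcal/mol/A^2 (default 1). Both
#'   stiffness observables scale linearly in \code{gamma}, so only relative
#'   comparisons are meaningful unless \code{gamma} is calibrated.
#' @param temperature Temperature in kelvin used for reporting amplitudes
#'   (default 298.15); the stiffness observables are independent of it.
#' @param zero_tol_rel Relative threshold for discarding rigid-body modes.
#' @return Object of class \code{"anm"}: list with \code{selection} (or
#'   \code{NULL} for bare coordinates), \code{network}, \code{modes},
#'   \code{units} and \code{call}.
#' @seealso \code{\link{k_protein}}, \code{\link{k_direct}},
#'   \code{\link{cumulative_profile}}, \code{\link{cutoff_scan}}
#' @export
#' @examples
#' fit <- anm(make_fixture("helix", n_atoms = 30, jitter = 0.2, seed = 1),
#'            cutoff = 5)
#' summary(fit)
#' k_protein(fit)
anm <- function(structure, cutoff = 5, gamma = 1, temperature = 298.15,
                zero_tol_rel = 1e-6) {
  sel <- if (inherits(structure, "anm_selection")) structure else NULL
  network <- build_network(structure, cutoff = cutoff, gamma = gamma)
  modes <- compute_modes(build_hessian(network), zero_tol_rel)
  structure(
    list(selection = sel, network = network, modes = modes,
         units = unit_system(temperature), call = match.call()),
    class = "anm"
  )
}

#' @export
print.anm <- function(x, ...) {
  n <- nrow(x$network$coords)
  cat("All-atom anisotropic network model\n")
  cat("  nodes: ", n, " heavy atoms, ", nrow(x$network$pairs),
      " springs (Rc = ", x$network$cutoff, " A, gamma = ",
      x$network$gamma, " kcal/mol/A^2)\n", sep = "")
  cat("  modes: ", x$modes$n_modes, " internal, ", x$modes$n_zero,
      " zero", if (x$modes$n_zero > 6L) "  [network disconnected]",
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.anm <- function(object, ...) {
  kp <- k_protein(object)
  out <- list(
    n_atoms = nrow(object$network$coords),
    n_pairs = nrow(object$network$pairs),
    cutoff = object$network$cutoff,
    gamma = object$network$gamma,
    n_modes = object$modes$n_modes,
    n_zero = object$modes$n_zero,
    connected = object$modes$n_zero == 6L,
    kappa_range = range(object$modes$values),
    k_protein = kp,
    temperature = object$units$temperature
  )
  class(out) <- "summary.anm"
  out
}

#' @export
print.summary.anm <- function(x, ...) {
  cat("All-atom anisotropic network model\n")
  cat("  atoms:   ", x$n_atoms, "   springs: ", x$n_pairs,
      "   Rc = ", x$cutoff, " A   gamma = ", x$gamma, "\n", sep = "")
  cat("  modes:   ", x$n_modes, " internal, ", x$n_zero, " zero (",
      if (x$connected) "connected" else "DISCONNECTED", ")\n", sep = "")
  cat("  kappa:   ", format(x$kappa_range[1], digits = 4), " .. ",
      format(x$kappa_range[2], digits = 4), " kcal/mol/A^2\n", sep = "")
  cat("  k_protein: ", format(x$k_protein$value_model_units, digits = 4),
      " kcal/mol/A^2  =  ", format(x$k_protein$value_si, digits = 4),
      " N/m\n", sep = "")
  invisible(x)
}

#' @export
coef.anm <- function(object, ...) {
  object$modes$values
}

#' Eigenvalue spectrum or convergence plot of a fitted network model
#'
#' @param x An \code{"anm"} object.
#' @param which \code{"spectrum"} (mode eigenvalues in ascending order) or
#'   \code{"profile"} (cumulative-mode convergence of the overall spring
#'   constant).
#' @param ... Passed to the underlying plot call.
#' @export
plot.anm <- function(x, which = c("spectrum", "profile"), ...) {
  which <- match.arg(which)
  if (which == "spectrum") {
    graphics::plot(seq_len(x$modes$n_modes), x$modes$values,
                   xlab = "mode index (ascending)",
                   ylab = "mode spring constant (kcal/mol/A^2)",
                   main = "ANM eigenvalue spectrum", type = "l", ...)
  } else {
    prof <- cumulative_profile(x, measure = "overall")
    graphics::plot(prof, ...)
  }
  invisible(x)
}

#' Thermal coordinate ensembles from the normal modes
#'
#' Draws configurations from the harmonic equilibrium distribution: each
#' internal mode i receives an independent Gaussian amplitude of standard
#' deviation \eqn{\sqrt{k_B T / \kappa_i}}, and the displacements are
#' added to the equilibrium coordinates.
#'
#' @param object An \code{"anm"} object.
#' @param nsim Number of configurations.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return List of \code{nsim} N x 3 coordinate matrices.
#' @export
simulate.anm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  m <- object$modes
  amp <- sqrt(object$units$kBT / m$values)
  n <- nrow(object$network$coords)
  lapply(seq_len(nsim), function(k) {
    z <- rnorm(m$n_modes) * amp
    dx <- as.numeric(m$vectors %*% z)
    object$network$coords + matrix(dx, n, 3L, byrow = TRUE)
  })
}
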