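.as_modes <- function(x) {
  if (inherits(x, "anm")) x$modes
  else if (inherits(x, "anm_modes")) x
  else stop("expected an 'anm' fit or an 'anm_modes' object", call. = FALSE)
}

#' Define a pulling axis between two residues' C-alpha atoms
#'
#' The directional stiffness observable needs an axis: the equilibrium
#' vector between the CA atoms of residues m and n, typically the N- and
#' C-terminal residues of a domain — the axis stretched in single-molecule
#' AFM pulling experiments.
#'
#' @param selection An \code{"anm_selection"}.
#' @param residue_m,residue_n Author residue numbers of the two residues.
#' @param chain Optional chain identifier.
#' @return Object of class \code{"pulling_pair"}: list with
#'   \code{residue_m}, \code{residue_n}, \code{index_m}, \code{index_n}
#'   (atom positions of the CA atoms in the selection) and \code{r0_mn}
#'   (equilibrium vector in Angstrom).
#' @export
pulling_pair <- function(selection, residue_m, residue_n, chain = NULL) {
  m <- locate_calpha(selection, residue_m, chain = chain)
  n <- locate_calpha(selection, residue_n, chain = chain)
  r0 <- n$coords - m$coords
  if (sqrt(sum(r0^2)) == 0) {
    stop("pulling pair has zero equilibrium separation", call. = FALSE)
  }
  structure(
    list(residue_m = residue_m, residue_n = residue_n,
         index_m = m$index, index_n = n$index, r0_mn = r0),
    class = "pulling_pair"
  )
}

#' @export
print.pulling_pair <- function(x, ...) {
  cat("Pulling axis: residues ", x$residue_m, " -> ", x$residue_n,
      " (|r0| = ", format(sqrt(sum(x$r0_mn^2)), digits = 4), " A)\n",
      sep = "")
  invisible(x)
}

# Rows of the 3N eigenvector matrix belonging to atom i.
.atom_rows <- function(i) (3L * (i - 1L) + 1L):(3L * i)

# Per-mode directional deformations d_mn^i = sqrt(kBT/kappa_i) *
# |cos(theta_mn^i)| * |u_mn^i| for all modes at once.
.directional_d <- function(modes, pair, units) {
  U <- modes$vectors[.atom_rows(pair$index_n), , drop = FALSE] -
    modes$vectors[.atom_rows(pair$index_m), , drop = FALSE]
  r0 <- pair$r0_mn
  proj <- abs(colSums(U * r0)) / sqrt(sum(r0^2))
  sqrt(units$kBT / modes$values) * proj
}

#' Overall protein spring constant
#'
#' The overall stiffness is the thermal energy divided by the cumulative
#' variance of atomic fluctuations accumulated over the internal modes in
#' ascending eigenvalue order:
#' \deqn{k_{protein} = k_B T / \sigma^2, \qquad
#'       \sigma^2 = \sum_{i=1}^{N_{modes}} k_B T / \kappa_i,}
#' i.e. the harmonic combination \eqn{1/\sum_i 1/\kappa_i} of the mode
#' spring constants — independent of temperature in model units, and
#' monotonically non-increasing as more modes are included.
#'
#' @param x An \code{"anm"} fit or \code{"anm_modes"} object.
#' @param n_modes Number of lowest modes to accumulate (default: all).
#' @param units A \code{"unit_system"}.
#' @return Object of class \code{"stiffness"} with \code{measure =
#'   "overall"}, \code{value_model_units} (kcal/mol/A^2), \code{value_si}
#'   (N/m), \code{sigma2} (cumulative variance, A^2) and
#'   \code{n_modes_used}.
#' @export
k_protein <- function(x, n_modes = NULL, units = unit_system()) {
  modes <- .as_modes(x)
  if (is.null(n_modes)) n_modes <- modes$n_modes
  if (n_modes < 1L) stop("n_modes must be at least 1", call. = FALSE)
  if (n_modes > modes$n_modes) {
    stop("n_modes exceeds the ", modes$n_modes, " available modes",
         call. = FALSE)
  }
  kappa <- modes$values[seq_len(n_modes)]
  sigma2 <- sum(units$kBT / kappa)
  value <- units$kBT / sigma2
  structure(
    list(measure = "overall",
         value_model_units = value,
         value_si = convert_units(value, units),
         n_modes_used = as.integer(n_modes),
         sigma2 = sigma2,
         units = units),
    class = "stiffness"
  )
}

#' Directional spring constant along a residue-pair axis
#'
#' The effective stiffness felt when the structure is deformed along the
#' axis joining the CA atoms of residues m and n: the deformation-weighted
#' mean of the mode spring constants,
#' \deqn{k_{direct}(m,n) = \frac{\sum_i \kappa_i d^i_{mn}}
#'                              {\sum_i d^i_{mn}},}
#' where \eqn{d^i_{mn} = \sqrt{k_B T / \kappa_i}\,
#' |\cos\theta^i_{mn}|\,|u^i_{mn}|} is the length mode i projects onto the
#' axis, \eqn{u^i_{mn}} the difference of the eigenvector components at the
#' two CA atoms and \eqn{\cos\theta^i_{mn}} the normalized projection onto
#' the equilibrium vector. Absolute values make the result independent of
#' the arbitrary eigenvector phases. All modes — low and high frequency —
#' contribute by default; localized high-frequency motions can project
#' substantially onto the axis, so truncating to the slow modes is not
#' recommended for this observable.
#'
#' @param x An \code{"anm"} fit or \code{"anm_modes"} object.
#' @param pair A \code{"pulling_pair"}.
#' @param n_modes Number of lowest modes to include (default: all).
#' @param units A \code{"unit_system"}.
#' @param keep_projections Logical; attach the per-mode
#'   \code{\link{mode_projection}} records (default \code{FALSE}).
#' @return Object of class \code{"stiffness"} with \code{measure =
#'   "directional"}; the value always lies between the smallest and largest
#'   contributing mode spring constants.
#' @export
k_direct <- function(x, pair, n_modes = NULL, units = unit_system(),
                     keep_projections = FALSE) {
  modes <- .as_modes(x)
  stopifnot(inherits(pair, "pulling_pair"))
  if (3L * max(pair$index_m, pair$index_n) > nrow(modes$vectors)) {
    stop("pair indices exceed the eigenvector dimension", call. = FALSE)
  }
  if (is.null(n_modes)) n_modes <- modes$n_modes
  if (n_modes < 1L || n_modes > modes$n_modes) {
    stop("n_modes must be between 1 and ", modes$n_modes, call. = FALSE)
  }
  d <- .directional_d(modes, pair, units)[seq_len(n_modes)]
  if (all(d == 0)) {
    stop("undefined direction: the pulling axis is orthogonal to every ",
         "mode displacement", call. = FALSE)
  }
  kappa <- modes$values[seq_len(n_modes)]
  value <- sum(kappa * d) / sum(d)
  proj <- NULL
  if (keep_projections) {
    proj <- lapply(seq_len(n_modes), function(i)
      mode_projection(modes, pair, i, units))
  }
  structure(
    list(measure = "directional",
         value_model_units = value,
         value_si = convert_units(value, units),
         n_modes_used = as.integer(n_modes),
         pair = pair,
         projections = proj,
         units = units),
    class = "stiffness"
  )
}

#' @export
print.stiffness <- function(x, ...) {
  lab <- if (x$measure == "overall") "k_protein" else
    paste0("k_direct(", x$pair$residue_m, ",", x$pair$residue_n, ")")
  cat(lab, " = ", format(x$value_model_units, digits = 4),
      " kcal/mol/A^2  =  ", format(x$value_si, digits = 4),
      " N/m   [", x$n_modes_used, " modes]\n", sep = "")
  invisible(x)
}

#' Per-mode projection onto a pulling axis
#'
#' Diagnostic record for a single mode: the relative displacement
#' \eqn{u_{mn}} of the two CA atoms, its normalized projection
#' \eqn{\cos\theta} onto the equilibrium axis, and the resulting
#' deformation length \eqn{d_{mn}}. When a mode displaces both CA atoms
#' identically (\eqn{|u_{mn}| = 0}) the angle is undefined;
#' \code{cos_theta} is reported as 0 and \code{d_mn} as 0 by convention.
#'
#' @param x An \code{"anm"} fit or \code{"anm_modes"} object.
#' @param pair A \code{"pulling_pair"}.
#' @param i Mode index (ascending eigenvalue order).
#' @param units A \code{"unit_system"}.
#' @return Object of class \code{"mode_projection"}: list with
#'   \code{mode_index}, \code{kappa}, \code{u_mn}, \code{cos_theta},
#'   \code{d_mn} (Angstrom).
#' @export
mode_projection <- function(x, pair, i, units = unit_system()) {
  modes <- .as_modes(x)
  stopifnot(inherits(pair, "pulling_pair"))
  if (i < 1L || i > modes$n_modes) {
    stop("mode index out of range", call. = FALSE)
  }
  u <- modes$vectors[.atom_rows(pair$index_n), i] -
    modes$vectors[.atom_rows(pair$index_m), i]
  unorm <- sqrt(sum(u^2))
  r0 <- pair$r0_mn
  if (unorm == 0) {
    ct <- 0
    d <- 0
  } else {
    ct <- sum(r0 * u) / (sqrt(sum(r0^2)) * unorm)
    d <- sqrt(units$kBT / modes$values[i]) * abs(ct) * unorm
  }
  structure(
    list(mode_index = as.integer(i), kappa = modes$values[i],
         u_mn = u, cos_theta = ct, d_mn = d),
    class = "mode_projection"
  )
}

#' Convergence of a stiffness observable with cumulative modes
#'
#' Evaluates the overall or directional spring constant at every cumulative
#' mode count 1..N_modes (or a stride thereof), accumulating modes in
#' ascending eigenvalue order. The overall measure is monotonically
#' non-increasing and converges within the first few (collective, low
#' frequency) modes; the directional measure keeps evolving out to the
#' high-frequency end because localized motions also project onto the axis.
#'
#' @param x An \code{"anm"} fit or \code{"anm_modes"} object.
#' @param measure \code{"overall"} or \code{"directional"}.
#' @param pair A \code{"pulling_pair"}; required for the directional
#'   measure.
#' @param units A \code{"unit_system"}.
#' @param stride Evaluate every \code{stride}-th cumulative count (the
#'   final count N_modes is always included).
#' @return Object of class \code{"stiffness_profile"}: data frame with
#'   columns \code{n_modes}, \code{value_model_units}, \code{value_si}
#'   (directional points with zero accumulated deformation are \code{NA}),
#'   plus attributes \code{measure} and \code{pair}.
#' @export
cumulative_profile <- function(x, measure = c("overall", "directional"),
                               pair = NULL, units = unit_system(),
                               stride = 1L) {
  measure <- match.arg(measure)
  modes <- .as_modes(x)
  if (measure == "directional" && is.null(pair)) {
    stop("the directional measure needs a `pair`", call. = FALSE)
  }
  counts <- unique(c(seq(1L, modes$n_modes, by = as.integer(stride)),
                     modes$n_modes))
  kappa <- modes$values
  if (measure == "overall") {
    vals <- (1 / cumsum(1 / kappa))[counts]
  } else {
    d <- .directional_d(modes, pair, units)
    num <- cumsum(kappa * d)
    den <- cumsum(d)
    v <- ifelse(den > 0, num / den, NA_real_)
    vals <- v[counts]
  }
  out <- data.frame(n_modes = counts,
                    value_model_units = vals,
                    value_si = convert_units(vals, units))
  attr(out, "measure") <- measure
  attr(out, "pair") <- pair
  class(out) <- c("stiffness_profile", "data.frame")
  out
}

#' @export
plot.stiffness_profile <- function(x, ...) {
  lab <- if (attr(x, "measure") == "overall") "k_protein" else "k_direct"
  graphics::plot(x$n_modes, x$value_model_units,
                 xlab = "cumulative modes", type = "l",
                 ylab = paste(lab, "(kcal/mol/A^2)"),
                 main = paste(lab, "vs cumulative normal modes"), ...)
  invisible(x)
}

#' Stiffness observables over a grid of cutoffs
#'
#' Rebuilds the network and rediagonalizes the Hessian at each cutoff in an
#' ascending grid, reporting both observables and the zero-mode count. Rows
#' where the network is disconnected (more than six zero modes) are flagged
#' and their stiffness values suppressed as \code{NA}: stiffness of a
#' disconnected body is not meaningful.
#'
#' @param selection An \code{"anm_selection"}.
#' @param cutoffs Ascending cutoff values in Angstrom.
#' @param pair_residues Optional pair \code{c(m, n)} of residue numbers
#'   defining the pulling axis for \code{k_direct}.
#' @param gamma Force constant (kcal/mol/A^2).
#' @param units A \code{"unit_system"}.
#' @param zero_tol_rel Relative zero-mode threshold.
#' @return Data frame with one row per cutoff: \code{cutoff}, \code{n_zero},
#'   \code{disconnected}, \code{k_protein_model}, \code{k_protein_si},
#'   and (when a pair is given) \code{k_direct_model}, \code{k_direct_si}.
#' @export
cutoff_scan <- function(selection, cutoffs, pair_residues = NULL,
                        gamma = 1, units = unit_system(),
                        zero_tol_rel = 1e-6) {
  stopifnot(length(cutoffs) >= 1L)
  if (is.unsorted(cutoffs, strictly = TRUE)) {
    stop("cutoffs must be in ascending order", call. = FALSE)
  }
  rows <- lapply(cutoffs, function(rc) {
    fit <- anm(selection, cutoff = rc, gamma = gamma,
               temperature = units$temperature,
               zero_tol_rel = zero_tol_rel)
    disc <- fit$modes$n_zero > 6L
    kp <- if (disc) NA_real_ else
      k_protein(fit, units = units)$value_model_units
    kd <- NA_real_
    if (!disc && !is.null(pair_residues)) {
      pr <- pulling_pair(selection, pair_residues[1L], pair_residues[2L])
      kd <- k_direct(fit, pr, units = units)$value_model_units
    }
    row <- data.frame(cutoff = rc, n_zero = fit$modes$n_zero,
                      disconnected = disc,
                      k_protein_model = kp,
                      k_protein_si = convert_units(kp, units))
    if (!is.null(pair_residues)) {
      row$k_direct_model <- kd
      row$k_direct_si <- convert_units(kd, units)
    }
    row
  })
  do.call(rbind, rows)
}
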