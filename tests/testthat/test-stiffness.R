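fit_fixture <- function(sel, cutoff = 6, gamma = 1, ...) {
  anm(sel, cutoff = cutoff, gamma = gamma, ...)
}

test_that("single-mode truncation returns the lowest eigenvalue", {
  sel <- make_fixture("tetrahedron", spacing = 3, jitter = 0.25, seed = 41)
  fit <- fit_fixture(sel)
  pr <- termini_pair(sel)
  # kBT cancels when the variance sum has one term
  expect_equal(k_protein(fit, n_modes = 1)$value_model_units,
               fit$modes$values[1])
  # the weighted mean of one value is that value
  expect_equal(k_direct(fit, pr, n_modes = 1)$value_model_units,
               fit$modes$values[1])
  expect_error(k_protein(fit, n_modes = 0), "at least 1")
  expect_error(k_protein(fit, n_modes = 999), "available")
})

test_that("both observables are temperature-invariant in model units", {
  sel <- make_fixture("helix", n_atoms = 12, jitter = 0.2, seed = 42)
  fit <- fit_fixture(sel, cutoff = 5)
  pr <- termini_pair(sel)
  cold <- unit_system(150)
  hot <- unit_system(600)
  expect_equal(k_protein(fit, units = cold)$value_model_units,
               k_protein(fit, units = hot)$value_model_units,
               tolerance = 1e-12)
  expect_equal(k_direct(fit, pr, units = cold)$value_model_units,
               k_direct(fit, pr, units = hot)$value_model_units,
               tolerance = 1e-12)
})

test_that("both observables scale linearly in gamma", {
  sel <- make_fixture("lattice", n_atoms = 8, spacing = 3,
                      jitter = 0.3, seed = 43)
  pr <- termini_pair(sel)
  f1 <- fit_fixture(sel, cutoff = 5, gamma = 1)
  f2 <- fit_fixture(sel, cutoff = 5, gamma = 2)
  expect_equal(k_protein(f2)$value_model_units,
               2 * k_protein(f1)$value_model_units, tolerance = 1e-12)
  expect_equal(k_direct(f2, pr)$value_model_units,
               2 * k_direct(f1, pr)$value_model_units, tolerance = 1e-12)
})

test_that("observables respect their spectral bounds", {
  for (sel in small_fixtures()) {
    fit <- fit_fixture(sel, cutoff = 6)
    pr <- termini_pair(sel)
    kappa <- fit$modes$values
    expect_lte(k_protein(fit)$value_model_units, kappa[1])
    kd <- k_direct(fit, pr)$value_model_units
    expect_gte(kd, min(kappa))
    expect_lte(kd, max(kappa))
  }
})

test_that("k_direct is exactly invariant to eigenvector sign flips", {
  sel <- make_fixture("helix", n_atoms = 10, jitter = 0.25, seed = 44)
  fit <- fit_fixture(sel, cutoff = 5.5)
  pr <- termini_pair(sel)
  base <- k_direct(fit, pr)$value_model_units
  flipped <- fit
  set.seed(9)
  signs <- sample(c(-1, 1), fit$modes$n_modes, replace = TRUE)
  flipped$modes$vectors <- sweep(fit$modes$vectors, 2, signs, `*`)
  expect_identical(k_direct(flipped, pr)$value_model_units, base)
})

test_that("rigid rotation changes neither observable", {
  sel <- make_fixture("lattice", n_atoms = 9, spacing = 3,
                      jitter = 0.3, seed = 45)
  pr_res <- c(1, 9)
  th <- 0.9
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- sel
  rot$atoms[, c("x", "y", "z")] <- coords(sel) %*% t(R)

  for (s in list(sel, rot)) {
    fit <- fit_fixture(s, cutoff = 5)
    pr <- pulling_pair(s, pr_res[1], pr_res[2])
    assign(if (identical(s, sel)) "a" else "b",
           c(k_protein(fit)$value_model_units,
             k_direct(fit, pr)$value_model_units))
  }
  expect_equal(b, a, tolerance = 1e-9)
})

test_that("main path agrees with the brute-force oracle on all fixtures", {
  for (sel in small_fixtures()) {
    net <- build_network(sel, cutoff = 6, gamma = 1.4)
    pr <- termini_pair(sel)
    fit <- compute_modes(build_hessian(net))
    ref <- reference_stiffness(net, pr)
    expect_equal(k_protein(fit)$value_model_units, ref$k_protein,
                 tolerance = 1e-10)
    expect_equal(k_direct(fit, pr)$value_model_units, ref$k_direct,
                 tolerance = 1e-10)
  }
})

test_that("mode projections follow the deformation formula", {
  sel <- make_fixture("tetrahedron", spacing = 3, jitter = 0.25, seed = 46)
  fit <- fit_fixture(sel)
  pr <- termini_pair(sel)
  u <- unit_system()

  mp <- mode_projection(fit, pr, 1, units = u)
  expect_lte(abs(mp$cos_theta), 1 + 1e-12)
  expect_gte(mp$d_mn, 0)
  # d simplifies to sqrt(kBT/kappa) |r0.u| / |r0|
  r0 <- pr$r0_mn
  expect_equal(mp$d_mn,
               sqrt(u$kBT / mp$kappa) *
                 abs(sum(r0 * mp$u_mn)) / sqrt(sum(r0^2)))

  # an eigenvector displacing both CA atoms identically contributes zero
  rigged <- fit
  rigged$modes$vectors[, 2] <- 0
  rigged$modes$vectors[1:3, 2] <- c(1, 0, 0) / sqrt(2)
  rigged$modes$vectors[.rows <- (3 * (pr$index_n - 1) + 1):(3 * pr$index_n), 2] <-
    c(1, 0, 0) / sqrt(2)
  rigged$modes$vectors[(3 * (pr$index_m - 1) + 1):(3 * pr$index_m), 2] <-
    c(1, 0, 0) / sqrt(2)
  mp2 <- mode_projection(rigged, pr, 2, units = u)
  expect_identical(mp2$d_mn, 0)
  expect_identical(mp2$cos_theta, 0)

  # flipping the eigenvector sign leaves the deformation unchanged
  neg <- fit
  neg$modes$vectors[, 1] <- -neg$modes$vectors[, 1]
  expect_identical(mode_projection(neg, pr, 1, units = u)$d_mn, mp$d_mn)
})

test_that("an axis orthogonal to every mode displacement is rejected", {
  sel <- make_fixture("triangle", spacing = 3, jitter = 0.2, seed = 47)
  fit <- fit_fixture(sel)
  pr <- pulling_pair(sel, 1, 2)
  # zero out every eigenvector component at the two CA atoms
  fit$modes$vectors[c(1:3, 4:6), ] <- 0
  expect_error(k_direct(fit, pr), "undefined direction")
})

test_that("cumulative profiles are consistent and monotone where due", {
  sel <- make_fixture("helix", n_atoms = 20, jitter = 0.25, seed = 48)
  fit <- fit_fixture(sel, cutoff = 5)
  pr <- termini_pair(sel)

  prof <- cumulative_profile(fit, "overall")
  expect_equal(nrow(prof), fit$modes$n_modes)
  expect_false(is.unsorted(prof$n_modes, strictly = TRUE))
  # final point equals the all-mode observable
  expect_equal(prof$value_model_units[nrow(prof)],
               k_protein(fit)$value_model_units)
  # adding modes only adds variance: non-increasing profile
  expect_true(all(diff(prof$value_model_units) <= 1e-15))

  dprof <- cumulative_profile(fit, "directional", pair = pr)
  expect_equal(dprof$value_model_units[nrow(dprof)],
               k_direct(fit, pr)$value_model_units)
  # stride keeps the final count
  strided <- cumulative_profile(fit, "overall", stride = 7)
  expect_equal(strided$n_modes[nrow(strided)], fit$modes$n_modes)
  expect_error(cumulative_profile(fit, "directional"), "pair")
})

test_that("cutoff scans match single-shot results and flag disconnection", {
  sel <- make_fixture("lattice", n_atoms = 8, spacing = 3,
                      jitter = 0.3, seed = 49)
  pr <- termini_pair(sel)
  tab <- cutoff_scan(sel, cutoffs = 5.5, pair_residues = c(1, 8))
  fit <- fit_fixture(sel, cutoff = 5.5)
  expect_equal(tab$k_protein_model, k_protein(fit)$value_model_units)
  expect_equal(tab$k_direct_model, k_direct(fit, pr)$value_model_units)
  expect_false(tab$disconnected)

  far <- make_fixture("two_clusters", n_atoms = 10, spacing = 3,
                      jitter = 0.2, seed = 50, gap = 20)
  tab2 <- cutoff_scan(far, cutoffs = c(4.5, 5.0), pair_residues = c(1, 10))
  expect_true(all(tab2$disconnected))
  expect_true(all(is.na(tab2$k_protein_model)))
  expect_true(all(tab2$n_zero > 6))

  expect_error(cutoff_scan(sel, cutoffs = c(5, 4)), "ascending")
})

test_that("unit conversion uses the physical kcal/mol/A^2 to N/m factor", {
  u <- unit_system()
  expect_equal(convert_units(1, u), 0.694769, tolerance = 1e-6)
  expect_identical(convert_units(0, u), 0)
  x <- 3.9
  expect_equal(convert_units(x, u) / u$to_newton_per_meter, x,
               tolerance = 1e-15)
  # kBT at room temperature in kcal/mol
  expect_equal(unit_system(298.15)$kBT, 0.59248, tolerance = 1e-4)
})
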