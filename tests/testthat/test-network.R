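test_that("pair enumeration honors the inclusive cutoff", {
  two <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))
  expect_equal(nrow(build_network(two(3), cutoff = 5)$pairs), 1)
  expect_equal(nrow(build_network(two(6), cutoff = 5)$pairs), 0)
  # boundary is inclusive
  expect_equal(nrow(build_network(two(5), cutoff = 5)$pairs), 1)
  expect_error(build_network(two(3)[1, , drop = FALSE], cutoff = 5),
               "at least 2")
  expect_error(build_network(two(3), cutoff = -1), "cutoff")
  expect_error(build_network(two(3), cutoff = 5, gamma = 0), "gamma")
})

test_that("pair list matches a brute-force double loop", {
  sel <- make_fixture("lattice", n_atoms = 20, spacing = 3,
                      jitter = 0.4, seed = 21)
  xyz <- coords(sel)
  rc <- 4.5
  net <- build_network(sel, cutoff = rc)
  brute <- NULL
  for (j in seq_len(nrow(xyz) - 1)) {
    for (l in (j + 1):nrow(xyz)) {
      if (sqrt(sum((xyz[j, ] - xyz[l, ])^2)) <= rc) {
        brute <- rbind(brute, c(j, l))
      }
    }
  }
  expect_equal(unname(net$pairs), unname(brute))
  expect_equal(net$r0,
               apply(brute, 1, function(p)
                 sqrt(sum((xyz[p[1], ] - xyz[p[2], ])^2))))
})

test_that("potential energy matches hand evaluation of the spring sum", {
  # single pair at r0 = 3 stretched to 4 with gamma = 1: V = 1/2
  net <- build_network(rbind(c(0, 0, 0), c(3, 0, 0)), cutoff = 5)
  expect_equal(potential_energy(net, net$coords), 0)
  expect_equal(potential_energy(net, rbind(c(0, 0, 0), c(4, 0, 0))), 0.5)

  # random displacement on a 5-atom fixture vs an independent evaluator
  sel <- make_fixture("lattice", n_atoms = 5, spacing = 3,
                      jitter = 0.3, seed = 22)
  net5 <- build_network(sel, cutoff = 4.5, gamma = 1.7)
  set.seed(1)
  disp <- coords(sel) + matrix(rnorm(15, sd = 0.1), 5, 3)
  hand <- 0
  for (p in seq_len(nrow(net5$pairs))) {
    j <- net5$pairs[p, 1]; l <- net5$pairs[p, 2]
    r <- sqrt(sum((disp[j, ] - disp[l, ])^2))
    hand <- hand + 0.5 * 1.7 * (r - net5$r0[p])^2
  }
  expect_equal(potential_energy(net5, disp), hand)
  expect_error(potential_energy(net5, disp[1:4, ]), "shape")
})

test_that("two-body Hessian has a single nonzero eigenvalue of 2*gamma", {
  for (g in c(1, 2.5)) {
    net <- build_network(rbind(c(0, 0, 0), c(3, 0, 0)), cutoff = 5,
                         gamma = g)
    ev <- eigen(build_hessian(net), symmetric = TRUE, only.values = TRUE)
    expect_identical(sum(abs(ev$values) > 1e-12), 1L)
    expect_equal(max(ev$values), 2 * g, tolerance = 1e-15)
  }
})

test_that("Hessian is symmetric with exact translational null vectors", {
  sel <- make_fixture("helix", n_atoms = 15, jitter = 0.2, seed = 23)
  H <- build_hessian(build_network(sel, cutoff = 5))
  expect_identical(max(abs(H - t(H))), 0)
  n <- n_atoms(sel)
  scale <- max(abs(H))
  for (ax in 1:3) {
    tvec <- rep(as.numeric(seq_len(3) == ax), n)
    expect_lt(max(abs(H %*% tvec)), 1e-13 * scale)
  }
  # rotation generators about the centroid lie in the numeric null space
  xyz <- sweep(coords(sel), 2, colMeans(coords(sel)))
  gens <- list(cbind(-xyz[, 2], xyz[, 1], 0),
               cbind(-xyz[, 3], 0, xyz[, 1]),
               cbind(0, -xyz[, 3], xyz[, 2]))
  for (g in gens) {
    v <- as.numeric(t(g))
    expect_lt(max(abs(H %*% v)), 1e-8 * max(abs(H)) * max(abs(v)))
  }
})

test_that("analytic Hessian matches the finite-difference oracle", {
  sel <- make_fixture("lattice", n_atoms = 6, spacing = 3,
                      jitter = 0.35, seed = 24)
  net <- build_network(sel, cutoff = 4.8, gamma = 1.3)
  H <- build_hessian(net)
  Hfd <- finite_difference_hessian(net, step = 1e-4)
  expect_lt(max(abs(H - Hfd)), 1e-6)
})

test_that("duplicate coordinates in contact are rejected", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 0), c(3, 0, 0))
  expect_error(build_hessian(build_network(xyz, cutoff = 5)),
               "zero equilibrium distance")
})

test_that("spectrum is invariant under rigid rotation and linear in gamma", {
  sel <- make_fixture("lattice", n_atoms = 10, spacing = 3,
                      jitter = 0.3, seed = 25)
  xyz <- coords(sel)
  ev <- function(x, g = 1)
    compute_modes(build_hessian(build_network(x, cutoff = 4.6,
                                              gamma = g)))$values
  base <- ev(xyz)

  th <- 0.7; ph <- 1.2
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Rx <- rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)), c(0, sin(ph), cos(ph)))
  rotated <- ev(xyz %*% t(Rx %*% Rz))
  expect_equal(rotated, base, tolerance = 1e-9)

  expect_equal(ev(xyz, g = 3.5), 3.5 * base, tolerance = 1e-12)
})
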