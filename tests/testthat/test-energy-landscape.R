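test_that("regime classification follows the radii inequalities", {
  r <- radii_geometric(fix_cells(6))
  expect_identical(classify_regime(0.8, r), "IV")
  expect_identical(classify_regime(1.2, r), "III")
  expect_identical(classify_regime(1.5, r), "II")
  expect_identical(classify_regime(2.0, r), "I")
  ## boundary ties go to the larger-particle regime
  expect_identical(classify_regime(2 * r$r_in, r), "III")
  expect_identical(classify_regime(2 * r$r_out, r), "I")
})

test_that("sphere-avoiding strand energies have exact gradients", {
  set.seed(11)
  bn <- to_bead_network(fix_cells(6), N = 1, replicate_neighbors = TRUE)
  ctr <- c(0.07, 0.02, -0.04); R <- 0.8; kappa <- 1.5
  X <- bn$crosslinks + matrix(rnorm(length(bn$crosslinks), 0, 0.05), ncol = 3)
  ## keep endpoints feasible, as projection guarantees during relaxation
  A <- sweep(X, 2, ctr); dd <- sqrt(rowSums(A^2)); bad <- dd < R * 1.02
  X[bad, ] <- sweep(A[bad, , drop = FALSE] * (R * 1.02 / dd[bad]), 2, ctr, "+")
  en <- cellhop:::.network_energy(X, bn$strands, ctr, R, kappa)
  expect_gt(sum(en$blocked), 0)     # exercise the detour branch
  h <- 1e-6
  for (i in sample(nrow(X), 6)) for (c3 in 1:3) {
    Xp <- X; Xp[i, c3] <- Xp[i, c3] + h
    Xm <- X; Xm[i, c3] <- Xm[i, c3] - h
    num <- (cellhop:::.network_energy(Xp, bn$strands, ctr, R, kappa, grad = FALSE)$E -
              cellhop:::.network_energy(Xm, bn$strands, ctr, R, kappa, grad = FALSE)$E) / (2 * h)
    expect_lt(abs(en$G[i, c3] - num), 1e-6)
  }
})

test_that("cross-link relaxation matches the symmetric-dilation oracle", {
  cube <- fix_cells(6)
  bn <- to_bead_network(cube, N = 1, replicate_neighbors = TRUE)
  r <- radii_geometric(cube)
  R <- 1.05 * r$r_out
  rx <- relax_crosslinks(bn, particle_spec(2 * R), c(0, 0, 0))
  expect_true(rx$feasible)
  ## every free cross-link displaced at least to the sphere surface
  dd <- sqrt(rowSums(rx$crosslinks[!bn$pinned, ]^2))
  expect_true(all(dd >= R - 1e-8))
  ## brute-force search over symmetric radial dilation of the free vertices
  en_of <- function(s) {
    X <- bn$crosslinks
    X[!bn$pinned, ] <- X[!bn$pinned, ] * s
    cellhop:::.network_energy(X, bn$strands, c(0, 0, 0), R, 1.5,
                              grad = FALSE)$E
  }
  oracle <- min(vapply(seq(1, 1.6, by = 5e-4), en_of, numeric(1)))
  expect_lt(rx$energy, oracle + 1e-3)
  expect_gt(rx$energy, oracle - 0.2)   # full relaxation may do slightly better
  ## re-running from the returned state is stationary
  rx2 <- relax_crosslinks(bn, particle_spec(2 * R), c(0, 0, 0),
                          list(X0 = rx$crosslinks))
  expect_lt(abs(rx2$energy - rx$energy), 1e-6)
  ## Regime IV particle: nothing moves, energy equals the unperturbed network
  rx0 <- relax_crosslinks(bn, particle_spec(0.8), c(0, 0, 0),
                          list(perturb = 0))
  expect_equal(rx0$energy,
               cellhop:::.network_energy(bn$crosslinks, bn$strands,
                                         c(0, 0, 0), 0.4, 1.5,
                                         grad = FALSE)$E,
               tolerance = 1e-6)
  ## infeasible: particle swallowing the pinned shell
  rxbad <- relax_crosslinks(bn, particle_spec(4), c(0, 0, 0))
  expect_false(rxbad$feasible)
  expect_identical(rxbad$energy, Inf)
})

test_that("free-energy landscape behaves per confinement regime", {
  cube <- fix_cells(6)
  r <- radii_geometric(cube)
  ## Regime IV: flat along the whole path
  p4 <- mep_profile(cube, 0.9, n_z = 8)
  expect_lt(max(abs(p4$dF)), 0.1)
  expect_lt(p4$U_b, 1e-6)
  ## center reference is exactly zero
  env <- landscape_env(cube, 1.4)
  expect_identical(free_energy_point(env, c(0, 0, 0)), 0)
  ## confinement work at the face center is positive for d/a_x = 1.4
  expect_gt(free_energy_point(env, c(0.5, 0, 0)), 0)
  ## Regime III: zero at small z, then a delayed rise (nonconsecutive)
  p3 <- mep_profile(cube, 1.2, n_z = 16)
  expect_lt(max(abs(p3$dF[p3$z < 0.15])), 0.02)
  expect_gt(p3$U_b, 0.1)
  ## barrier grows with diameter up to the contact-dominated plateau
  Ub <- vapply(c(1.1, 1.3, 1.5, 1.7), function(d)
    mep_profile(cube, d, n_z = 8)$U_b, numeric(1))
  expect_true(all(diff(Ub) > -0.1))
  expect_gt(Ub[4], Ub[1])
})

test_that("free-energy field is symmetric under the cube point group", {
  fld <- free_energy_field(fix_cells(6), 1.4,
                           grid_spec = list(n = 5, half_width = 0.45))
  ## value at the center node is the reference zero
  expect_equal(fld$values[3, 3, 3], 0, tolerance = 1e-9)
  ## 90-degree rotations permute the axes: compare rotated pairs
  expect_equal(fld$values[1, 3, 3], fld$values[3, 1, 3], tolerance = 1e-6)
  expect_equal(fld$values[3, 5, 3], fld$values[3, 3, 5], tolerance = 1e-6)
  expect_true(all(is.finite(fld$values)))
  ## the in-face restriction has a local minimum at the face centroid:
  ## moving off-axis within the face plane raises dF
  env <- landscape_env(fix_cells(6), 1.4)
  f0 <- free_energy_point(env, c(0.5, 0, 0))
  expect_gt(free_energy_point(env, c(0.5, 0.15, 0)), f0)
  expect_gt(free_energy_point(env, c(0.5, 0, -0.15)), f0)
})

test_that("bridge survival behaves at its limits and against enumeration", {
  ## unreachable obstacle and forced intersection
  expect_equal(as.numeric(bridge_survival(c(0, 0, 0), c(1, 0, 0),
                                          c(100, 0, 0), 0.5, 8, 0.354,
                                          500, 1)), 1)
  p0 <- bridge_survival(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), 0.5, 8, 0.354,
                        500, 1)
  expect_identical(as.numeric(p0), 0)
  expect_true(attr(p0, "endpoint_inside"))
  ## deterministic given seed
  a <- bridge_survival(c(-0.5, 0.3, 0), c(0.5, 0.3, 0), c(0, 0, 0), 0.5,
                       16, 0.25, 2000, 42)
  b <- bridge_survival(c(-0.5, 0.3, 0), c(0.5, 0.3, 0), c(0, 0, 0), 0.5,
                       16, 0.25, 2000, 42)
  expect_identical(a, b)
  ## closed-form oracle at N = 2: the single interior node of a symmetric
  ## bridge is Gaussian around the sphere center with per-coordinate
  ## variance b^2/6, so the survival probability is a chi-square tail:
  ## P = P(chi2_3 > R^2 / (b^2/6)).
  bk <- 0.5; R <- 0.45
  ri <- c(-0.6, 0, 0); rj <- c(0.6, 0, 0)
  p_exact <- pchisq(R^2 / (bk^2 / 6), df = 3, lower.tail = FALSE)
  n_mc <- 40000
  p_pkg <- bridge_survival(ri, rj, c(0, 0, 0), R, 2, bk, n_mc, 7)
  se <- sqrt(p_exact * (1 - p_exact) / n_mc)
  expect_lt(abs(p_pkg - p_exact), 3 * se)
})

test_that("strand free energy = stretching plus confinement penalty", {
  ## no obstacle: exact Gaussian stretching
  expect_identical(strand_free_energy(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0),
                                      0, 16, 0.25), 1.5)
  ## |r_i - r_j| = a_x, N b^2 = a_x^2 gives 1.5 k_BT exactly
  expect_identical(strand_free_energy(c(0, 0, 0), c(0, 1, 0), c(5, 5, 5),
                                      0, 4, 0.5), 1.5)
  ## obstacle on the strand: penalty strictly positive
  f <- strand_free_energy(c(-0.5, 0.2, 0), c(0.5, 0.2, 0), c(0, 0, 0),
                          0.4, 16, 0.25, list(n_samples = 4000, seed = 3))
  expect_gt(f, 1.5)
  ## fully blocked: infinite flag
  fb <- strand_free_energy(c(-0.5, 0, 0), c(0.5, 0, 0), c(0.45, 0, 0),
                           0.449, 16, 0.25, list(n_samples = 200, seed = 3))
  expect_identical(fb, Inf)
})
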