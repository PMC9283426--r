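test_that("periodized potentials reflect, repeat and preserve the barrier", {
  prof <- mep_profile(fix_cells(6), 1.5, n_z = 16)
  pot <- periodic_potential(prof)
  expect_equal(pot$period, 2 * prof$z_face, tolerance = 1e-12)
  xs <- seq(0.01, 0.49, length.out = 7)
  ## mirror symmetry about the face plane and the next cell center
  expect_equal(pot$dF(pot$z_face + xs), pot$dF(pot$z_face - xs),
               tolerance = 1e-9)
  expect_equal(pot$dF(2 * pot$z_face), pot$dF(0), tolerance = 1e-9)
  expect_equal(pot$dF(xs + 3 * pot$period), pot$dF(xs), tolerance = 1e-9)
  ## max over one period equals the profile barrier (within interpolation)
  zz <- seq(0, pot$period, length.out = 2001)
  expect_equal(max(pot$dF(zz)), prof$U_b, tolerance = 0.02 * max(prof$U_b, 0.1))
  expect_error(periodic_potential(list(z = c(0, 1), dF = c(0, Inf))),
               "finite")
})

test_that("free diffusion recovers D0 = kBT/gamma and Gaussian van Hove", {
  ens <- simulate_nle(NULL, nle_config(t_total = 1e4, n_replicas = 8,
                                       seed = 42))
  est <- diffusion_coefficient(ens)
  expect_lt(abs(est$D - 0.1), 3 * est$se + 0.001 * 0.1)  # EM bias < 1%
  ## VACF and MSD routes agree
  expect_lt(abs(est$D - est$D_msd) / est$D, 0.15)
  ## determinism
  tr1 <- simulate_nle(NULL, nle_config(t_total = 100, seed = 7))
  tr2 <- simulate_nle(NULL, nle_config(t_total = 100, seed = 7))
  expect_identical(tr1$z, tr2$z)
  ## van Hove at lag t: Gaussian with variance 2 D0 t
  vh <- van_hove(ens, c(5, 20))
  dz <- diff(vh$z_grid)[1]
  for (j in 1:2) {
    expect_equal(sum(vh$G_s[, j]) * dz, 1, tolerance = 1e-6)
    v_obs <- sum(vh$G_s[, j] * vh$z_grid^2) * dz
    expect_equal(v_obs, 2 * 0.1 * vh$t_slices[j], tolerance = 0.12)
  }
  ## Kolmogorov-Smirnov against the exact law at one slice
  L <- round(5 / (ens$replicas[[1]]$config$dt *
                    ens$replicas[[1]]$config$out_stride))
  disp <- unlist(lapply(ens$replicas, function(tr) {
    n <- length(tr$z)
    orig <- seq(1L, n - L, by = max(1L, L))   # non-overlapping windows
    tr$z[orig + L] - tr$z[orig]
  }))
  ks <- suppressWarnings(ks.test(disp, "pnorm", 0, sqrt(2 * 0.1 * 5)))
  expect_gt(ks$p.value, 0.01)
})

test_that("equilibrium histogram follows the Boltzmann weight", {
  prof <- list(z = seq(0, 0.5, length.out = 33),
               dF = 1.5 * sin(seq(0, 0.5, length.out = 33) * pi)^2)
  pot <- periodic_potential(prof)
  tr <- simulate_nle(pot, nle_config(t_total = 4e4, seed = 31))
  ## thin to approximately independent samples (a few intra-cell times)
  zz <- (tr$z %% pot$period)[seq(1, length(tr$z), by = 500)]
  brk <- seq(0, pot$period, length.out = 13)
  cnt <- hist(zz, breaks = brk, plot = FALSE)$counts
  zc <- (brk[-1] + brk[-13]) / 2
  p <- exp(-pot$dF(zc)); p <- p / sum(p)
  chi <- sum((cnt - sum(cnt) * p)^2 / (sum(cnt) * p))
  expect_gt(pchisq(chi, df = 11, lower.tail = FALSE), 0.01)
})

test_that("event detection recovers ground truth and jump statistics", {
  ## constructed telegraph signal: exact recovery
  jt <- c(12.5, 30.1, 55.7, 80.3)
  traj <- make_telegraph(jt, period = 1, t_total = 100, dt = 0.1)
  ev <- detect_events(traj, 1)
  expect_identical(ev$n_events, 4L)
  expect_equal(ev$jump_times, jt, tolerance = 0.1)
  expect_true(all(abs(ev$jumps) == 1))
  expect_true(ev$wide_uncertainty)
  ## trapped run: no events, undefined waiting time
  flat <- make_telegraph(numeric(0), period = 1)
  ev0 <- detect_events(flat, 1)
  expect_identical(ev0$n_events, 0L)
  expect_true(is.na(ev0$t_w))
  ## free diffusion: jump counts grow linearly, slope consistent with 1/t_w
  tr <- simulate_nle(NULL, nle_config(t_total = 2e4, seed = 3))
  evf <- detect_events(tr, 1)
  expect_gt(evf$n_events, 200)
  Nt <- seq_along(evf$jump_times)
  fit <- lm(Nt ~ evf$jump_times)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_lt(abs(coef(fit)[2] - 1 / evf$t_w) / (1 / evf$t_w), 0.05)
})

test_that("motion classification separates the three dynamical types", {
  ## Brownian: flat landscape
  ens_b <- simulate_nle(NULL, nle_config(t_total = 2e4, n_replicas = 8,
                                         seed = 11))
  ev_b <- detect_events(ens_b$replicas[[1]], 1)
  expect_identical(classify_motion(msd_curve(ens_b), ev_b), "Brownian")
  ## hopping: moderate sinusoidal barrier
  prof <- list(z = seq(0, 0.5, length.out = 33),
               dF = 4 * sin(seq(0, 0.5, length.out = 33) * pi)^2)
  pot <- periodic_potential(prof)
  ens_h <- simulate_nle(pot, nle_config(t_total = 2e4, n_replicas = 8,
                                        seed = 12))
  ev_h <- detect_events(ens_h$replicas[[1]], pot$period)
  expect_gt(ev_h$n_events, 0)
  expect_identical(classify_motion(msd_curve(ens_h), ev_h), "hopping")
  ## trapped: high barrier, no escape within the run
  prof_t <- list(z = seq(0, 0.5, length.out = 33),
                 dF = 14 * sin(seq(0, 0.5, length.out = 33) * pi)^2)
  pot_t <- periodic_potential(prof_t)
  ens_t <- simulate_nle(pot_t, nle_config(t_total = 2e4, n_replicas = 8,
                                          seed = 13))
  ev_t <- detect_events(ens_t$replicas[[1]], pot_t$period)
  expect_identical(ev_t$n_events, 0L)
  expect_identical(classify_motion(msd_curve(ens_t), ev_t), "trapped")
  expect_error(classify_motion(structure(list(t = c(1, 2), msd = c(1, 2)),
                                         class = "msd_curve"), ev_t),
               "3 decades")
})

test_that("friction models scale as stated", {
  expect_identical(effective_friction(1, "rouse_coupling", 10), 10)
  expect_identical(effective_friction(2, "rouse_coupling", 10), 80)
  expect_identical(effective_friction(2, "stokes", 10), 20)
  expect_error(effective_friction(-1), "positive")
})

test_that("seed derivation is deterministic, distinct and bounded", {
  s1 <- derive_seed(1, 2, 3)
  expect_identical(s1, derive_seed(1, 2, 3))
  expect_false(s1 == derive_seed(1, 3, 2))
  ss <- vapply(1:500, function(i) derive_seed(7, i), integer(1))
  expect_identical(length(unique(ss)), 500L)
  expect_true(all(ss >= 0 & ss < 2^31))
})
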