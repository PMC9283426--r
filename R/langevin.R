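#' NLE simulation configuration
#'
#' Natural units: mesh size `a_x` = 1 (length), `tau` (time), `k_B T` = 1
#' (energy), particle mass `m` = 1.  Defaults follow the production settings
#' of the method: time step 0.01 tau and friction rate gamma/m = 10 / tau.
#'
#' @param dt integration time step (tau).
#' @param gamma_over_m friction rate (1/tau).
#' @param m particle mass.
#' @param kBT thermal energy.
#' @param t_total run length (tau).  Production value is 1e7 tau; the default
#'   here is a scaled-down 1e5 tau suitable for desk-scale runs.
#' @param seed integer seed.
#' @param n_replicas independent replicas.
#' @param out_stride store every `out_stride`-th step (default 0.1 tau worth).
#' @param vacf_max_lag maximum velocity-autocorrelation lag (tau).
#' @param burn_in equilibration time discarded from averages (tau).
#' @return List of class `nle_config`.
#' @export
nle_config <- function(dt = 0.01, gamma_over_m = 10, m = 1, kBT = 1,
                       t_total = 1e5, seed = 1L, n_replicas = 1L,
                       out_stride = NULL, vacf_max_lag = NULL,
                       burn_in = NULL) {
  if (dt <= 0 || gamma_over_m <= 0) stop("dt and gamma_over_m must be positive")
  if (is.null(out_stride)) out_stride <- max(1L, round(0.1 / dt))
  if (is.null(vacf_max_lag)) vacf_max_lag <- 30 * m / (gamma_over_m * m)
  if (is.null(burn_in)) burn_in <- min(0.05 * t_total, 100)
  structure(list(dt = dt, gamma_over_m = gamma_over_m, m = m, kBT = kBT,
                 t_total = t_total, seed = as.integer(seed),
                 n_replicas = as.integer(n_replicas),
                 out_stride = as.integer(out_stride),
                 vacf_max_lag = vacf_max_lag, burn_in = burn_in),
            class = "nle_config")
}

#' Periodize a half-cell MEP profile onto the whole line
#'
#' Even reflection of \eqn{\Delta F(z)} about `z = 0` and about
#' `z = z_face`, then periodic continuation with period `2 z_face`: minima at
#' even multiples of `z_face` (cell centers), barrier `U_b` at odd multiples
#' (face centers).  Periodic cubic-spline interpolation with a continuous
#' first derivative.
#'
#' @param profile an `mep_profile` (fields `z`, `dF`) or a list with `z`,
#'   `dF` on `[0, z_face]`.
#' @return List of class `periodic_potential`: functions `dF(z)`,
#'   `dFprime(z)`, plus `period`, `U_b`, `z_face`.
#' @export
periodic_potential <- function(profile) {
  z <- profile$z; dF <- profile$dF
  if (any(!is.finite(dF))) stop("profile contains non-finite values")
  z_face <- max(z)
  ## mirrored second half; drop duplicated joint points
  z2 <- c(z, 2 * z_face - rev(z)[-1])
  f2 <- c(dF, rev(dF)[-1])
  period <- 2 * z_face
  ## periodic spline needs f(0) == f(period): true by construction (both dF[1])
  sp <- splinefun(z2, f2, method = "periodic")
  wrap <- function(x) x - floor(x / period) * period
  structure(list(
    dF = function(x) sp(wrap(x)),
    dFprime = function(x) sp(wrap(x), deriv = 1),
    period = period, z_face = z_face, U_b = max(dF)),
    class = "periodic_potential")
}

## Tabulate the potential derivative over one period for the C++ integrator.
.potential_grid <- function(potential, n = 4096L) {
  if (is.null(potential)) return(list(grid = numeric(0), period = 1))
  zz <- seq(0, potential$period, length.out = n + 1L)[-(n + 1L)]
  list(grid = potential$dFprime(zz), period = potential$period)
}

#' Simulate the nonlinear Langevin equation on a periodic landscape
#'
#' Euler-Maruyama integration of
#' \deqn{m \ddot z = -\Delta F'(z) - \gamma \dot z + \xi(t), \qquad
#'       \langle \xi(t)\xi(t')\rangle = 2\gamma k_B T\, \delta(t - t')}
#' starting from `z = 0` with a Maxwell-distributed initial velocity.
#' Deterministic given the seed.
#'
#' @param potential a `periodic_potential`, or `NULL` for free diffusion.
#' @param config an `nle_config`.
#' @return For one replica an object of class `nle_trajectory` with thinned
#'   `t`, `z`, `v`, the velocity autocorrelation `vacf` (`vacf_dt` spacing),
#'   and `config`.  For `n_replicas > 1` an `nle_ensemble` (list of
#'   trajectories with replica-derived seeds).
#' @export
simulate_nle <- function(potential = NULL, config = nle_config()) {
  stopifnot(inherits(config, "nle_config"))
  if (config$n_replicas > 1L) {
    runs <- lapply(seq_len(config$n_replicas), function(r) {
      cfg <- config
      cfg$n_replicas <- 1L
      cfg$seed <- derive_seed(config$seed, r)
      simulate_nle(potential, cfg)
    })
    return(structure(list(replicas = runs, config = config),
                     class = "nle_ensemble"))
  }
  pg <- .potential_grid(potential)
  nsteps <- ceiling(config$t_total / config$dt)
  vacf_lags <- as.integer(round(config$vacf_max_lag / config$dt))
  set.seed(config$seed)
  v0 <- rnorm(1, 0, sqrt(config$kBT / config$m))
  res <- nle_run_cpp(0, v0, config$dt, nsteps,
                     config$gamma_over_m * config$m, config$m, config$kBT,
                     pg$grid, pg$period,
                     config$out_stride, vacf_lags,
                     max(1L, vacf_lags %/% 4L),
                     config$burn_in / config$dt)
  structure(list(t = config$dt + config$dt * config$out_stride *
                   (seq_along(res$z) - 1),
                 z = res$z, v = res$v,
                 vacf = res$vacf, vacf_dt = config$dt,
                 potential = potential, config = config),
            class = "nle_trajectory")
}

#' @export
print.nle_trajectory <- function(x, ...) {
  cat(sprintf("NLE trajectory: %d stored points, t_total = %g tau, dt = %g tau\n",
              length(x$z), x$config$t_total, x$config$dt))
  invisible(x)
}

#' Diffusion coefficient from the velocity autocorrelation
#'
#' Green-Kubo estimate \eqn{D = \int_0^{t_c} \langle v(t) v(0)\rangle dt}
#' (trapezoidal, automatic cutoff where the VACF has decayed), cross-checked
#' against half the long-time MSD slope.
#'
#' @param obj an `nle_trajectory` or `nle_ensemble`.
#' @return List of class `diffusion_estimate`: `D` (VACF route), `D_msd`
#'   (MSD-slope route), `se` (between-replica standard error, ensembles only),
#'   `reliable` (VACF decayed at the cutoff).
#' @export
diffusion_coefficient <- function(obj) {
  if (inherits(obj, "nle_ensemble")) {
    per <- vapply(obj$replicas, function(tr) diffusion_coefficient(tr)$D,
                  numeric(1))
    per_msd <- vapply(obj$replicas, function(tr) diffusion_coefficient(tr)$D_msd,
                      numeric(1))
    return(structure(list(D = mean(per), D_msd = mean(per_msd),
                          se = sd(per) / sqrt(length(per)),
                          per_replica = per, reliable = TRUE),
                     class = "diffusion_estimate"))
  }
  stopifnot(inherits(obj, "nle_trajectory"))
  vacf <- obj$vacf
  dt <- obj$vacf_dt
  n <- length(vacf)
  ## cutoff: lag where |vacf| has fully decayed (0.1% of vacf(0)), else the end
  small <- abs(vacf) < 1e-3 * vacf[1]
  cut <- if (any(small)) which(small)[1] else n
  D <- sum((vacf[1:(cut - 1)] + vacf[2:cut]) / 2) * dt
  reliable <- abs(vacf[cut]) < 0.05 * vacf[1]
  ## MSD-slope cross-check on the stored (thinned) positions
  msd <- msd_curve(obj, n_lags = 12L)
  k <- length(msd$t)
  win <- max(1, k - 4):k
  D_msd <- unname(coef(lm(msd$msd[win] ~ msd$t[win]))[2] / 2)
  structure(list(D = D, D_msd = D_msd, se = NA_real_, reliable = reliable),
            class = "diffusion_estimate")
}

#' Mean-squared displacement of stored trajectories
#'
#' Time-averaged MSD over log-spaced lags using subsampled time origins;
#' for ensembles the replica MSDs are averaged.
#'
#' @param obj an `nle_trajectory` or `nle_ensemble`.
#' @param n_lags number of log-spaced lags.
#' @param t_max maximum lag time (default 1/4 of the run).
#' @return List of class `msd_curve` with `t`, `msd`.
#' @export
msd_curve <- function(obj, n_lags = 40L, t_max = NULL) {
  if (inherits(obj, "nle_ensemble")) {
    curves <- lapply(obj$replicas, msd_curve, n_lags = n_lags, t_max = t_max)
    msd <- rowMeans(do.call(cbind, lapply(curves, `[[`, "msd")))
    return(structure(list(t = curves[[1]]$t, msd = msd), class = "msd_curve"))
  }
  stopifnot(inherits(obj, "nle_trajectory"))
  z <- obj$z
  dt_s <- obj$config$dt * obj$config$out_stride
  n <- length(z)
  if (is.null(t_max)) t_max <- n * dt_s / 4
  max_lag <- max(2L, min(n - 2L, floor(t_max / dt_s)))
  lags <- unique(pmax(1L, round(exp(seq(log(1), log(max_lag),
                                        length.out = n_lags)))))
  msd <- vapply(lags, function(L) {
    orig <- seq(1L, n - L, by = max(1L, (n - L) %/% 2000L))
    mean((z[orig + L] - z[orig])^2)
  }, numeric(1))
  structure(list(t = lags * dt_s, msd = msd), class = "msd_curve")
}

#' Decompose a trajectory into jump and waiting events
#'
#' The trajectory is coarse-grained into cell indices `round(z / period)`;
#' an index change is committed only once the trajectory reaches the new
#' cell's core region (within a quarter period of its center), which prevents
#' barrier-top recrossings from being counted as jumps.  The characteristic
#' waiting time `t_w` is the mean inter-event time.
#'
#' @param traj an `nle_trajectory`.
#' @param period MEP period (two inradii).
#' @return List of class `event_series`: `jump_times`, `jumps` (signed
#'   displacements), `waits`, `t_w`, `n_events`, `wide_uncertainty` flag.
#' @export
detect_events <- function(traj, period) {
  stopifnot(inherits(traj, "nle_trajectory"))
  z <- traj$z
  t <- traj$t
  idx <- round(z / period)
  core <- abs(z - idx * period) < 0.25 * period
  jt <- numeric(0); jumps <- numeric(0)
  core_i <- which(core)
  if (length(core_i)) {
    seq_idx <- idx[core_i]
    ## events: positions in the core-sample sequence where the index changes
    changed <- which(diff(c(0L, seq_idx)) != 0L)
    prev <- 0L
    for (w in changed) {
      jt <- c(jt, t[core_i[w]])
      jumps <- c(jumps, (seq_idx[w] - prev) * period)
      prev <- seq_idx[w]
    }
  }
  waits <- diff(c(0, jt))
  t_w <- if (length(waits)) mean(waits) else NA_real_
  structure(list(jump_times = jt, jumps = jumps, waits = waits, t_w = t_w,
                 n_events = length(jt),
                 wide_uncertainty = length(jt) < 10),
            class = "event_series")
}

#' Self part of the van Hove displacement distribution
#'
#' Normalized histograms of displacements \eqn{z(t_0 + t) - z(t_0)} at the
#' requested lag times, pooled over replicas and time origins.
#'
#' @param ensemble an `nle_ensemble` (or a single trajectory).
#' @param t_slices lag times (tau).
#' @param n_bins displacement bins.
#' @return List of class `van_hove`: `t_slices`, `z_grid` (bin centers),
#'   `G_s` (matrix, one column per slice; each integrates to 1).
#' @export
van_hove <- function(ensemble, t_slices, n_bins = 101L) {
  trajs <- if (inherits(ensemble, "nle_ensemble")) ensemble$replicas
           else list(ensemble)
  dt_s <- trajs[[1]]$config$dt * trajs[[1]]$config$out_stride
  disp <- lapply(t_slices, function(ts) {
    L <- max(1L, round(ts / dt_s))
    unlist(lapply(trajs, function(tr) {
      n <- length(tr$z)
      if (L >= n) return(numeric(0))
      orig <- seq(1L, n - L, by = max(1L, (n - L) %/% 500L))
      tr$z[orig + L] - tr$z[orig]
    }))
  })
  zmax <- max(abs(unlist(disp)), 1e-8)
  brk <- seq(-zmax * 1.001, zmax * 1.001, length.out = n_bins + 1L)
  dz <- diff(brk)[1]
  G <- vapply(disp, function(d) {
    h <- hist(d, breaks = brk, plot = FALSE)$counts
    h / sum(h) / dz
  }, numeric(n_bins))
  structure(list(t_slices = t_slices, z_grid = (brk[-1] + brk[-length(brk)]) / 2,
                 G_s = G), class = "van_hove")
}

#' Classify the motion type from MSD and events
#'
#' Brownian: the local log-log MSD slope stays in [0.9, 1.1] after the
#' ballistic regime.  Trapped: the MSD plateaus (final slope < 0.1) with no
#' committed jump events.  Hopping: otherwise (a slowed-down MSD together
#' with jump events).  A run with no events but no clean plateau either is
#' ambiguous and labelled "mixed".
#'
#' @param msd an `msd_curve` spanning at least 3 decades in t.
#' @param events an `event_series`.
#' @param ballistic_t end of the ballistic regime, i.e. where slope
#'   estimation starts (default 2 tau, about 20 m / gamma at the standard
#'   friction rate gamma/m = 10 / tau; pass explicitly for other frictions).
#' @return One of `"Brownian"`, `"hopping"`, `"trapped"`, `"mixed"`.
#' @export
classify_motion <- function(msd, events, ballistic_t = 2) {
  stopifnot(inherits(msd, "msd_curve"))
  if (log10(max(msd$t) / min(msd$t)) < 3)
    stop("MSD must span at least 3 decades in t")
  keep <- msd$t >= ballistic_t & msd$msd > 0
  lt <- log(msd$t[keep]); lm_ <- log(msd$msd[keep])
  ## local slopes over sliding half-decade windows
  slopes <- vapply(seq_along(lt), function(i) {
    w <- which(abs(lt - lt[i]) < log(3))
    if (length(w) < 3) return(NA_real_)
    unname(coef(lm(lm_[w] ~ lt[w]))[2])
  }, numeric(1))
  slopes <- slopes[!is.na(slopes)]
  n_events <- if (is.null(events)) 0L else events$n_events
  final_slope <- mean(tail(slopes, 3))
  if (all(slopes > 0.9 & slopes < 1.1)) "Brownian"
  else if (n_events == 0) {
    if (final_slope < 0.1) "trapped" else "mixed"
  } else "hopping"
}

#' Size-dependent friction models
#'
#' `stokes`: \eqn{\gamma \propto d} (continuum Stokes drag).
#' `rouse_coupling`: \eqn{\gamma \propto d^3 / a_x^2}, i.e. the friction a
#' particle experiences when coupled to the local Rouse modes of the strands,
#' giving \eqn{D_0 \propto (d/a_x)^{-3}}.  Normalized so
#' `gamma(d = a_x) = gamma_ref`.
#'
#' @param d particle diameter.
#' @param model `"stokes"` or `"rouse_coupling"`.
#' @param gamma_ref friction at `d = a_x` (default 10).
#' @param a_x mesh size.
#' @return Friction coefficient gamma.
#' @export
effective_friction <- function(d, model = c("rouse_coupling", "stokes"),
                               gamma_ref = 10, a_x = 1) {
  model <- match.arg(model)
  if (any(d <= 0)) stop("d must be positive")
  switch(model,
         rouse_coupling = gamma_ref * (d / a_x)^3,
         stokes = gamma_ref * (d / a_x))
}

#' Deterministic seed derivation
#'
#' Derives child seeds from a base seed (kept below 2^31) so that all
#' randomness in a pipeline flows from a single documented root.
#'
#' @param base integer base seed.
#' @param ... integer stream identifiers.
#' @return Integer seed.
#' @export
derive_seed <- function(base, ...) {
  ids <- c(base, ...)
  s <- 0
  for (x in ids) s <- (s * 69069 + as.numeric(x) + 1) %% 2147483647
  as.integer(s)
}
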