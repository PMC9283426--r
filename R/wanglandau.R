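#' Wang-Landau Monte Carlo configuration
#'
#' Flat-histogram schedule: a penalty increment `f0` (default 0.5 k_BT) is
#' deposited in the current z-bin at every attempt; when every bin's count
#' reaches `flatness` times the mean count the increment is multiplied by
#' `reduction` and the histogram resets; the run terminates when the
#' increment falls below `f_min`.
#'
#' @param f0 initial penalty increment (k_BT).
#' @param flatness histogram flatness criterion, fraction of the mean.
#' @param reduction penalty reduction factor per stage.
#' @param f_min terminal increment (k_BT).
#' @param n_sweeps_max cap on total sweeps.
#' @param move_site bead/cross-link trial displacement (a_x).
#' @param move_particle particle 1-D trial displacement (a_x).
#' @param n_bins bins along the MEP.
#' @param check_every flatness check interval (sweeps).
#' @param seed integer seed.
#' @return List of class `mc_config`.
#' @export
mc_config <- function(f0 = 0.5, flatness = 0.8, reduction = 0.5,
                      f_min = 1e-4, n_sweeps_max = 2e5, move_site = 0.3,
                      move_particle = 0.1, n_bins = 32L, check_every = 50L,
                      seed = 1L) {
  if (flatness <= 0 || flatness >= 1) stop("flatness must be in (0, 1)")
  if (reduction <= 0 || reduction >= 1) stop("reduction must be in (0, 1)")
  structure(list(f0 = f0, flatness = flatness, reduction = reduction,
                 f_min = f_min, n_sweeps_max = n_sweeps_max,
                 move_site = move_site, move_particle = move_particle,
                 n_bins = as.integer(n_bins),
                 check_every = as.integer(check_every),
                 seed = as.integer(seed)),
            class = "mc_config")
}

## Initial feasible site configuration: any site within R of the particle at
## z_init is pushed radially just outside the sphere.
.feasible_sites <- function(network, R, ppos) {
  X <- network$sites
  d <- sqrt(rowSums(sweep(X, 2, ppos)^2))
  bad <- d < R & !network$site_fixed
  if (any(bad)) {
    A <- sweep(X[bad, , drop = FALSE], 2, ppos)
    nz <- sqrt(rowSums(A^2))
    nz[nz < 1e-12] <- 1e-12
    X[bad, ] <- sweep(A * (R * 1.05 / nz), 2, ppos, "+")
  }
  if (any(d < R & network$site_fixed))
    stop("pinned site overlaps the particle: infeasible configuration")
  X
}

#' Wang-Landau free-energy profile along the MEP
#'
#' Flat-histogram Monte Carlo of a bead-spring network with a hard-sphere
#' particle confined to the MEP axis.  The converged bias gives the free
#' energy, \eqn{\beta F(z) = -f(z)}, reported shifted so `F(0) = 0`.
#' Deterministic given the seed.
#'
#' @param network a `bead_network` (beads plus cross-links; pinned sites do
#'   not move).
#' @param particle a `particle_spec` or diameter.
#' @param frame an `mep_frame` (bins cover `[0, z_face]`).
#' @param config an `mc_config`.
#' @return An `mep_profile` (bin centers as `z`) with extra fields
#'   `converged`, `stages`, `sweeps`, `histogram`.
#' @export
wang_landau_profile <- function(network, particle, frame,
                                config = mc_config()) {
  stopifnot(inherits(network, "bead_network"), inherits(frame, "mep_frame"))
  if (is.numeric(particle)) particle <- particle_spec(particle)
  R <- particle$R
  kspring <- 3 / (2 * network$b^2)
  sites <- .feasible_sites(network, R, c(0, 0, 0))
  set.seed(config$seed)
  res <- wang_landau_cpp(sites, network$site_fixed,
                         network$springs - 1L, kspring,
                         frame$axis, R, frame$z_face, config$n_bins,
                         config$f0, config$flatness, config$reduction,
                         config$f_min, config$n_sweeps_max,
                         config$move_site, config$move_particle, 0,
                         config$check_every, FALSE)
  binw <- frame$z_face / config$n_bins
  zc <- (seq_len(config$n_bins) - 0.5) * binw
  F_z <- -res$bias
  F_z <- F_z - F_z[1]
  radii <- radii_geometric(network$cell)
  structure(list(z = zc, dF = F_z, U_b = max(F_z), d = particle$d,
                 g_label = network$cell$g_label, z_face = frame$z_face,
                 regime = classify_regime(particle, radii),
                 truncated = FALSE, converged = res$converged,
                 stages = res$stage, sweeps = res$sweeps,
                 histogram = res$histogram),
            class = "mep_profile")
}

#' Multi-run Wang-Landau mean profile and standard error
#'
#' Runs `n_runs` independent Wang-Landau samplings with seeds derived from
#' the config's base seed and reports the per-bin mean and standard error of
#' `F(z)` (each run aligned to `F(0) = 0`).  Non-converged runs are excluded
#' and counted.
#'
#' @param network a `bead_network`.
#' @param particle a `particle_spec` or diameter.
#' @param frame an `mep_frame`.
#' @param config an `mc_config`.
#' @param n_runs number of independent runs (the production protocol uses at
#'   least 50).
#' @return List of class `wl_multi`: `z`, `mean`, `se`, `max_se`, `n_used`,
#'   `n_excluded`, `profiles`.
#' @export
multi_run_error <- function(network, particle, frame, config = mc_config(),
                            n_runs = 50L) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  profiles <- lapply(seq_len(n_runs), function(r) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 7L, r)
    wang_landau_profile(network, particle, frame, cfg)
  })
  ok <- vapply(profiles, `[[`, logical(1), "converged")
  used <- profiles[ok]
  if (length(used) < 2) stop("fewer than two converged runs")
  Fm <- do.call(cbind, lapply(used, `[[`, "dF"))
  mu <- rowMeans(Fm)
  se <- apply(Fm, 1, sd) / sqrt(ncol(Fm))
  structure(list(z = used[[1]]$z, mean = mu, se = se, max_se = max(se),
                 n_used = length(used), n_excluded = sum(!ok),
                 profiles = profiles),
            class = "wl_multi")
}

#' @export
print.wl_multi <- function(x, ...) {
  cat(sprintf("Wang-Landau multi-run profile: %d runs used (%d excluded), max SE = %.3g k_BT\n",
              x$n_used, x$n_excluded, x$max_se))
  invisible(x)
}

#' Unbiased Metropolis reference sampling
#'
#' Plain Metropolis sampling of the bead-spring network with the particle
#' frozen at a position; used to validate the Wang-Landau bias through
#' thermodynamic-perturbation spot checks and equipartition.
#'
#' @param network a `bead_network`.
#' @param particle a `particle_spec` or diameter (`NULL` or `d = 0` for no
#'   particle).
#' @param position particle center (3-vector).
#' @param config an `mc_config` (uses `move_site`, `seed`).
#' @param n_sweeps sampling sweeps.
#' @param burn_in discarded sweeps.
#' @return List: `mean_energy`, `mean_energy_per_spring` (k_BT),
#'   `acceptance`, `overlap_fraction`; warns when acceptance < 1%.
#' @export
metropolis_reference <- function(network, particle = NULL,
                                 position = c(0, 0, 0),
                                 config = mc_config(), n_sweeps = 5000,
                                 burn_in = 500) {
  stopifnot(inherits(network, "bead_network"))
  R <- if (is.null(particle)) 0 else {
    if (is.numeric(particle)) particle <- particle_spec(particle)
    particle$R
  }
  kspring <- 3 / (2 * network$b^2)
  sites <- if (R > 0) .feasible_sites(network, R, position) else network$sites
  set.seed(config$seed)
  out <- metropolis_cpp(sites, network$site_fixed, network$springs - 1L,
                        kspring, as.numeric(position), R,
                        n_sweeps, burn_in, config$move_site)
  if (out$acceptance < 0.01)
    warning("Metropolis acceptance below 1%; reduce move_site")
  out
}
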