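#' Particle specification
#'
#' @param d hard-sphere diameter in units of the mesh size `a_x`.
#' @return List of class `particle_spec` with `d` and radius `R = d/2`.
#' @export
particle_spec <- function(d) {
  if (!is.numeric(d) || d <= 0) stop("particle diameter d must be positive")
  structure(list(d = d, R = d / 2), class = "particle_spec")
}

#' Classify the confinement regime of a particle in a cell
#'
#' Regimes are set by the particle radius `R = d/2` against the cell's
#' characteristic radii: Regime I `R > r_out` (deforms cross-links), II
#' `r_mid < R < r_out` (deforms strands), III `r_in < R < r_mid` (feels the
#' faces), IV `R < r_in` (free).  Boundary equalities go to the larger-particle
#' regime.
#'
#' @param particle a `particle_spec` (or a diameter).
#' @param radii a `radii_triple`.
#' @return Character scalar `"I"`, `"II"`, `"III"` or `"IV"`.
#' @export
classify_regime <- function(particle, radii) {
  if (is.numeric(particle)) particle <- particle_spec(particle)
  R <- particle$R
  if (R >= radii$r_out) "I"
  else if (R >= radii$r_mid) "II"
  else if (R >= radii$r_in) "III"
  else "IV"
}

## ---------------------------------------------------------------------------
## Sphere-avoiding geodesic ("taut string") length of a strand and its
## gradient w.r.t. both endpoints; vectorized over strands.
##
## For endpoints p, q outside a sphere (center ctr, radius R) the shortest
## path avoiding the sphere is either the straight segment or
## tangent-line + great-circle-arc + tangent-line:
##   L = sqrt(da^2 - R^2) + sqrt(db^2 - R^2) + R * (gamma - alpha - beta)
## with da = |p - ctr|, db = |q - ctr|, gamma the angle between the endpoint
## directions, alpha = acos(R/da), beta = acos(R/db).
## ---------------------------------------------------------------------------
.seg_geo <- function(P, Q, ctr, R, grad = TRUE) {
  A <- sweep(P, 2, ctr); B <- sweep(Q, 2, ctr)
  da <- sqrt(rowSums(A^2)); db <- sqrt(rowSums(B^2))
  D <- Q - P
  L_str <- sqrt(rowSums(D^2))
  if (R <= 0) {
    G <- if (grad) -D / L_str else NULL  # dL/dP
    return(list(L = L_str, blocked = rep(FALSE, nrow(P)), gP = G,
                gQ = if (grad) -G else NULL))
  }
  ## clamp endpoint distances marginally outside the sphere for stability
  da <- pmax(da, R * (1 + 1e-12)); db <- pmax(db, R * (1 + 1e-12))
  U <- A / da; W <- B / db
  cosg <- pmin(1, pmax(-1, rowSums(U * W)))
  gamma <- acos(cosg)
  alpha <- acos(pmin(1, R / da)); beta <- acos(pmin(1, R / db))
  arc <- gamma - alpha - beta
  ## segment-sphere proximity: nearest point on segment to the center
  tstar <- pmin(1, pmax(0, -rowSums(A * D) / pmax(rowSums(D^2), 1e-300)))
  near2 <- rowSums((A + tstar * D)^2)
  blocked <- arc > 0 & near2 < R^2 & tstar > 0 & tstar < 1
  L <- L_str
  L[blocked] <- (sqrt(da^2 - R^2) + sqrt(db^2 - R^2) + R * arc)[blocked]
  gP <- gQ <- NULL
  if (grad) {
    gP <- -D / L_str; gQ <- D / L_str        # straight-segment branch
    if (any(blocked)) {
      ib <- which(blocked)
      sing <- pmax(sqrt(pmax(0, 1 - cosg[ib]^2)), 1e-12)
      dgam_dP <- -(W[ib, , drop = FALSE] - cosg[ib] * U[ib, , drop = FALSE]) /
        (da[ib] * sing)
      dgam_dQ <- -(U[ib, , drop = FALSE] - cosg[ib] * W[ib, , drop = FALSE]) /
        (db[ib] * sing)
      gP[ib, ] <- (sqrt(da[ib]^2 - R^2) / da[ib]) * U[ib, , drop = FALSE] +
        R * dgam_dP
      gQ[ib, ] <- (sqrt(db[ib]^2 - R^2) / db[ib]) * W[ib, , drop = FALSE] +
        R * dgam_dQ
    }
  }
  list(L = L, blocked = blocked, gP = gP, gQ = gQ)
}

## Total saddle-path network energy (k_BT) and gradient w.r.t. cross-links.
## kappa = 3 / (2 N b^2) = 3 / (2 a_x^2) since sqrt(N) b = a_x.
.network_energy <- function(X, strands, ctr, R, kappa, grad = TRUE) {
  P <- X[strands[, 1], , drop = FALSE]
  Q <- X[strands[, 2], , drop = FALSE]
  sg <- .seg_geo(P, Q, ctr, R, grad = grad)
  E <- kappa * sum(sg$L^2)
  G <- NULL
  if (grad) {
    GP <- 2 * kappa * sg$L * sg$gP
    GQ <- 2 * kappa * sg$L * sg$gQ
    G <- matrix(0, nrow(X), 3)
    for (col in 1:3) {
      G[, col] <- tabulate_sum(strands[, 1], GP[, col], nrow(X)) +
        tabulate_sum(strands[, 2], GQ[, col], nrow(X))
    }
  }
  list(E = E, G = G, L = sg$L, blocked = sg$blocked)
}

## sum `vals` into bins `idx` of length n (base-R scatter-add)
tabulate_sum <- function(idx, vals, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Relax cross-links around a fixed particle (saddle point)
#'
#' Minimizes the total strand free energy \eqn{\sum_s (3/2) L_s^2 / (N b^2)}
#' over the free cross-link positions, where \eqn{L_s} is the length of the
#' shortest strand path avoiding the hard sphere (the saddle-point path of the
#' Gaussian-chain Hamiltonian under hard-sphere exclusion), subject to the
#' hard constraint that every free cross-link stays outside the particle.
#' Pinned (outer-shell) cross-links do not move.  Projected gradient descent
#' with backtracking; deterministic.
#'
#' @param network a `bead_network` (cross-link level is used).
#' @param particle a `particle_spec`.
#' @param position particle center (3-vector).
#' @param opts list: `maxit` (default 5000), `tol` energy tolerance (1e-10),
#'   `step0` initial step, `X0` warm-start cross-link positions, `perturb`
#'   amplitude of the deterministic symmetry-breaking perturbation applied to
#'   cold starts (default 1e-3; highly symmetric configurations are otherwise
#'   saddle points of the descent).
#' @return List: `crosslinks` relaxed positions, `energy` total (k_BT),
#'   `feasible`, `iterations`, `blocked` logical per strand.
#' @export
relax_crosslinks <- function(network, particle, position, opts = list()) {
  stopifnot(inherits(network, "bead_network"))
  if (is.numeric(particle)) particle <- particle_spec(particle)
  R <- particle$R
  maxit <- opts$maxit %||% 5000L
  tol <- opts$tol %||% 1e-10
  kappa <- 3 / (2 * network$a_x^2)
  X <- opts$X0 %||% network$crosslinks
  if (is.null(opts$X0)) {
    ## deterministic symmetry breaking: a fixed quasi-random displacement
    M <- nrow(X)
    eps <- opts$perturb %||% 1e-3
    X <- X + eps * matrix(sin(seq_len(3 * M) * 12.9898 + 78.233), M, 3)
  }
  free <- !network$pinned
  X[!free, ] <- network$crosslinks[!free, ]   # pinned stay exact
  ctr <- as.numeric(position)

  ## infeasible if a pinned cross-link overlaps the particle
  dp <- sqrt(rowSums(sweep(X, 2, ctr)^2))
  if (any(dp[!free] < R * (1 - 1e-12)))
    return(list(crosslinks = X, energy = Inf, feasible = FALSE,
                iterations = 0L, blocked = rep(NA, nrow(network$strands))))

  project <- function(X) {
    A <- sweep(X, 2, ctr)
    dd <- sqrt(rowSums(A^2))
    bad <- free & dd < R
    if (any(bad)) {
      scl <- R * (1 + 1e-9) / pmax(dd[bad], 1e-12)
      X[bad, ] <- sweep(A[bad, , drop = FALSE] * scl, 2, ctr, "+")
    }
    X
  }
  X <- project(X)
  en <- .network_energy(X, network$strands, ctr, R, kappa)
  step <- opts$step0 %||% (0.1 / kappa / max(1, nrow(network$strands) / 10))
  it <- 0L
  repeat {
    it <- it + 1L
    Gf <- en$G; Gf[!free, ] <- 0
    gn <- max(abs(Gf))
    if (gn < 1e-9 || it > maxit) break
    accepted <- FALSE
    for (ls in 1:40) {
      Xn <- project(X - step * Gf)
      en_new <- .network_energy(Xn, network$strands, ctr, R, kappa)
      if (en_new$E <= en$E + 1e-14) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break
    dE <- en$E - en_new$E
    X <- Xn; en <- en_new
    step <- step * 1.3
    if (dE < tol && it > 10) break
  }
  list(crosslinks = X, energy = en$E, feasible = TRUE, iterations = it,
       blocked = en$blocked)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## Landscape environment: a cell plus its first-shell image network, cached
## reference energy at the cell center.
## ---------------------------------------------------------------------------

#' Prepare a free-energy landscape environment for a cell and particle
#'
#' Builds the cross-link network (cell plus first-shell mirror-image cells,
#' outer image cross-links pinned) and caches the relaxed reference free
#' energy with the particle at the cell center.
#'
#' @param cell a `polyhedral_cell`.
#' @param particle a `particle_spec` or diameter.
#' @param config list: `replicate_neighbors` (default TRUE), `relax` options.
#' @return List of class `landscape_env`.
#' @export
landscape_env <- function(cell, particle, config = list()) {
  if (is.numeric(particle)) particle <- particle_spec(particle)
  repl <- config$replicate_neighbors %||% TRUE
  net <- to_bead_network(cell, N = 1L, b = cell$a_x, replicate_neighbors = repl)
  ref <- relax_crosslinks(net, particle, c(0, 0, 0), config$relax %||% list())
  structure(list(cell = cell, particle = particle, network = net,
                 F0 = ref$energy, ref = ref, config = config),
            class = "landscape_env")
}

#' Free-energy change of the particle at a point
#'
#' \eqn{\Delta F(r) = F(r) - F(0)} with \eqn{F} the relaxed (saddle-point)
#' network free energy around the particle at `position`, in units of
#' \eqn{k_B T}.  Exactly zero at the cell center by construction.
#'
#' @param env a `landscape_env` (or a `polyhedral_cell`, with `particle`).
#' @param position 3-vector, units of `a_x`.
#' @param particle,config used when `env` is a cell.
#' @return Scalar \eqn{\Delta F} in k_BT (`Inf` if infeasible).
#' @export
free_energy_point <- function(env, position, particle = NULL, config = list()) {
  if (inherits(env, "polyhedral_cell"))
    env <- landscape_env(env, particle, config)
  rx <- relax_crosslinks(env$network, env$particle, position,
                         env$config$relax %||% list())
  rx$energy - env$F0
}

#' Free-energy profile along the minimum-energy path
#'
#' Evaluates \eqn{\Delta F(z)} at `n_z` points from the cell center
#' (`z = 0`) to the face center (`z = z_face`) along the MEP axis, and the
#' barrier \eqn{U_b = \max_z \Delta F(z)}.
#'
#' @param cell a `polyhedral_cell`.
#' @param particle a `particle_spec` or diameter.
#' @param n_z number of points (>= 8).
#' @param config landscape options (see [landscape_env()]); `face_index`
#'   selects the face (default 1).
#' @return Object of class `mep_profile`: data frame fields `z`, `dF`, plus
#'   `U_b`, `d`, `g_label`, `regime`, `truncated`.
#' @export
mep_profile <- function(cell, particle, n_z = 32L, config = list()) {
  if (is.numeric(particle)) particle <- particle_spec(particle)
  if (n_z < 8) stop("n_z must be >= 8")
  env <- landscape_env(cell, particle, config)
  frame <- mep_frame(cell, config$face_index %||% 1L)
  z <- seq(0, frame$z_face, length.out = n_z)
  ropts <- env$config$relax %||% list()
  ## three passes against descent hysteresis: cold starts, then forward and
  ## backward warm-start continuation; keep the lowest energy per point
  relax_at <- function(zz, opts) relax_crosslinks(env$network, env$particle,
                                                  frame$axis * zz, opts)
  cold <- lapply(z, relax_at, opts = ropts)
  En <- vapply(cold, `[[`, numeric(1), "energy")
  Xs <- lapply(cold, `[[`, "crosslinks")
  for (dir in list(seq_len(n_z)[-1], rev(seq_len(n_z))[-1])) {
    prev <- if (dir[1] == 2L) 1L else n_z
    for (i in dir) {
      w <- relax_at(z[i], modifyList(ropts, list(X0 = Xs[[prev]])))
      if (is.finite(w$energy) && w$energy < En[i]) {
        En[i] <- w$energy; Xs[[i]] <- w$crosslinks
      }
      prev <- i
    }
  }
  dF <- En - En[1]
  dF[1] <- 0
  truncated <- any(!is.finite(dF))
  if (truncated) {
    keep <- seq_len(which(!is.finite(dF))[1] - 1L)
    z <- z[keep]; dF <- dF[keep]
  }
  radii <- radii_geometric(cell)
  structure(list(z = z, dF = dF, U_b = max(dF), d = particle$d,
                 g_label = cell$g_label, z_face = frame$z_face,
                 regime = classify_regime(particle, radii),
                 truncated = truncated),
            class = "mep_profile")
}

#' @export
print.mep_profile <- function(x, ...) {
  cat(sprintf("MEP profile g = %d, d/a_x = %.3g (Regime %s): U_b = %.3g k_BT, %d points%s\n",
              x$g_label, x$d, x$regime, x$U_b, length(x$z),
              if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

#' Free-energy field on a regular grid
#'
#' \eqn{\Delta F} evaluated on a regular 3-D lattice covering the cell
#' interior.
#'
#' @param cell a `polyhedral_cell`.
#' @param particle a `particle_spec` or diameter.
#' @param grid_spec list with `n` points per axis (default 9) and `half_width`
#'   (default the circumradius).
#' @param config landscape options.
#' @return List of class `free_energy_field`: `x`, `y`, `z` axes, `values`
#'   3-D array (k_BT), `d`, `g_label`.
#' @export
free_energy_field <- function(cell, particle, grid_spec = list(),
                              config = list()) {
  if (is.numeric(particle)) particle <- particle_spec(particle)
  n <- grid_spec$n %||% 9L
  hw <- grid_spec$half_width %||% radii_geometric(cell)$r_out
  ax <- seq(-hw, hw, length.out = n)
  env <- landscape_env(cell, particle, config)
  vals <- array(NA_real_, dim = c(n, n, n))
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    vals[i, j, k] <- free_energy_point(env, c(ax[i], ax[j], ax[k]))
  }
  structure(list(x = ax, y = ax, z = ax, values = vals, d = particle$d,
                 g_label = cell$g_label), class = "free_energy_field")
}

## ---------------------------------------------------------------------------
## Brownian-bridge confinement entropy (strand-level fluctuations)
## ---------------------------------------------------------------------------

#' Survival probability of a Gaussian bridge against a hard sphere
#'
#' Monte-Carlo estimate of the probability that a discrete Gaussian bridge of
#' `N` steps (step variance `b^2/3` per coordinate) from `r_i` to `r_j` keeps
#' all its interior nodes outside a hard sphere.  Deterministic given `seed`.
#'
#' @param r_i,r_j strand endpoints (3-vectors), outside the sphere.
#' @param sphere_center 3-vector.
#' @param R sphere radius.
#' @param N number of bridge steps.
#' @param b Kuhn length.
#' @param n_samples Monte-Carlo sample count.
#' @param seed integer seed.
#' @return Probability in [0, 1]; attribute `endpoint_inside` flags a forced 0.
#' @export
bridge_survival <- function(r_i, r_j, sphere_center, R, N, b,
                            n_samples = 10000L, seed = 1L) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  di <- sqrt(sum((r_i - sphere_center)^2))
  dj <- sqrt(sum((r_j - sphere_center)^2))
  if (di < R || dj < R) {
    out <- 0
    attr(out, "endpoint_inside") <- TRUE
    return(out)
  }
  if (N <= 1) return(1)  # no interior nodes
  set.seed(seed)
  p <- bridge_survival_cpp(as.numeric(r_i), as.numeric(r_j),
                           as.numeric(sphere_center), R, as.integer(N),
                           b, as.integer(n_samples))
  attr(p, "endpoint_inside") <- FALSE
  p
}

#' Free energy of a single strand near a hard sphere
#'
#' Gaussian stretching term plus the excluded-volume confinement penalty:
#' \deqn{F = \tfrac{3}{2}\,|r_i - r_j|^2 / (N b^2) - \ln P_{surv}}
#' in units of k_BT.
#'
#' @inheritParams bridge_survival
#' @param sampler_config list with `n_samples` and `seed`.
#' @return Free energy (k_BT); `Inf` when the bridge cannot avoid the sphere.
#' @export
strand_free_energy <- function(r_i, r_j, sphere_center, R, N, b,
                               sampler_config = list()) {
  stretch <- 1.5 * sum((r_i - r_j)^2) / (N * b^2)
  if (R <= 0) return(stretch)
  p <- bridge_survival(r_i, r_j, sphere_center, R, N, b,
                       n_samples = sampler_config$n_samples %||% 10000L,
                       seed = sampler_config$seed %||% 1L)
  if (p <= 0) return(Inf)
  stretch - log(p)
}
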