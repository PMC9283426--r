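#' Numerical inverse Laplace transform (fixed Talbot)
#'
#' Fixed-Talbot contour quadrature with `M` nodes.  Suitable for the smooth,
#' non-oscillatory images that arise in the regime-resolved MSD theory.
#'
#' @param Fs function of a complex Laplace variable `s`, vectorized or not.
#' @param t positive times.
#' @param M number of contour nodes (default 32).
#' @return Numeric vector `f(t)`.
#' @export
invlap_talbot <- function(Fs, t, M = 32L) {
  vapply(t, function(tt) {
    if (tt <= 0) stop("t must be positive")
    r <- 2 * M / (5 * tt)
    k <- seq_len(M - 1)
    theta <- k * pi / M
    cot <- 1 / tan(theta)
    s <- r * theta * (cot + 1i)
    sigma <- theta + (theta * cot - 1) * cot
    terms <- Re(exp(tt * s) * vapply(s, Fs, complex(1)) * (1 + 1i * sigma))
    (r / M) * (0.5 * Re(Fs(complex(real = r, imaginary = 0))) * exp(r * tt) +
                 sum(terms))
  }, numeric(1))
}

## One-time self-test of the transform engine against a closed-form pair.
.talbot_gate <- local({
  passed <- FALSE
  function() {
    if (passed) return(invisible(TRUE))
    tt <- c(0.1, 1, 5, 20)
    got <- invlap_talbot(function(s) 1 / s - 1 / (s + 1), tt)
    if (max(abs(got - (1 - exp(-tt))) / (1 - exp(-tt))) > 1e-6)
      stop("inverse-Laplace self-test failed")
    passed <<- TRUE
    invisible(TRUE)
  }
})

#' Analytic-theory parameter bundle from landscape quantities
#'
#' Maps the free-energy landscape onto the regime-resolved MSD theory:
#' the V-potential slope \eqn{\rho = U_b / r_{in}}, the harmonic frequency
#' \eqn{\omega = \sqrt{2 U_b / m} / r_{in}} (natural units m = k_BT = 1), and
#' the derived quantities
#' \eqn{\omega_1 = \sqrt{\omega^2 - (\gamma/m)^2/8}},
#' \eqn{\beta_1 = \sqrt{(\gamma/m)^2 - 8\omega^2}},
#' \eqn{\Delta_0 = \sqrt{1 + 4 D_0/(\rho^2 t_w)}}.
#' Exactly one of \eqn{\omega_1}, \eqn{\beta_1} is real.
#'
#' @param U_b barrier (k_BT).
#' @param r_in inradius (a_x).
#' @param t_w waiting time (tau), measured from simulation.
#' @param config list: `gamma` (default 10), `m` (1), `kBT` (1), `D0`
#'   (default `kBT / gamma`, the bare 1-D diffusivity of the Langevin model),
#'   `tau0` (Regime-III relaxation time; default `r_in^2 / (12 D0)` so the
#'   short-time expansion matches free diffusion `2 D0 t`).
#' @return List of class `regime_params`.
#' @export
params_from_landscape <- function(U_b, r_in, t_w = NA_real_,
                                  config = list()) {
  if (U_b < 0 || r_in <= 0) stop("need U_b >= 0 and r_in > 0")
  m <- config$m %||% 1
  kBT <- config$kBT %||% 1
  gamma <- config$gamma %||% 10
  D0 <- config$D0 %||% (kBT / gamma)
  rho <- U_b / r_in
  omega <- sqrt(2 * U_b * kBT / m) / r_in
  gm <- gamma / m
  omega1 <- if (omega^2 >= gm^2 / 8) sqrt(omega^2 - gm^2 / 8) else NA_real_
  beta1 <- if (gm^2 >= 8 * omega^2) sqrt(gm^2 - 8 * omega^2) else NA_real_
  Delta0 <- if (rho > 0 && is.finite(t_w))
    sqrt(1 + 4 * D0 / (rho^2 * t_w)) else NA_real_
  tau0 <- config$tau0 %||% (r_in^2 / (12 * D0))
  structure(list(rho = rho, omega = omega, omega1 = omega1, beta1 = beta1,
                 t_w = t_w, D0 = D0, Delta0 = Delta0, tau0 = tau0,
                 r_in = r_in, m = m, gamma = gamma, kBT = kBT),
            class = "regime_params")
}

#' Short-time MSD in Regime I (V-shaped potential)
#'
#' Numerical inverse Laplace transform of
#' \deqn{\langle\Delta z^2(s)\rangle = \frac{8 D_0^2}{\rho^2}
#'   \frac{1}{s\,(1 + \sqrt{1 + 4 D_0 (1/t_w + s)/\rho^2})^2}}
#' which saturates at long times to
#' \eqn{2 D_0 t_w - \rho^2 t_w^2 (\Delta_0 - 1)}.
#'
#' @param t times (tau).
#' @param params a `regime_params` with `rho > 0` and finite `t_w`.
#' @return MSD values (a_x^2).
#' @export
msd_regime1 <- function(t, params) {
  stopifnot(inherits(params, "regime_params"))
  if (!(params$rho > 0)) stop("Regime I requires rho > 0")
  if (!is.finite(params$t_w)) stop("Regime I requires a finite t_w")
  .talbot_gate()
  D0 <- params$D0; rho <- params$rho; tw <- params$t_w
  Fs <- function(s) {
    8 * D0^2 / rho^2 / (s * (1 + sqrt(1 + 4 * D0 * (1 / tw + s) / rho^2))^2)
  }
  invlap_talbot(Fs, t)
}

#' Long-time MSD plateau of Regime I
#'
#' @param params a `regime_params`.
#' @return \eqn{2 D_0 t_w - \rho^2 t_w^2 (\Delta_0 - 1)} (a_x^2).
#' @export
msd_regime1_plateau <- function(params) {
  with(params, 2 * D0 * t_w - rho^2 * t_w^2 * (Delta0 - 1))
}

#' Short-time MSD in Regime II (harmonic potential)
#'
#' Brownian motion of a harmonic oscillator with frequency omega.  For
#' \eqn{\gamma > \sqrt{8} m \omega} (overdamped branch)
#' \deqn{\langle\Delta z^2\rangle = \frac{k_BT}{m\omega^2}\Big[1 -
#'  e^{-\gamma t/2m}\big(2\sinh^2(\beta_1 t/4) +
#'  \tfrac{\gamma}{m\beta_1}\sinh(\beta_1 t/2) + 1\big)\Big]}
#' and for \eqn{\gamma < \sqrt{8} m \omega} (underdamped branch)
#' \deqn{\langle\Delta z^2\rangle = \frac{k_BT}{m\omega^2}\Big[1 -
#'  e^{-\gamma t/2m}\big(-2\sin^2(\tfrac{\sqrt2}{2}\omega_1 t) +
#'  \tfrac{\gamma\sin(\sqrt2 \omega_1 t)}{\sqrt8 m\omega_1} + 1\big)\Big].}
#' The branches join continuously at \eqn{\gamma = \sqrt{8} m \omega}.
#' Evaluated in an overflow-safe exponential form.
#'
#' @param t times (tau).
#' @param params a `regime_params` with `omega > 0`.
#' @return MSD values (a_x^2).
#' @export
msd_regime2 <- function(t, params) {
  stopifnot(inherits(params, "regime_params"))
  om <- params$omega
  if (!(om > 0)) stop("Regime II requires omega > 0")
  m <- params$m; gamma <- params$gamma; kBT <- params$kBT
  gm <- gamma / m
  C <- kBT / (m * om^2)
  if (gm^2 > 8 * om^2 * (1 + 1e-12)) {
    b1 <- sqrt(gm^2 - 8 * om^2)
    ## bracket = e^{-gm t/2} (cosh(b1 t/2) + (gm/b1) sinh(b1 t/2))
    E1 <- exp((b1 - gm) * t / 2); E2 <- exp(-(b1 + gm) * t / 2)
    bracket <- 0.5 * (E1 + E2) + (gm / b1) * 0.5 * (E1 - E2)
  } else if (gm^2 < 8 * om^2 * (1 - 1e-12)) {
    w1 <- sqrt(om^2 - gm^2 / 8)
    y <- sqrt(2) * w1 * t
    bracket <- exp(-gm * t / 2) * (cos(y) + (gm / (sqrt(8) * w1)) * sin(y))
  } else {
    ## critical branch point: common limit of both branches
    bracket <- exp(-gm * t / 2) * (1 + gm * t / 2)
  }
  C * (1 - bracket)
}

#' Short-time MSD in Regime III (reflected random walk)
#'
#' Random walk between reflecting boundaries at \eqn{z = \pm r_{in}}:
#' \deqn{\langle\Delta z^2(t)\rangle = \frac{r_{in}^2}{6}
#'   \big[1 - e^{-t/\tau_0}\big]}
#' with plateau \eqn{r_{in}^2/6}; overdamped relaxation with time
#' \eqn{\tau_0} (default \eqn{r_{in}^2 / 12 D_0}).
#'
#' @param t times (tau).
#' @param params a `regime_params` with `r_in > 0`, `tau0 > 0`.
#' @return MSD values (a_x^2).
#' @export
msd_regime3 <- function(t, params) {
  stopifnot(inherits(params, "regime_params"))
  if (!(params$r_in > 0) || !(params$tau0 > 0))
    stop("Regime III requires r_in > 0 and tau0 > 0")
  params$r_in^2 / 6 * (1 - exp(-t / params$tau0))
}

#' Total MSD from the jump-waiting decomposition
#'
#' Coarse-grained hopping picture \eqn{z(t) = \sum_i \delta z_i} with
#' \eqn{\langle N(t)\rangle = t / t_w}:
#' \deqn{\langle\Delta z^2(t)\rangle =
#'   \begin{cases} (t/t_w)\,\langle\delta z^2(t)\rangle & t \ge t_w \\
#'                 \langle\delta z^2(t)\rangle & t < t_w \end{cases}}
#' which is continuous at `t = t_w` and linear in `t` for
#' `t >> t_w` (normal diffusion recovered).
#'
#' @param t times (tau).
#' @param t_w waiting time (tau).
#' @param short_time_msd function of `t` giving the intra-cell MSD
#'   \eqn{\langle\delta z^2(t)\rangle}.
#' @return MSD values (a_x^2).
#' @export
compose_total_msd <- function(t, t_w, short_time_msd) {
  if (!(t_w > 0)) stop("t_w must be positive")
  base <- short_time_msd(t)
  ifelse(t >= t_w, (t / t_w) * base, base)
}

#' Oscillation mode of the intra-cell dynamics
#'
#' Regime I: underdamped (the characteristic root of the V-potential MSD is
#' complex).  Regime II: underdamped iff \eqn{\gamma < \sqrt{8} m \omega},
#' overdamped otherwise.  Regime III: always overdamped.  Regime IV has no
#' landscape and hence no oscillation ("none").
#'
#' @param regime `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param params a `regime_params`.
#' @return `"underdamped"`, `"overdamped"` or `"none"`.
#' @export
oscillation_mode <- function(regime, params) {
  switch(regime,
         I = "underdamped",
         II = if (params$gamma < sqrt(8) * params$m * params$omega)
           "underdamped" else "overdamped",
         III = "overdamped",
         IV = "none",
         stop("unknown regime ", regime))
}
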