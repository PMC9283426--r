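#' Fit a log-log scaling exponent
#'
#' Least-squares slope of `log(y)` against `log(x)` inside a window,
#' \eqn{y \sim x^\eta}.
#'
#' @param x,y positive series.
#' @param window `c(x_min, x_max)` fit range (inclusive); default all points.
#' @return List of class `exponent_fit`: `eta`, `stderr`, `window`,
#'   `n_points`.
#' @export
fit_exponent <- function(x, y, window = range(x)) {
  keep <- x >= window[1] & x <= window[2] & y > 0 & x > 0
  if (sum(keep) < 5) stop("need at least 5 positive points in the window")
  fit <- lm(log(y[keep]) ~ log(x[keep]))
  ## exact power laws trigger a harmless perfect-fit warning in summary()
  sm <- suppressWarnings(summary(fit))
  structure(list(eta = unname(coef(fit)[2]),
                 stderr = sm$coefficients[2, 2],
                 window = window, n_points = sum(keep)),
            class = "exponent_fit")
}

#' @export
print.exponent_fit <- function(x, ...) {
  cat(sprintf("eta = %.4f +/- %.2g (%d points in [%g, %g])\n",
              x$eta, x$stderr, x$n_points, x$window[1], x$window[2]))
  invisible(x)
}

#' Barrier scan over cells and particle diameters
#'
#' Computes the hopping barrier \eqn{U_b(d; g)} along the MEP for every
#' combination, with the regime-boundary diameters `2 r_out` and `2 r_mid`
#' marked per cell.
#'
#' @param g_labels catalog labels.
#' @param d_grid particle diameters (units a_x).
#' @param config landscape options (see [mep_profile()]); `n_z` points per
#'   profile (default 16).
#' @return Data frame with `g`, `d`, `U_b`, `regime`, `feasible`, plus
#'   attribute `boundaries` (data frame `g`, `d_2rout`, `d_2rmid`,
#'   `Ub_2rout`, `Ub_2rmid`).
#' @export
barrier_scan <- function(g_labels, d_grid, config = list()) {
  n_z <- config$n_z %||% 16L
  rows <- list()
  bnds <- list()
  for (g in g_labels) {
    cell <- build_cell(g)
    radii <- radii_geometric(cell)
    for (d in d_grid) {
      prof <- mep_profile(cell, d, n_z = n_z, config = config)
      rows[[length(rows) + 1L]] <- data.frame(
        g = g, d = d, U_b = prof$U_b,
        regime = prof$regime, feasible = !prof$truncated)
    }
    bprof <- lapply(c(2 * radii$r_out, 2 * radii$r_mid), function(db)
      mep_profile(cell, db, n_z = n_z, config = config)$U_b)
    bnds[[length(bnds) + 1L]] <- data.frame(
      g = g, d_2rout = 2 * radii$r_out, d_2rmid = 2 * radii$r_mid,
      Ub_2rout = bprof[[1]], Ub_2rmid = bprof[[2]])
  }
  out <- do.call(rbind, rows)
  attr(out, "boundaries") <- do.call(rbind, bnds)
  out
}

#' Master-curve collapse of diffusion coefficients
#'
#' Normalizes each cell's diffusivities by the value at `d = 2 r_norm`
#' (`r_in` or `r_out`; log-log interpolated when not sampled exactly) and
#' pools `D / D(2 r_norm)` versus `d / (2 r_norm)`.  For `norm = "r_in"` the
#' fitted log-log slope on the small-particle branch (`d <= 2 r_in`) is
#' reported; for `norm = "r_out"` the quality (R^2) of the exponential law
#' `ln D ~ d^2` on the large-particle branch.
#'
#' @param records data frame with columns `g`, `d`, `D`.
#' @param norm `"r_in"` or `"r_out"`.
#' @return List of class `master_curve`: `collapsed` (data frame `g`,
#'   `d_norm`, `D_norm`), `slope` + `slope_stderr` (r_in branch) or
#'   `exp_r2` (r_out branch).
#' @export
master_curve <- function(records, norm = c("r_in", "r_out")) {
  norm <- match.arg(norm)
  stopifnot(all(c("g", "d", "D") %in% names(records)))
  collapsed <- NULL
  for (g in unique(records$g)) {
    radii <- radii_geometric(build_cell(g))
    r0 <- 2 * if (norm == "r_in") radii$r_in else radii$r_out
    sub <- records[records$g == g, ]
    sub <- sub[order(sub$d), ]
    hit <- which(abs(sub$d - r0) < 1e-9)
    D0 <- if (length(hit)) sub$D[hit[1]] else {
      if (r0 < min(sub$d) || r0 > max(sub$d))
        warning("normalization diameter outside sampled range for g = ", g,
                "; extrapolating")
      .loglog_interp(sub$d, sub$D, r0)
    }
    collapsed <- rbind(collapsed, data.frame(
      g = g, d_norm = sub$d / r0, D_norm = sub$D / D0))
  }
  out <- list(collapsed = collapsed, norm = norm)
  if (norm == "r_in") {
    br <- collapsed[collapsed$d_norm <= 1 + 1e-9, ]
    fit <- lm(log(br$D_norm) ~ log(br$d_norm))
    out$slope <- unname(coef(fit)[2])
    out$slope_stderr <- suppressWarnings(summary(fit))$coefficients[2, 2]
  } else {
    br <- collapsed[collapsed$d_norm >= 1 - 1e-9, ]
    fit <- lm(log(br$D_norm) ~ I(br$d_norm^2))
    out$exp_r2 <- suppressWarnings(summary(fit))$r.squared
  }
  structure(out, class = "master_curve")
}

## log-log linear interpolation with edge-pair extrapolation (exact on power
## laws); x must be sorted increasing.
.loglog_interp <- function(x, y, x0) {
  lx <- log(x); ly <- log(y); l0 <- log(x0)
  if (l0 <= lx[1]) i <- 1L
  else if (l0 >= lx[length(lx)]) i <- length(lx) - 1L
  else i <- findInterval(l0, lx)
  sl <- (ly[i + 1] - ly[i]) / (lx[i + 1] - lx[i])
  exp(ly[i] + sl * (l0 - lx[i]))
}

#' Regime diagram across the cell catalog
#'
#' Boundary diameters between the four confinement regimes per cell:
#' I/II at `d = 2 r_out`, II/III at `d = 2 r_mid`, III/IV at `d = 2 r_in`.
#'
#' @param g_labels catalog labels.
#' @return Data frame of class `regime_diagram` with `g`, `boundary_III_IV`,
#'   `boundary_II_III`, `boundary_I_II`, and relative widths
#'   `width_II_rel`, `width_III_rel` (in units of `2 r_in`).
#' @export
regime_diagram <- function(g_labels = cell_labels()) {
  rows <- lapply(g_labels, function(g) {
    r <- radii_geometric(build_cell(g))
    data.frame(g = g,
               boundary_III_IV = 2 * r$r_in,
               boundary_II_III = 2 * r$r_mid,
               boundary_I_II = 2 * r$r_out,
               width_II_rel = (r$r_out - r$r_mid) / r$r_in,
               width_III_rel = (r$r_mid - r$r_in) / r$r_in)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("regime_diagram", "data.frame")
  out
}

#' Free-energy heat map over diameter and path position
#'
#' Assembles a (d, z) table of \eqn{\Delta F} from a collection of MEP
#' profiles of one cell, with the regime-boundary diameters attached.
#'
#' @param profiles list of `mep_profile` objects sharing a cell.
#' @return List of class `eta_heatmap`: `d` (sorted diameters), `z`,
#'   `dF` matrix (rows = d, cols = z), `boundaries` (2 r_mid, 2 r_out).
#' @export
eta_heatmap <- function(profiles) {
  g <- unique(vapply(profiles, `[[`, integer(1), "g_label"))
  if (length(g) != 1) stop("profiles must share one cell")
  ds <- vapply(profiles, `[[`, numeric(1), "d")
  ord <- order(ds)
  profiles <- profiles[ord]; ds <- ds[ord]
  z <- profiles[[1]]$z
  dF <- t(vapply(profiles, function(p) {
    if (length(p$z) == length(z)) p$dF
    else approx(p$z, p$dF, xout = z, rule = 2)$y
  }, numeric(length(z))))
  radii <- radii_geometric(build_cell(g))
  structure(list(d = ds, z = z, dF = dF, g_label = g,
                 boundaries = c(II_III = 2 * radii$r_mid,
                                I_II = 2 * radii$r_out)),
            class = "eta_heatmap")
}
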