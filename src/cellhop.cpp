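#include <Rcpp.h>
using namespace Rcpp;

// Survival probability of a discrete Gaussian bridge of N steps from a to b
// against a hard sphere: fraction of sampled bridges whose N-1 interior nodes
// all stay outside the sphere. Sequential conditional (bridge) sampling:
// given the node at step k, the next node is Gaussian with mean moving a
// fraction 1/(N-k) toward the end point and per-coordinate variance
// (b^2/3) * (N-k-1)/(N-k). Uses R's RNG (seed via set.seed in the caller).
// [[Rcpp::export]]
double bridge_survival_cpp(NumericVector a, NumericVector b,
                           NumericVector ctr, double R, int N,
                           double bkuhn, int n_samples) {
  const double var1 = bkuhn * bkuhn / 3.0;
  const double R2 = R * R;
  int surv = 0;
  for (int s = 0; s < n_samples; ++s) {
    double x = a[0], y = a[1], z = a[2];
    bool ok = true;
    for (int k = 0; k < N - 1; ++k) {
      int m = N - k;                  // steps remaining from current node
      double frac = 1.0 / m;
      double sd = std::sqrt(var1 * (double)(m - 1) / (double)m);
      x += (b[0] - x) * frac + sd * norm_rand();
      y += (b[1] - y) * frac + sd * norm_rand();
      z += (b[2] - z) * frac + sd * norm_rand();
      double dx = x - ctr[0], dy = y - ctr[1], dz = z - ctr[2];
      if (dx * dx + dy * dy + dz * dz < R2) { ok = false; break; }
    }
    if (ok) ++surv;
  }
  return (double)surv / (double)n_samples;
}

static inline double spring_de(const std::vector<double>& X,
                               const std::vector<double>& Y,
                               const std::vector<double>& Z,
                               const IntegerVector& nb, int from, int to,
                               int site, double nx, double ny, double nz,
                               double kspring) {
  // energy change of springs incident to `site` when it moves to (nx,ny,nz)
  double de = 0.0;
  for (int q = from; q < to; ++q) {
    int o = nb[q];
    double dx0 = X[site] - X[o], dy0 = Y[site] - Y[o], dz0 = Z[site] - Z[o];
    double dx1 = nx - X[o], dy1 = ny - Y[o], dz1 = nz - Z[o];
    de += kspring * (dx1 * dx1 + dy1 * dy1 + dz1 * dz1
                     - dx0 * dx0 - dy0 * dy0 - dz0 * dz0);
  }
  return de;
}

// Wang-Landau flat-histogram sampling of F(z) for a bead-spring network with
// a hard-sphere particle confined to the MEP axis.
//  sites: initial site coordinates (beads + cross-links), some fixed.
//  springs: 0-based site index pairs; spring energy (3/2)|dr|^2/b^2 (k_BT).
//  The particle moves in 1-D along `axis` with z in [0, zmax]; any mobile or
//  fixed site within R of the particle is an overlap (move rejected).
//  Bias f(z) per bin; acceptance exp(-dE - df); every attempt deposits
//  f_current in the current bin and increments the histogram. When
//  min(hist) >= flatness * mean(hist), f_current *= reduction and the
//  histogram resets; terminate at f_current < f_min.
// [[Rcpp::export]]
List wang_landau_cpp(NumericMatrix sites, LogicalVector fixed,
                     IntegerMatrix springs, double kspring,
                     NumericVector axis, double R, double zmax, int nbins,
                     double f0, double flatness, double reduction,
                     double f_min, double max_sweeps, double move_site,
                     double move_particle, double z_init,
                     int check_every, bool freeze_bias) {
  int S = sites.nrow();
  std::vector<double> X(S), Y(S), Z(S);
  for (int i = 0; i < S; ++i) { X[i] = sites(i, 0); Y[i] = sites(i, 1); Z[i] = sites(i, 2); }
  int E = springs.nrow();

  // adjacency in CSR form
  std::vector<int> deg(S, 0);
  for (int e = 0; e < E; ++e) { deg[springs(e, 0)]++; deg[springs(e, 1)]++; }
  IntegerVector off(S + 1);
  for (int i = 0; i < S; ++i) off[i + 1] = off[i] + deg[i];
  IntegerVector nb(2 * E);
  std::vector<int> cur(S, 0);
  for (int e = 0; e < E; ++e) {
    int i = springs(e, 0), j = springs(e, 1);
    nb[off[i] + cur[i]++] = j;
    nb[off[j] + cur[j]++] = i;
  }

  std::vector<int> mobile;
  for (int i = 0; i < S; ++i) if (!fixed[i]) mobile.push_back(i);
  int M = mobile.size();

  const double R2 = R * R;
  double zp = z_init;                      // particle position along axis
  double px = axis[0] * zp, py = axis[1] * zp, pz = axis[2] * zp;
  const double binw = zmax / nbins;
  std::vector<double> bias(nbins, 0.0);
  std::vector<double> hist(nbins, 0.0);
  double f = f0;
  int stage = 0;
  std::vector<double> log_f, log_sweeps;
  double sweeps = 0.0;
  bool converged = false;

  auto binof = [&](double z) {
    int b = (int)(z / binw);
    if (b < 0) b = 0; if (b >= nbins) b = nbins - 1;
    return b;
  };
  auto overlap = [&](double qx, double qy, double qz) {
    for (int i = 0; i < S; ++i) {
      double dx = X[i] - qx, dy = Y[i] - qy, dz = Z[i] - qz;
      if (dx * dx + dy * dy + dz * dz < R2) return true;
    }
    return false;
  };

  while (sweeps < max_sweeps) {
    // one sweep: M site moves + 4 particle moves
    for (int mv = 0; mv < M; ++mv) {
      int i = mobile[(int)(unif_rand() * M) % M];
      double nx = X[i] + move_site * (unif_rand() - 0.5);
      double ny = Y[i] + move_site * (unif_rand() - 0.5);
      double nz = Z[i] + move_site * (unif_rand() - 0.5);
      bool ok = true;
      if (R > 0) {
        double dx = nx - px, dy = ny - py, dz = nz - pz;
        if (dx * dx + dy * dy + dz * dz < R2) ok = false;
      }
      if (ok) {
        double de = spring_de(X, Y, Z, nb, off[i], off[i + 1], i,
                              nx, ny, nz, kspring);
        if (de <= 0.0 || unif_rand() < std::exp(-de)) {
          X[i] = nx; Y[i] = ny; Z[i] = nz;
        }
      }
    }
    for (int pm = 0; pm < 4; ++pm) {
      double znew = zp + move_particle * (unif_rand() - 0.5);
      int b0 = binof(zp);
      if (znew >= 0.0 && znew <= zmax) {
        double qx = axis[0] * znew, qy = axis[1] * znew, qz = axis[2] * znew;
        if (!(R > 0 && overlap(qx, qy, qz))) {
          int b1 = binof(znew);
          double darg = bias[b1] - bias[b0];
          if (darg <= 0.0 || unif_rand() < std::exp(-darg)) {
            zp = znew; px = qx; py = qy; pz = qz;
          }
        }
      }
      int bcur = binof(zp);
      if (!freeze_bias) bias[bcur] += f;
      hist[bcur] += 1.0;
    }
    sweeps += 1.0;

    if (!freeze_bias && ((long)sweeps) % check_every == 0) {
      double mn = hist[0], mean = 0.0;
      for (int b = 0; b < nbins; ++b) { mn = std::min(mn, hist[b]); mean += hist[b]; }
      mean /= nbins;
      if (mean > 0 && mn >= flatness * mean) {
        log_f.push_back(f); log_sweeps.push_back(sweeps);
        f *= reduction;
        ++stage;
        std::fill(hist.begin(), hist.end(), 0.0);
        if (f < f_min) { converged = true; break; }
      }
    }
  }

  NumericMatrix out_sites(S, 3);
  for (int i = 0; i < S; ++i) { out_sites(i, 0) = X[i]; out_sites(i, 1) = Y[i]; out_sites(i, 2) = Z[i]; }
  return List::create(_["bias"] = NumericVector(bias.begin(), bias.end()),
                      _["histogram"] = NumericVector(hist.begin(), hist.end()),
                      _["f_final"] = f, _["stage"] = stage,
                      _["sweeps"] = sweeps, _["converged"] = converged,
                      _["sites"] = out_sites, _["z"] = zp,
                      _["log_f"] = NumericVector(log_f.begin(), log_f.end()),
                      _["log_sweeps"] = NumericVector(log_sweeps.begin(), log_sweeps.end()));
}

// Plain Metropolis sampling of the network with the particle frozen at z.
// Returns mean total spring energy, mean energy per spring, acceptance rate
// and the fraction of attempted site moves rejected by particle overlap.
// [[Rcpp::export]]
List metropolis_cpp(NumericMatrix sites, LogicalVector fixed,
                    IntegerMatrix springs, double kspring,
                    NumericVector ppos, double R,
                    double n_sweeps, double burn_in, double move_site) {
  int S = sites.nrow();
  std::vector<double> X(S), Y(S), Z(S);
  for (int i = 0; i < S; ++i) { X[i] = sites(i, 0); Y[i] = sites(i, 1); Z[i] = sites(i, 2); }
  int E = springs.nrow();
  std::vector<int> deg(S, 0);
  for (int e = 0; e < E; ++e) { deg[springs(e, 0)]++; deg[springs(e, 1)]++; }
  IntegerVector off(S + 1);
  for (int i = 0; i < S; ++i) off[i + 1] = off[i] + deg[i];
  IntegerVector nb(2 * E);
  std::vector<int> cur(S, 0);
  for (int e = 0; e < E; ++e) {
    int i = springs(e, 0), j = springs(e, 1);
    nb[off[i] + cur[i]++] = j;
    nb[off[j] + cur[j]++] = i;
  }
  std::vector<int> mobile;
  for (int i = 0; i < S; ++i) if (!fixed[i]) mobile.push_back(i);
  int M = mobile.size();
  const double R2 = R * R;

  auto total_energy = [&]() {
    double en = 0.0;
    for (int e = 0; e < E; ++e) {
      int i = springs(e, 0), j = springs(e, 1);
      double dx = X[i] - X[j], dy = Y[i] - Y[j], dz = Z[i] - Z[j];
      en += kspring * (dx * dx + dy * dy + dz * dz);
    }
    return en;
  };

  double acc = 0.0, att = 0.0, ovl = 0.0;
  double esum = 0.0; long nsamp = 0;
  for (long sw = 0; sw < (long)n_sweeps; ++sw) {
    for (int mv = 0; mv < M; ++mv) {
      int i = mobile[(int)(unif_rand() * M) % M];
      double nx = X[i] + move_site * (unif_rand() - 0.5);
      double ny = Y[i] + move_site * (unif_rand() - 0.5);
      double nz = Z[i] + move_site * (unif_rand() - 0.5);
      att += 1.0;
      if (R > 0) {
        double dx = nx - ppos[0], dy = ny - ppos[1], dz = nz - ppos[2];
        if (dx * dx + dy * dy + dz * dz < R2) { ovl += 1.0; continue; }
      }
      double de = spring_de(X, Y, Z, nb, off[i], off[i + 1], i,
                            nx, ny, nz, kspring);
      if (de <= 0.0 || unif_rand() < std::exp(-de)) {
        X[i] = nx; Y[i] = ny; Z[i] = nz; acc += 1.0;
      }
    }
    if (sw >= (long)burn_in) { esum += total_energy(); ++nsamp; }
  }
  return List::create(_["mean_energy"] = esum / std::max(1L, nsamp),
                      _["mean_energy_per_spring"] = esum / std::max(1L, nsamp) / E,
                      _["acceptance"] = acc / att,
                      _["overlap_fraction"] = ovl / att);
}

// Euler-Maruyama integration of the underdamped NLE
//   m z'' = -dF'(z) - gamma z' + xi(t),  <xi xi'> = 2 gamma kBT delta
// on a periodized potential given by its tabulated derivative on a uniform
// grid over one period (linear interpolation, periodic wrap). Returns a
// thinned trajectory, a velocity autocorrelation estimate on a uniform lag
// grid (origins every `vacf_stride` steps) and the final state.
// [[Rcpp::export]]
List nle_run_cpp(double z0, double v0, double dt, double nsteps,
                 double gamma, double m, double kBT,
                 NumericVector dFgrid, double period,
                 int out_stride, int vacf_lags, int vacf_stride,
                 double burn_in_steps) {
  long NS = (long)nsteps;
  int ng = dFgrid.size();
  const double noise = std::sqrt(2.0 * gamma * kBT * dt) / m;
  const double gm = gamma / m;
  const bool flat = (ng == 0);
  double z = z0, v = v0;

  long nout = NS / out_stride + 1;
  NumericVector zs(nout), vs(nout);
  long oi = 0;

  std::vector<double> vacf(vacf_lags + 1, 0.0);
  std::vector<double> vacf_n(vacf_lags + 1, 0.0);
  std::vector<double> vbuf(vacf_lags + 1, 0.0);
  long bufcount = 0;

  auto force = [&](double zz) {
    if (flat) return 0.0;
    double u = zz / period;
    u -= std::floor(u);
    double x = u * ng;
    int i0 = (int)x; if (i0 >= ng) i0 = ng - 1;
    int i1 = (i0 + 1) % ng;
    double w = x - i0;
    double dF = dFgrid[i0] * (1.0 - w) + dFgrid[i1] * w;
    return -dF;
  };

  for (long s = 0; s < NS; ++s) {
    double F = force(z);
    v += dt * (F / m - gm * v) + noise * norm_rand();
    z += v * dt;
    if (!std::isfinite(z) || !std::isfinite(v) ||
        std::fabs(v) > 1e6 || std::fabs(z) > 1e9)
      stop("NLE integration unstable; reduce dt");
    if (s % out_stride == 0) { zs[oi] = z; vs[oi] = v; ++oi; }
    if (s >= (long)burn_in_steps) {
      // ring buffer of recent velocities for VACF at origins every vacf_stride
      long idx = bufcount % (vacf_lags + 1);
      vbuf[idx] = v;
      ++bufcount;
      if (bufcount > vacf_lags && (s % vacf_stride) == 0) {
        // origin = velocity vacf_lags steps ago
        double vorg = vbuf[(bufcount - 1 - vacf_lags) % (vacf_lags + 1)];
        for (int l = 0; l <= vacf_lags; ++l) {
          double vl = vbuf[(bufcount - 1 - vacf_lags + l) % (vacf_lags + 1)];
          vacf[l] += vorg * vl;
          vacf_n[l] += 1.0;
        }
      }
    }
  }
  NumericVector vacf_out(vacf_lags + 1);
  for (int l = 0; l <= vacf_lags; ++l)
    vacf_out[l] = vacf_n[l] > 0 ? vacf[l] / vacf_n[l] : NA_REAL;
  return List::create(_["z"] = zs[Range(0, oi - 1)],
                      _["v"] = vs[Range(0, oi - 1)],
                      _["vacf"] = vacf_out,
                      _["z_final"] = z, _["v_final"] = v);
}
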