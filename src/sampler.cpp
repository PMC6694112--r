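#include <Rcpp.h>
using namespace Rcpp;

// PSF variants share the integer coding used on the R side:
// 1 = gaussian3d, 2 = gaussian_cylindrical, 3 = gaussian_lorentzian.
static inline double psf_eval(int variant, double wxy, double wz,
                              double x, double y, double z) {
  const double r2 = x * x + y * y;
  switch (variant) {
  case 1:
    return std::exp(-2.0 * r2 / (wxy * wxy) - 2.0 * z * z / (wz * wz));
  case 2:
    return std::exp(-2.0 * r2 / (wxy * wxy));
  case 3: {
    // focused-beam profile: lateral Gaussian with z-dependent waist
    // w(z)^2 = wxy^2 (1 + (z/wz)^2) and on-axis amplitude (wxy/w(z))^2
    const double w2 = wxy * wxy * (1.0 + (z / wz) * (z / wz));
    return (wxy * wxy / w2) * std::exp(-2.0 * r2 / w2);
  }
  default:
    return NA_REAL;
  }
}

// [[Rcpp::export]]
NumericVector cpp_psf_values(NumericMatrix pos, int variant,
                             double wxy, double wz) {
  const int K = pos.nrow();
  NumericVector out(K);
  for (int k = 0; k < K; ++k)
    out[k] = psf_eval(variant, wxy, wz, pos(k, 0), pos(k, 1), pos(k, 2));
  return out;
}

// One single-site random-walk Metropolis sweep over the positions of one
// molecule.  Bin k's Poisson rate is other_rate[k] + scale[k] * PSF(pos_k)
// where other_rate and scale already carry the bin-width factor, so only
// bin k's likelihood term and the two adjacent Gaussian increment priors
// change when site k moves.  The first position has a uniform-box prior.
// Uses R's RNG so chains are reproducible via set.seed().
// [[Rcpp::export]]
List cpp_traj_sweep(NumericMatrix pos_in, NumericVector psf_in,
                    IntegerVector w, NumericVector other_rate,
                    NumericVector scale, double D, NumericVector dtvec,
                    int variant, double wxy, double wz,
                    NumericVector box, double prop_sd) {
  NumericMatrix pos = clone(pos_in);
  NumericVector psfv = clone(psf_in);
  const int K = pos.nrow();
  int n_acc = 0;
  RNGScope rngs;

  for (int k = 0; k < K; ++k) {
    const double x = pos(k, 0), y = pos(k, 1), z = pos(k, 2);
    const double xp = x + prop_sd * norm_rand();
    const double yp = y + prop_sd * norm_rand();
    const double zp = z + prop_sd * norm_rand();

    double dlp = 0.0;  // change in log prior
    if (k == 0) {
      if (std::abs(xp) > box[0] || std::abs(yp) > box[1] ||
          std::abs(zp) > box[2])
        continue;  // outside the uniform initial-position box
    } else {
      const double c = 1.0 / (4.0 * D * dtvec[k]);
      const double dx0 = x - pos(k - 1, 0), dy0 = y - pos(k - 1, 1),
                   dz0 = z - pos(k - 1, 2);
      const double dx1 = xp - pos(k - 1, 0), dy1 = yp - pos(k - 1, 1),
                   dz1 = zp - pos(k - 1, 2);
      dlp -= c * (dx1 * dx1 + dy1 * dy1 + dz1 * dz1 -
                  dx0 * dx0 - dy0 * dy0 - dz0 * dz0);
    }
    if (k < K - 1) {
      const double c = 1.0 / (4.0 * D * dtvec[k + 1]);
      const double dx0 = pos(k + 1, 0) - x, dy0 = pos(k + 1, 1) - y,
                   dz0 = pos(k + 1, 2) - z;
      const double dx1 = pos(k + 1, 0) - xp, dy1 = pos(k + 1, 1) - yp,
                   dz1 = pos(k + 1, 2) - zp;
      dlp -= c * (dx1 * dx1 + dy1 * dy1 + dz1 * dz1 -
                  dx0 * dx0 - dy0 * dy0 - dz0 * dz0);
    }

    const double pnew = psf_eval(variant, wxy, wz, xp, yp, zp);
    const double r_old = other_rate[k] + scale[k] * psfv[k];
    const double r_new = other_rate[k] + scale[k] * pnew;
    double dll = -(r_new - r_old);
    if (w[k] > 0) {
      if (r_new <= 0.0) continue;           // zero rate, positive count
      if (r_old <= 0.0) { dll = R_PosInf; } // escaping an impossible state
      else dll += w[k] * (std::log(r_new) - std::log(r_old));
    }

    if (std::log(unif_rand()) < dlp + dll) {
      pos(k, 0) = xp; pos(k, 1) = yp; pos(k, 2) = zp;
      psfv[k] = pnew;
      ++n_acc;
    }
  }
  return List::create(_["pos"] = pos, _["psf"] = psfv,
                      _["n_accept"] = n_acc);
}

// Windowed Brownian-bridge refresh of one molecule's trajectory.
// The trace is cut into windows of length L at a random phase; the interior
// of each window is re-proposed from the exact conditional prior given the
// window's anchors (a Brownian bridge at the current D; the final window,
// having no right anchor, is re-proposed by free forward propagation).
// Because the proposal equals the conditional prior, the Hastings ratio
// reduces to the likelihood ratio over the window's bins.  Far from the
// confocal volume that ratio is ~1, so out-of-volume path segments are
// refreshed essentially from the prior, keeping their roughness in
// equilibrium with the current diffusion coefficient.
// [[Rcpp::export]]
List cpp_bridge_refresh(NumericMatrix pos_in, NumericVector psf_in,
                        IntegerVector w, NumericVector other_rate,
                        NumericVector scale, double D, NumericVector dtvec,
                        int variant, double wxy, double wz, int L) {
  NumericMatrix pos = clone(pos_in);
  NumericVector psfv = clone(psf_in);
  const int K = pos.nrow();
  int n_acc = 0, n_win = 0;
  if (K < 3 || L < 2) {
    return List::create(_["pos"] = pos, _["psf"] = psfv,
                        _["n_accept"] = 0, _["n_windows"] = 0);
  }
  RNGScope rngs;
  // random phase so window boundaries move between sweeps; site 0 keeps its
  // box prior and is never refreshed here
  int a = 1 + (int)std::floor(unif_rand() * L);
  std::vector<double> px(L), py(L), pz(L), pp(L);
  while (a < K) {
    int b = a + L - 1;
    const bool tail = (b >= K - 1);
    if (tail) b = K - 1;
    const int len = b - a + 1;
    // propose interior positions sequentially
    double x = pos(a - 1, 0), y = pos(a - 1, 1), z = pos(a - 1, 2);
    double dll = 0.0;
    bool dead = false;
    for (int k = a; k <= b; ++k) {
      const int i = k - a;
      if (tail) {
        const double sd = std::sqrt(2.0 * D * dtvec[k]);
        x += sd * norm_rand(); y += sd * norm_rand(); z += sd * norm_rand();
      } else {
        const double G = (double)(b + 1 - k + 1); // remaining gap in steps
        const double sd = std::sqrt(2.0 * D * dtvec[k] * (G - 1.0) / G);
        x += (pos(b + 1, 0) - x) / G + sd * norm_rand();
        y += (pos(b + 1, 1) - y) / G + sd * norm_rand();
        z += (pos(b + 1, 2) - z) / G + sd * norm_rand();
      }
      px[i] = x; py[i] = y; pz[i] = z;
      const double pnew = psf_eval(variant, wxy, wz, x, y, z);
      pp[i] = pnew;
      const double r_old = other_rate[k] + scale[k] * psfv[k];
      const double r_new = other_rate[k] + scale[k] * pnew;
      dll -= (r_new - r_old);
      if (w[k] > 0) {
        if (r_new <= 0.0) { dead = true; break; }
        if (r_old <= 0.0) dll = R_PosInf;
        else dll += w[k] * (std::log(r_new) - std::log(r_old));
      }
    }
    ++n_win;
    if (!dead && std::log(unif_rand()) < dll) {
      for (int k = a; k <= b; ++k) {
        const int i = k - a;
        pos(k, 0) = px[i]; pos(k, 1) = py[i]; pos(k, 2) = pz[i];
        psfv[k] = pp[i];
      }
      ++n_acc;
    }
    a = b + 1;
    (void)len;
  }
  return List::create(_["pos"] = pos, _["psf"] = psfv,
                      _["n_accept"] = n_acc, _["n_windows"] = n_win);
}

// Data-anchored window refresh of one molecule's trajectory.
// Like cpp_bridge_refresh, but in windows that contain photon counts the
// proposal is forced through the bright region: the position at the
// window's maximum-count bin k* is drawn near the PSF centre
// (N(0, diag(sa_xy, sa_xy, sa_z)^2)) and the two flanking segments are
// filled with Brownian bridges.  The proposal density is Gaussian and
// evaluated exactly at both the proposed and the current path, so the
// Metropolis-Hastings acceptance is exact whatever the anchor quality.
// This is what lets a molecule jump onto an unexplained fluorescence burst
// (or off an explained one) in a single move.
// Dprop is the diffusivity at which the bridge proposals are generated; it
// need not equal the model's current D (the prior terms lp_* are computed
// at D and the proposal terms lq_* at Dprop, so the acceptance stays
// exact).  Proposing at Dprop != D lets the path's local roughness jump
// between diffusivity scales instead of only diffusing there.
// [[Rcpp::export]]
List cpp_anchor_refresh(NumericMatrix pos_in, NumericVector psf_in,
                        IntegerVector w, NumericVector other_rate,
                        NumericVector scale, double D, NumericVector dtvec,
                        int variant, double wxy, double wz,
                        double sa_xy, double sa_z, int L, double Dprop) {
  NumericMatrix pos = clone(pos_in);
  NumericVector psfv = clone(psf_in);
  const int K = pos.nrow();
  int n_acc = 0, n_win = 0;
  if (K < 3 || L < 4) {
    return List::create(_["pos"] = pos, _["psf"] = psfv,
                        _["n_accept"] = 0, _["n_windows"] = 0);
  }
  RNGScope rngs;
  int a = 1 + (int)std::floor(unif_rand() * L);
  std::vector<double> nx(L + 1), ny(L + 1), nz(L + 1), np(L + 1);
  const double sa2[3] = { sa_xy * sa_xy, sa_xy * sa_xy, sa_z * sa_z };

  while (a < K) {
    int b = a + L - 1;
    const bool tail = (b >= K - 1);
    if (tail) b = K - 1;

    // anchor bin: maximum count in the window (first on ties)
    int kstar = -1, wmax = 0;
    for (int k = a; k <= b; ++k)
      if (w[k] > wmax) { wmax = w[k]; kstar = k; }
    if (kstar < 0) { a = b + 1; continue; }  // dark window: bridge pass covers it
    ++n_win;

    // --- propose, axis by axis, and collect the quadratic forms ---------
    // log q terms (anchor + bridge conditionals) and log p terms
    // (free transitions incl. the step onto the right anchor); all
    // normalisation constants are shared between the proposed and the
    // current path, so only quadratic forms are accumulated.
    double lq_new = 0.0, lq_old = 0.0, lp_new = 0.0, lp_old = 0.0;
    for (int ax = 0; ax < 3; ++ax) {
      // anchor draw
      const double xs_new = std::sqrt(sa2[ax]) * norm_rand();
      const double xs_old = pos(kstar, ax);
      lq_new -= xs_new * xs_new / (2.0 * sa2[ax]);
      lq_old -= xs_old * xs_old / (2.0 * sa2[ax]);

      // left segment a..kstar-1: bridge from pos(a-1) to the anchor
      double xp = pos(a - 1, ax);   // proposed path's previous value
      double xo = pos(a - 1, ax);   // current path's previous value
      for (int k = a; k < kstar; ++k) {
        const double G = (double)(kstar - k + 1);
        const double v = 2.0 * Dprop * dtvec[k] * (G - 1.0) / G;
        const double mn = xp + (xs_new - xp) / G;
        const double mo = xo + (xs_old - xo) / G;
        const double xnew = mn + std::sqrt(v) * norm_rand();
        const double xold = pos(k, ax);
        lq_new -= (xnew - mn) * (xnew - mn) / (2.0 * v);
        lq_old -= (xold - mo) * (xold - mo) / (2.0 * v);
        if (ax == 0) nx[k - a] = xnew;
        else if (ax == 1) ny[k - a] = xnew;
        else nz[k - a] = xnew;
        xp = xnew; xo = xold;
      }
      if (ax == 0) nx[kstar - a] = xs_new;
      else if (ax == 1) ny[kstar - a] = xs_new;
      else nz[kstar - a] = xs_new;

      // right segment kstar+1..b: bridge to pos(b+1) (or free if tail)
      xp = xs_new; xo = xs_old;
      for (int k = kstar + 1; k <= b; ++k) {
        double mn, mo, v;
        if (tail) {
          v = 2.0 * Dprop * dtvec[k];
          mn = xp; mo = xo;
        } else {
          const double G = (double)(b + 1 - k + 1);
          v = 2.0 * Dprop * dtvec[k] * (G - 1.0) / G;
          mn = xp + (pos(b + 1, ax) - xp) / G;
          mo = xo + (pos(b + 1, ax) - xo) / G;
        }
        const double xnew = mn + std::sqrt(v) * norm_rand();
        const double xold = pos(k, ax);
        lq_new -= (xnew - mn) * (xnew - mn) / (2.0 * v);
        lq_old -= (xold - mo) * (xold - mo) / (2.0 * v);
        if (ax == 0) nx[k - a] = xnew;
        else if (ax == 1) ny[k - a] = xnew;
        else nz[k - a] = xnew;
        xp = xnew; xo = xold;
      }

      // prior transitions over the window (and onto the right anchor)
      xp = pos(a - 1, ax); xo = pos(a - 1, ax);
      for (int k = a; k <= b; ++k) {
        const double v = 4.0 * D * dtvec[k]; // 2 * var
        const double xnew = (ax == 0) ? nx[k - a] : (ax == 1) ? ny[k - a] : nz[k - a];
        const double xold = pos(k, ax);
        lp_new -= (xnew - xp) * (xnew - xp) / v;
        lp_old -= (xold - xo) * (xold - xo) / v;
        xp = xnew; xo = xold;
      }
      if (!tail) {
        const double v = 4.0 * D * dtvec[b + 1];
        const double xr = pos(b + 1, ax);
        lp_new -= (xr - xp) * (xr - xp) / v;
        lp_old -= (xr - xo) * (xr - xo) / v;
      }
    }

    // --- likelihood over the window's bins ------------------------------
    double dll = 0.0;
    bool dead = false;
    for (int k = a; k <= b; ++k) {
      const int i = k - a;
      np[i] = psf_eval(variant, wxy, wz, nx[i], ny[i], nz[i]);
      const double r_old = other_rate[k] + scale[k] * psfv[k];
      const double r_new = other_rate[k] + scale[k] * np[i];
      dll -= (r_new - r_old);
      if (w[k] > 0) {
        if (r_new <= 0.0) { dead = true; break; }
        if (r_old <= 0.0) dll = R_PosInf;
        else dll += w[k] * (std::log(r_new) - std::log(r_old));
      }
    }

    const double logalpha = dll + (lp_new - lp_old) + (lq_old - lq_new);
    if (!dead && std::log(unif_rand()) < logalpha) {
      for (int k = a; k <= b; ++k) {
        const int i = k - a;
        pos(k, 0) = nx[i]; pos(k, 1) = ny[i]; pos(k, 2) = nz[i];
        psfv[k] = np[i];
      }
      ++n_acc;
    }
    a = b + 1;
  }
  return List::create(_["pos"] = pos, _["psf"] = psfv,
                      _["n_accept"] = n_acc, _["n_windows"] = n_win);
}

// Accumulate sum_n PSF(pos^n_k) over n_mol independent free Brownian paths
// without storing them: reservoir-style generator for long stationary traces.
// Initial positions are uniform in the box; paths wrap periodically at the
// box faces so the occupancy of the (much smaller) confocal region stays
// statistically stationary over arbitrarily long traces.
// [[Rcpp::export]]
NumericVector cpp_sum_psf_paths(int n_mol, int K, double D, double dt,
                                NumericVector box, int variant,
                                double wxy, double wz) {
  NumericVector s(K);
  const double sd = std::sqrt(2.0 * D * dt);
  RNGScope rngs;
  for (int n = 0; n < n_mol; ++n) {
    double x = box[0] * (2.0 * unif_rand() - 1.0);
    double y = box[1] * (2.0 * unif_rand() - 1.0);
    double z = box[2] * (2.0 * unif_rand() - 1.0);
    for (int k = 0; k < K; ++k) {
      if (k > 0) {
        x += sd * norm_rand();
        y += sd * norm_rand();
        z += sd * norm_rand();
        // periodic wrap: keep coordinates inside [-box, box]
        if (x > box[0]) x -= 2.0 * box[0]; else if (x < -box[0]) x += 2.0 * box[0];
        if (y > box[1]) y -= 2.0 * box[1]; else if (y < -box[1]) y += 2.0 * box[1];
        if (z > box[2]) z -= 2.0 * box[2]; else if (z < -box[2]) z += 2.0 * box[2];
      }
      s[k] += psf_eval(variant, wxy, wz, x, y, z);
    }
  }
  return s;
}
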