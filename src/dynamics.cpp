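#include <Rcpp.h>
using namespace Rcpp;

static inline void normalize3(double* v) {
  double n = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  v[0] /= n; v[1] /= n; v[2] /= n;
}

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// Rotate v in place about the unit axis k by angle ang (Rodrigues formula).
static inline void rodrigues(double* v, const double* k, double ang) {
  double c = std::cos(ang), s = std::sin(ang);
  double kv[3];
  cross3(k, v, kv);
  double kd = k[0] * v[0] + k[1] * v[1] + k[2] * v[2];
  for (int i = 0; i < 3; ++i)
    v[i] = v[i] * c + kv[i] * s + k[i] * kd * (1.0 - c);
}

// Orthonormal pair (u, w) spanning the plane perpendicular to unit n.
static inline void perp_basis(const double* n, double* u, double* w) {
  double ref[3] = {1.0, 0.0, 0.0};
  if (std::fabs(n[0]) > 0.9) { ref[0] = 0.0; ref[1] = 1.0; }
  cross3(n, ref, u);
  normalize3(u);
  cross3(n, u, w);
}

// One isotropic rotational-diffusion step of a unit vector: independent
// Gaussian angular increments (sd = sig) about two perpendicular axes.
static inline void diffuse_direction(double* n, double sig) {
  double u[3], w[3];
  perp_basis(n, u, w);
  double g1 = R::norm_rand() * sig;
  double g2 = R::norm_rand() * sig;
  rodrigues(n, u, g1);
  rodrigues(n, w, g2);
  normalize3(n);
}

// Rotational-diffusion path of a full body frame (helix axis h plus the
// transverse pair e1, e2). Returns an (n_steps+1) x 9 matrix with rows
// [h, e1, e2]; row 0 is the initial frame. Angular increments have variance
// 2*Dr*dt about each of the two transverse axes, the frame is
// re-orthonormalized after every step.
// [[Rcpp::export]]
NumericMatrix rotdiff_frames_cpp(int n_steps, double Dr, double dt,
                                 NumericVector init) {
  if (init.size() != 9) stop("init frame must have 9 elements");
  NumericMatrix out(n_steps + 1, 9);
  double h[3], e1[3], e2[3];
  for (int i = 0; i < 3; ++i) {
    h[i] = init[i]; e1[i] = init[3 + i]; e2[i] = init[6 + i];
  }
  double sig = std::sqrt(2.0 * Dr * dt);
  for (int i = 0; i < 3; ++i) {
    out(0, i) = h[i]; out(0, 3 + i) = e1[i]; out(0, 6 + i) = e2[i];
  }
  for (int s = 1; s <= n_steps; ++s) {
    if (Dr > 0.0) {
      double g1 = R::norm_rand() * sig;
      double g2 = R::norm_rand() * sig;
      double ax1[3] = {e1[0], e1[1], e1[2]};
      rodrigues(h, ax1, g1);
      rodrigues(e2, ax1, g1);
      double ax2[3] = {e2[0], e2[1], e2[2]};
      rodrigues(h, ax2, g2);
      rodrigues(e1, ax2, g2);
      // re-orthonormalize (Gram-Schmidt keeps drift at machine precision)
      normalize3(h);
      double d = e1[0] * h[0] + e1[1] * h[1] + e1[2] * h[2];
      for (int i = 0; i < 3; ++i) e1[i] -= d * h[i];
      normalize3(e1);
      cross3(h, e1, e2);
    }
    for (int i = 0; i < 3; ++i) {
      out(s, i) = h[i]; out(s, 3 + i) = e1[i]; out(s, 6 + i) = e2[i];
    }
  }
  return out;
}

// Brownian dynamics ensemble of self-propelled ellipsoidal swimmers with an
// adaptive linear-response reorientation rate.
//
// Chemical memory: the convolution I(t) = int_{-inf}^t c(t') R(t-t') dt' with
// R(t) = W k exp(-kt) [1 - kt/2 - (kt/2)^2] is carried by three
// exponentially-weighted moments S_m(t) = int c(t') (t-t')^m exp(-k(t-t')) dt',
// updated exactly for piecewise-constant c:
//   shift:  S0' = e S0; S1' = e (S1 + dt S0); S2' = e (S2 + 2 dt S1 + dt^2 S0)
//   inject: S0 += c a0; S1 += c a1; S2 += c a2   (closed-form segment moments)
// and I = W k (S0 - k/2 S1 - k^2/4 S2).
//
// mode: 0 none, 1 lengthen-only, 2 shorten-only, 3 bipolar
// reorient: 0 reverse (exact flip), 1 tumble (gamma-distributed angle)
// [[Rcpp::export]]
List simulate_ensemble_cpp(int n_cells, int n_steps, double dt,
                           double v0, double lambda0, double Dr,
                           double Dpar, double Dperp,
                           NumericVector grad, double W, double k,
                           int mode, int reorient,
                           double tumble_shape, double tumble_scale,
                           int equil_steps, int record_every,
                           bool store_directions, bool store_reversals) {
  int n_rec = n_steps / record_every + 1;
  NumericVector pos_arr(Dimension(n_rec, 3, n_cells));
  NumericVector dir_arr(store_directions ? Dimension(n_rec, 3, n_cells)
                                         : Dimension(0, 0, 0));
  IntegerVector n_rev(n_cells);
  List rev_times(store_reversals ? n_cells : 0);

  double sig = std::sqrt(2.0 * Dr * dt);
  double spar = Dpar > 0 ? std::sqrt(2.0 * Dpar * dt) : 0.0;
  double sperp = Dperp > 0 ? std::sqrt(2.0 * Dperp * dt) : 0.0;
  double e = std::exp(-k * dt);
  double a0 = (1.0 - e) / k;
  double a1 = (1.0 - e * (1.0 + k * dt)) / (k * k);
  double a2 = (2.0 - e * (2.0 + 2.0 * k * dt + k * k * dt * dt)) / (k * k * k);
  double g0 = grad[0], g1v = grad[1], g2v = grad[2];

  long floored = 0;
  double pmax = 0.0;

  for (int cell = 0; cell < n_cells; ++cell) {
    // isotropic random initial direction
    double n[3] = {R::norm_rand(), R::norm_rand(), R::norm_rand()};
    normalize3(n);
    for (int s = 0; s < equil_steps; ++s)
      if (Dr > 0.0) diffuse_direction(n, sig);

    double pos[3] = {0.0, 0.0, 0.0};
    // memory pre-filled at the starting concentration c0 (here c0 = 0 at the
    // origin in general only if grad.pos = 0; use the steady-state moments)
    double c0 = g0 * pos[0] + g1v * pos[1] + g2v * pos[2];
    double S0 = c0 / k, S1 = c0 / (k * k), S2 = 2.0 * c0 / (k * k * k);

    std::vector<double> revs;
    int rec = 0;
    for (int i = 0; i < 3; ++i) pos_arr[rec + n_rec * (i + 3 * cell)] = pos[i];
    if (store_directions)
      for (int i = 0; i < 3; ++i) dir_arr[rec + n_rec * (i + 3 * cell)] = n[i];

    for (int s = 0; s < n_steps; ++s) {
      double c = g0 * pos[0] + g1v * pos[1] + g2v * pos[2];
      double S0n = e * S0;
      double S1n = e * (S1 + dt * S0);
      double S2n = e * (S2 + 2.0 * dt * S1 + dt * dt * S0);
      S0 = S0n + c * a0;
      S1 = S1n + c * a1;
      S2 = S2n + c * a2;

      double lam = lambda0;
      if (mode != 0 && W != 0.0) {
        double I = W * k * (S0 - 0.5 * k * S1 - 0.25 * k * k * S2);
        lam = lambda0 * (1.0 - I);
        if (mode == 1 && lam > lambda0) lam = lambda0;        // lengthen only
        else if (mode == 2 && lam < lambda0) lam = lambda0;   // shorten only
        if (lam < 0.0) { lam = 0.0; ++floored; }
      }
      double p = lam * dt;
      if (p > pmax) pmax = p;
      if (p > 1.0) stop("lambda(t)*dt exceeded 1: invalid discretization");
      if (p > 0.0 && R::unif_rand() < p) {
        if (reorient == 0) {
          n[0] = -n[0]; n[1] = -n[1]; n[2] = -n[2];
        } else {
          double ang = R::rgamma(tumble_shape, tumble_scale);
          if (ang > M_PI) ang = M_PI;
          double u[3], w[3];
          perp_basis(n, u, w);
          double az = R::unif_rand() * 2.0 * M_PI;
          double ax[3];
          for (int i = 0; i < 3; ++i)
            ax[i] = std::cos(az) * u[i] + std::sin(az) * w[i];
          rodrigues(n, ax, ang);
          normalize3(n);
        }
        ++n_rev[cell];
        if (store_reversals) revs.push_back((s + 1) * dt);
      }
      if (Dr > 0.0) diffuse_direction(n, sig);
      double dpar = v0 * dt + (spar > 0 ? R::norm_rand() * spar : 0.0);
      pos[0] += dpar * n[0];
      pos[1] += dpar * n[1];
      pos[2] += dpar * n[2];
      if (sperp > 0) {
        double u[3], w[3];
        perp_basis(n, u, w);
        double zu = R::norm_rand() * sperp, zw = R::norm_rand() * sperp;
        for (int i = 0; i < 3; ++i) pos[i] += zu * u[i] + zw * w[i];
      }
      if ((s + 1) % record_every == 0) {
        ++rec;
        for (int i = 0; i < 3; ++i)
          pos_arr[rec + n_rec * (i + 3 * cell)] = pos[i];
        if (store_directions)
          for (int i = 0; i < 3; ++i)
            dir_arr[rec + n_rec * (i + 3 * cell)] = n[i];
      }
    }
    if (store_reversals) rev_times[cell] = wrap(revs);
  }

  NumericVector times(n_rec);
  for (int r = 0; r < n_rec; ++r) times[r] = r * record_every * dt;

  return List::create(
    _["times"] = times,
    _["positions"] = pos_arr,
    _["directions"] = dir_arr,
    _["n_reversals"] = n_rev,
    _["reversal_times"] = rev_times,
    _["floored_fraction"] = (double)floored / ((double)n_steps * n_cells),
    _["max_lambda_dt"] = pmax);
}
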