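#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Units: lengths in Angstrom, times in ns, rates in 1/ns, angles in rad.
// All randomness comes from R's RNG (norm_rand/unif_rand/exp_rand), so a
// single set.seed() call makes every kernel bit-reproducible.

static const double POLE_EPS = 1e-6;
// polar window (rad) inside which angle coordinates are abandoned for a
// local tangent-plane step; the cot/tan drifts are singular at the poles
// and a narrow window is not enough once a step can land inside it
static const double POLE_WINDOW = 0.3;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// reflect a polar angle into [0, pi]; azimuth shifts by pi on reflection
static inline void reflect_polar(double &th, double &ph) {
  if (th < 0.0 || th > M_PI) {
    double t = th - 2.0 * M_PI * std::floor(th / (2.0 * M_PI));
    if (t > M_PI) { t = 2.0 * M_PI - t; ph += M_PI; }
    th = t;
  }
}

// --- spherical Brownian motion -------------------------------------------
//
// Angle-coordinate Heun (Stratonovich) step for
//   dtheta = (sigma^2/2) cot(theta) dt + sigma o dB
//   dphi   = sigma / sin(theta)       o dB'
// with sigma^2 = 2 D.  Within a pole tolerance the step is taken in the
// local tangent plane and rotated back to the sphere, which removes the
// coordinate singularity without touching the uniform stationary law.
static void sphere_step_(double &th, double &ph, double sig, double dt) {
  const double sdt = std::sqrt(dt);
  const double z1 = norm_rand(), z2 = norm_rand();
  // keep angle steps well clear of the pole: the window must dominate a
  // few step standard deviations or the cot drift can overshoot
  double win = std::max(POLE_WINDOW, 5.0 * sig * sdt);
  if (win > 1.0) win = 1.0;
  if (th < win || th > M_PI - win) {
    // tangent-plane step
    double st = std::sin(th), ct = std::cos(th);
    double cp = std::cos(ph), sp = std::sin(ph);
    double mx = st * cp, my = st * sp, mz = ct;
    // orthonormal frame (e1 = d mu/d theta, e2 = azimuthal direction)
    double e1x = ct * cp, e1y = ct * sp, e1z = -st;
    double e2x = -sp, e2y = cp, e2z = 0.0;
    double a = sig * sdt * z1, b = sig * sdt * z2;
    double x = mx + a * e1x + b * e2x;
    double y = my + a * e1y + b * e2y;
    double z = mz + a * e1z + b * e2z;
    double n = std::sqrt(x * x + y * y + z * z);
    th = std::acos(clampd(z / n, -1.0, 1.0));
    ph = std::atan2(y, x);
    return;
  }
  const double D = 0.5 * sig * sig;
  double th_safe = clampd(th, POLE_EPS, M_PI - POLE_EPS);
  double a0 = D / std::tan(th_safe);
  double b0 = sig / std::sin(th_safe);
  // predictor
  double thp = th + a0 * dt + sig * sdt * z1;
  double php = ph; // phi does not enter any coefficient
  reflect_polar(thp, php);
  double thp_safe = clampd(thp, POLE_EPS, M_PI - POLE_EPS);
  double a1 = D / std::tan(thp_safe);
  double b1 = sig / std::sin(thp_safe);
  // corrector (shared Brownian increments)
  th = th + 0.5 * (a0 + a1) * dt + sig * sdt * z1;
  ph = ph + 0.5 * (b0 + b1) * sdt * z2;
  reflect_polar(th, ph);
}

// [[Rcpp::export]]
NumericMatrix cpp_sphere_path(double theta0, double phi0, double D,
                              double dt, int n_steps) {
  if (D < 0 || dt <= 0 || n_steps < 0) stop("invalid sphere path arguments");
  NumericMatrix out(n_steps + 1, 2);
  double th = theta0, ph = phi0;
  double sig = std::sqrt(2.0 * D);
  out(0, 0) = th; out(0, 1) = ph;
  for (int i = 1; i <= n_steps; ++i) {
    sphere_step_(th, ph, sig, dt);
    out(i, 0) = th; out(i, 1) = ph;
  }
  return out;
}

// --- elastic pendulum -----------------------------------------------------
//
// Stratonovich-Heun step for the spherical-coordinate Langevin system
//   dr     = [-k_r (r - r_eq) + c_r / r] dt            + sigma_r          o dB
//   dtheta = [-k_th sin(theta)
//             + sigma_th^2/(2 r^2 tan(theta))] dt      + (sigma_th / r)   o dB'
//   dphi   =                                            (sigma_ph /
//                                                        (r sin(theta)))  o dB''
// A step driving r non-positive is retried with halved dt (split in two).
struct PendulumPars {
  double kr, kth, req, cr, sr, sth, sph;
};

static void pendulum_drift_noise_(const PendulumPars &p, double r, double th,
                                  double *a, double *b) {
  double r_safe = std::max(r, 1e-12);
  double th_safe = clampd(th, POLE_EPS, M_PI - POLE_EPS);
  a[0] = -p.kr * (r_safe - p.req) + p.cr / r_safe;
  a[1] = -p.kth * std::sin(th_safe) +
         p.sth * p.sth / (2.0 * r_safe * r_safe * std::tan(th_safe));
  a[2] = 0.0;
  b[0] = p.sr;
  b[1] = p.sth / r_safe;
  b[2] = p.sph / (r_safe * std::sin(th_safe));
}

static int pendulum_step_(const PendulumPars &p, double &r, double &th,
                          double &ph, double dt, int depth) {
  if (depth > 30) stop("pendulum step: dt halving exceeded 30 levels");
  double sdt = std::sqrt(dt);
  double z[3] = {norm_rand(), norm_rand(), norm_rand()};
  double r_safe = std::max(r, 1e-12);
  double win = std::max(POLE_WINDOW, 5.0 * (p.sth / r_safe) * sdt);
  if (win > 1.0) win = 1.0;
  bool near_pole = (th < win || th > M_PI - win);
  double rn, thn, phn;
  if (near_pole) {
    // angular part in the local tangent plane at the pole: for small polar
    // offsets the spherical angular system is an isotropic 2-D diffusion
    // (scale sigma_th / r) with the sin(theta) restoring force; the
    // cot(theta) geometric drift is generated automatically
    bool south = th > 0.5 * M_PI;
    double v = south ? M_PI - th : th;   // offset from the nearer pole
    double u1 = v * std::cos(ph), u2 = v * std::sin(ph);
    double restoring = (v > 1e-12) ? -p.kth * std::sin(th) * (south ? -1.0 : 1.0) / v : 0.0;
    // drift per component: restoring * u_i (sign folded via 'south')
    double a0r = -p.kr * (r_safe - p.req) + p.cr / r_safe;
    double bang0 = p.sth / r_safe;
    double u1p = u1 + restoring * u1 * dt + bang0 * sdt * z[1];
    double u2p = u2 + restoring * u2 * dt + bang0 * sdt * z[2];
    double rp = r + a0r * dt + p.sr * sdt * z[0];
    if (rp <= 0.0) {
      int d1 = pendulum_step_(p, r, th, ph, 0.5 * dt, depth + 1);
      int d2 = pendulum_step_(p, r, th, ph, 0.5 * dt, depth + 1);
      return 1 + std::max(d1, d2);
    }
    double vp = std::sqrt(u1p * u1p + u2p * u2p);
    double thp_full = south ? M_PI - vp : vp;
    double rest1 = (vp > 1e-12) ? -p.kth * std::sin(clampd(thp_full, 0.0, M_PI)) *
                                      (south ? -1.0 : 1.0) / vp : 0.0;
    double a1r = -p.kr * (rp - p.req) + p.cr / rp;
    double bang1 = p.sth / rp;
    rn = r + 0.5 * (a0r + a1r) * dt + p.sr * sdt * z[0];
    double u1n = u1 + 0.5 * (restoring * u1 + rest1 * u1p) * dt +
                 0.5 * (bang0 + bang1) * sdt * z[1];
    double u2n = u2 + 0.5 * (restoring * u2 + rest1 * u2p) * dt +
                 0.5 * (bang0 + bang1) * sdt * z[2];
    double vn = std::sqrt(u1n * u1n + u2n * u2n);
    thn = south ? M_PI - vn : vn;
    phn = std::atan2(u2n, u1n);
    if (vn < 1e-15) phn = ph;
  } else {
    double a0[3], b0[3], a1[3], b1[3];
    pendulum_drift_noise_(p, r, th, a0, b0);
    double rp = r + a0[0] * dt + b0[0] * sdt * z[0];
    double thp = th + a0[1] * dt + b0[1] * sdt * z[1];
    double php = ph;
    if (rp <= 0.0) { // reject, retry at finer resolution
      int d1 = pendulum_step_(p, r, th, ph, 0.5 * dt, depth + 1);
      int d2 = pendulum_step_(p, r, th, ph, 0.5 * dt, depth + 1);
      return 1 + std::max(d1, d2);
    }
    reflect_polar(thp, php);
    pendulum_drift_noise_(p, rp, thp, a1, b1);
    rn = r + 0.5 * (a0[0] + a1[0]) * dt + 0.5 * (b0[0] + b1[0]) * sdt * z[0];
    thn = th + 0.5 * (a0[1] + a1[1]) * dt + 0.5 * (b0[1] + b1[1]) * sdt * z[1];
    phn = ph + 0.5 * (b0[2] + b1[2]) * sdt * z[2];
  }
  if (rn <= 0.0) {
    int d1 = pendulum_step_(p, r, th, ph, 0.5 * dt, depth + 1);
    int d2 = pendulum_step_(p, r, th, ph, 0.5 * dt, depth + 1);
    return 1 + std::max(d1, d2);
  }
  r = rn; th = thn; ph = phn;
  reflect_polar(th, ph);
  return 0;
}

// [[Rcpp::export]]
List cpp_pendulum_path(NumericVector state0, double kr, double kth,
                       double req, double cr, double sr, double sth,
                       double sph, double dt, int n_steps) {
  if (state0.size() != 3) stop("state0 must be (r, theta, phi)");
  if (state0[0] <= 0) stop("initial radius must be positive");
  PendulumPars p = {kr, kth, req, cr, sr, sth, sph};
  NumericMatrix out(n_steps + 1, 3);
  double r = state0[0], th = state0[1], ph = state0[2];
  out(0, 0) = r; out(0, 1) = th; out(0, 2) = ph;
  int n_retry = 0;
  for (int i = 1; i <= n_steps; ++i) {
    n_retry += pendulum_step_(p, r, th, ph, dt, 0);
    out(i, 0) = r; out(i, 1) = th; out(i, 2) = ph;
  }
  return List::create(_["path"] = out, _["n_retries"] = n_retry);
}

// --- kappa^2 --------------------------------------------------------------

static inline double kappa2_(double thD, double phD, double thA, double phA,
                             const double *rhat) {
  double sD = std::sin(thD), sA = std::sin(thA);
  double mD[3] = {sD * std::cos(phD), sD * std::sin(phD), std::cos(thD)};
  double mA[3] = {sA * std::cos(phA), sA * std::sin(phA), std::cos(thA)};
  double dd = mD[0] * mA[0] + mD[1] * mA[1] + mD[2] * mA[2];
  double rd = rhat[0] * mD[0] + rhat[1] * mD[1] + rhat[2] * mD[2];
  double ra = rhat[0] * mA[0] + rhat[1] * mA[1] + rhat[2] * mA[2];
  double k = dd - 3.0 * rd * ra;
  return k * k;
}

// --- one excitation event with dynamic kappa ------------------------------
//
// Exact Lewis-Shedler thinning of the inhomogeneous total exit hazard
// lambda(t) = k_D + k_ET(t), bounded by k_D (1 + 4 C / r^6) since
// kappa^2 <= 4 and the inter-dye distance is frozen during the event.
// Both dipoles evolve by spherical Brownian motion between candidate times;
// the integral of kappa^2 along the path is accumulated by trapezoid.
struct EventResult {
  int outcome;      // 0 = donor photon, 1 = acceptor photon
  double dwell;     // time spent in the donor excited state
  double delay;     // excitation-to-photon delay
  double mean_k2;   // time-average kappa^2 over the dwell
};

static EventResult sample_event_dynamic_(const double *rvec, double r,
                                         double &thD, double &phD,
                                         double &thA, double &phA,
                                         double kD, double kA,
                                         double C, double DD, double DA,
                                         double dt_orient) {
  double rhat[3] = {rvec[0] / r, rvec[1] / r, rvec[2] / r};
  double r6 = std::pow(r, 6.0);
  double lam_max = kD * (1.0 + 4.0 * C / r6);
  double sigD = std::sqrt(2.0 * DD), sigA = std::sqrt(2.0 * DA);
  double t = 0.0, k2_int = 0.0;
  double k2 = kappa2_(thD, phD, thA, phA, rhat);
  const double t_cap = 500.0 / kD; // survival beyond this is ~exp(-500)
  EventResult res;
  for (;;) {
    double w = exp_rand() / lam_max;
    if (t + w > t_cap) { // numerically impossible tail; emit donor photon
      res.outcome = 0; res.dwell = t_cap; res.delay = t_cap;
      res.mean_k2 = k2_int / t_cap;
      return res;
    }
    // propagate both dipoles over w, accumulating the kappa^2 integral
    int n_sub = (int)std::ceil(w / dt_orient);
    if (n_sub < 1) n_sub = 1;
    double h = w / n_sub;
    for (int i = 0; i < n_sub; ++i) {
      sphere_step_(thD, phD, sigD, h);
      sphere_step_(thA, phA, sigA, h);
      double k2n = kappa2_(thD, phD, thA, phA, rhat);
      k2_int += 0.5 * (k2 + k2n) * h;
      k2 = k2n;
    }
    t += w;
    double lam_t = kD * (1.0 + C * k2 / r6);
    if (lam_t > lam_max * (1.0 + 1e-9))
      stop("thinning bound violated (kappa^2 > 4?)"); // cannot happen
    if (unif_rand() * lam_max < lam_t) {
      // accepted exit at time t; pick the exit branch
      res.dwell = t;
      res.mean_k2 = (t > 0.0) ? k2_int / t : k2;
      if (unif_rand() * lam_t < kD) {
        res.outcome = 0; res.delay = t;
      } else {
        res.outcome = 1; res.delay = t + exp_rand() / kA;
      }
      return res;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_sample_event_dynamic(NumericVector rvec, double thD,
                                       double phD, double thA, double phA,
                                       double kD, double kA, double C,
                                       double DD, double DA,
                                       double dt_orient) {
  if (rvec.size() != 3) stop("rvec must have length 3");
  double r = std::sqrt(rvec[0] * rvec[0] + rvec[1] * rvec[1] +
                       rvec[2] * rvec[2]);
  if (r <= 0) stop("zero separation must be handled by the caller");
  double rv[3] = {rvec[0], rvec[1], rvec[2]};
  EventResult e = sample_event_dynamic_(rv, r, thD, phD, thA, phA, kD, kA,
                                        C, DD, DA, dt_orient);
  return NumericVector::create(e.outcome, e.dwell, e.delay, e.mean_k2);
}

// --- burst-level experiment loop ------------------------------------------

struct Frame { double e1[3], e2[3], u[3]; };

static Frame frame_from_pole_(const double *u) {
  Frame f;
  double n = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  for (int i = 0; i < 3; ++i) f.u[i] = u[i] / n;
  // any vector not parallel to u
  double a[3] = {1.0, 0.0, 0.0};
  if (std::fabs(f.u[0]) > 0.9) { a[0] = 0.0; a[1] = 1.0; }
  // e1 = normalize(a - (a.u)u), e2 = u x e1
  double du = a[0] * f.u[0] + a[1] * f.u[1] + a[2] * f.u[2];
  double e1[3] = {a[0] - du * f.u[0], a[1] - du * f.u[1], a[2] - du * f.u[2]};
  double ne = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
  for (int i = 0; i < 3; ++i) f.e1[i] = e1[i] / ne;
  f.e2[0] = f.u[1] * f.e1[2] - f.u[2] * f.e1[1];
  f.e2[1] = f.u[2] * f.e1[0] - f.u[0] * f.e1[2];
  f.e2[2] = f.u[0] * f.e1[1] - f.u[1] * f.e1[0];
  return f;
}

static inline void pendulum_position_(const Frame &f, const double *att,
                                      double r, double th, double ph,
                                      double *x) {
  double st = std::sin(th);
  double c1 = r * st * std::cos(ph), c2 = r * st * std::sin(ph);
  double c3 = r * std::cos(th);
  for (int i = 0; i < 3; ++i)
    x[i] = att[i] + c1 * f.e1[i] + c2 * f.e2[i] + c3 * f.u[i];
}

// exact OU transition per axis
static inline void ou_propagate_(double *x, const double *xeq,
                                 const double *k, double sig, double dt) {
  for (int i = 0; i < 3; ++i) {
    double e = std::exp(-k[i] * dt);
    double sd = sig * std::sqrt((1.0 - e * e) / (2.0 * k[i]));
    x[i] = xeq[i] + (x[i] - xeq[i]) * e + sd * norm_rand();
  }
}

static inline void uniform_sphere_(double &th, double &ph) {
  th = std::acos(1.0 - 2.0 * unif_rand());
  ph = 2.0 * M_PI * unif_rand();
}

// propagate a dipole over a long (inter-event) gap: once the accumulated
// angular mean squared displacement exceeds a few radians^2 the orientation
// has mixed to uniform; otherwise coarse diffusion steps (<= 0.1 rad^2
// MSD each) carry the correlation
static void dipole_gap_(double &th, double &ph, double D, double gap) {
  double msd = 4.0 * D * gap;
  if (msd > 8.0) { uniform_sphere_(th, ph); return; }
  int n = (int)std::ceil(msd / 0.1);
  if (n < 1) n = 1;
  double h = gap / n;
  double sig = std::sqrt(2.0 * D);
  for (int i = 0; i < n; ++i) sphere_step_(th, ph, sig, h);
}

// Simulate n_bursts bursts.  Per burst: dye state drawn fresh (new molecule),
// detected excitation events pre-thinned at the detection efficiency
// (detection is outcome-independent Bernoulli with equal channel
// efficiencies, so thinning commutes with the photophysics), translational
// state propagated between detected events, each event resolved either in
// the homogeneous closed form (static kappa^2) or by exact thinning with
// evolving dipoles (dynamic kappa).
//
// model: 0 = OU springs, 1 = elastic pendulum.
// Returns a matrix with columns
//   I_D, I_A, donor_delay_sum, mean_k2_sum, n_events, r_sum
// [[Rcpp::export]]
NumericMatrix cpp_run_bursts(int model, int n_bursts, int n_pulses,
                             double period, double det_eff, double kD,
                             double kA, double C, bool kappa_dynamic,
                             double kappa_static, double DD, double DA,
                             double dt_orient, bool dipole_reset_burst,
                             NumericVector kvecD, NumericVector kvecA,
                             double sigD_tr, double sigA_tr,
                             NumericVector attD, NumericVector attA,
                             double kr, double kth, double req, double cr,
                             double sr, double sth, double sph,
                             NumericVector poleD, NumericVector poleA,
                             double dt_trans, int n_burn) {
  if (det_eff <= 0 || det_eff > 1) stop("detection efficiency outside (0,1]");
  NumericMatrix out(n_bursts, 6);
  PendulumPars pp = {kr, kth, req, cr, sr, sth, sph};
  Frame fD, fA;
  double aD[3] = {attD[0], attD[1], attD[2]};
  double aA[3] = {attA[0], attA[1], attA[2]};
  if (model == 1) {
    double pD[3] = {poleD[0], poleD[1], poleD[2]};
    double pA[3] = {poleA[0], poleA[1], poleA[2]};
    fD = frame_from_pole_(pD);
    fA = frame_from_pole_(pA);
  }
  double kD_ax[3] = {kvecD[0], kvecD[1], kvecD[2]};
  double kA_ax[3] = {kvecA[0], kvecA[1], kvecA[2]};
  // pendulum start near the deterministic radial fixed point
  double r_star = 0.5 * (req + std::sqrt(req * req + 4.0 * cr / kr));
  const double lg1m = std::log1p(-det_eff);

  for (int b = 0; b < n_bursts; ++b) {
    // --- initial molecule state
    double xD[3], xA[3];                 // OU positions
    double sD[3], sA[3];                 // pendulum (r, th, ph)
    if (model == 0) {
      for (int i = 0; i < 3; ++i) {
        xD[i] = aD[i] + sigD_tr / std::sqrt(2.0 * kD_ax[i]) * norm_rand();
        xA[i] = aA[i] + sigA_tr / std::sqrt(2.0 * kA_ax[i]) * norm_rand();
      }
    } else {
      sD[0] = r_star; sD[1] = 1.0; sD[2] = 2.0 * M_PI * unif_rand();
      sA[0] = r_star; sA[1] = 1.0; sA[2] = 2.0 * M_PI * unif_rand();
      for (int i = 0; i < n_burn; ++i) {
        pendulum_step_(pp, sD[0], sD[1], sD[2], dt_trans, 0);
        pendulum_step_(pp, sA[0], sA[1], sA[2], dt_trans, 0);
      }
    }
    double I_D = 0, I_A = 0, delay_sum = 0, k2_sum = 0, r_sum = 0;
    int n_ev = 0;
    double thD = 0, phD = 0, thA = 0, phA = 0;
    if (kappa_dynamic && dipole_reset_burst) {
      uniform_sphere_(thD, phD);
      uniform_sphere_(thA, phA);
    }
    long idx = 0; // pulse index of previous detected event
    for (;;) {
      // geometric skip to the next detected pulse
      long g = 1 + (long)std::floor(std::log(unif_rand()) / lg1m);
      if (idx + g > n_pulses) break;
      double gap = g * period;
      idx += g;
      // propagate translational state over the gap
      if (model == 0) {
        ou_propagate_(xD, aD, kD_ax, sigD_tr, gap);
        ou_propagate_(xA, aA, kA_ax, sigA_tr, gap);
      } else {
        int n_sub = (int)std::ceil(gap / dt_trans);
        double h = gap / n_sub;
        for (int i = 0; i < n_sub; ++i) {
          pendulum_step_(pp, sD[0], sD[1], sD[2], h, 0);
          pendulum_step_(pp, sA[0], sA[1], sA[2], h, 0);
        }
        pendulum_position_(fD, aD, sD[0], sD[1], sD[2], xD);
        pendulum_position_(fA, aA, sA[0], sA[1], sA[2], xA);
      }
      double rv[3] = {xA[0] - xD[0], xA[1] - xD[1], xA[2] - xD[2]};
      double r = std::sqrt(rv[0] * rv[0] + rv[1] * rv[1] + rv[2] * rv[2]);
      n_ev += 1;
      r_sum += r;
      if (r < 1e-9) {
        // CTMC reduction at r = 0: certain transfer, Exp(kA) acceptor delay
        I_A += 1; k2_sum += kappa_static;
        continue;
      }
      if (!kappa_dynamic) {
        double kET = kD * C * kappa_static / std::pow(r, 6.0);
        double ktot = kD + kET;
        double dwell = exp_rand() / ktot;
        k2_sum += kappa_static;
        if (unif_rand() * ktot < kD) { I_D += 1; delay_sum += dwell; }
        else I_A += 1;
      } else {
        if (dipole_reset_burst) {
          // dipoles persist on the molecule: diffuse over the inter-event
          // gap (the dwell itself advances them inside the event sampler)
          dipole_gap_(thD, phD, DD, gap);
          dipole_gap_(thA, phA, DA, gap);
        } else {
          uniform_sphere_(thD, phD);
          uniform_sphere_(thA, phA);
        }
        EventResult e = sample_event_dynamic_(rv, r, thD, phD, thA, phA,
                                              kD, kA, C, DD, DA, dt_orient);
        k2_sum += e.mean_k2;
        if (e.outcome == 0) { I_D += 1; delay_sum += e.delay; }
        else I_A += 1;
      }
    }
    out(b, 0) = I_D; out(b, 1) = I_A; out(b, 2) = delay_sum;
    out(b, 3) = k2_sum; out(b, 4) = n_ev; out(b, 5) = r_sum;
    if (b % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// --- kappa^2 path ensembles --------------------------------------------
//
// n_paths independent excitation-style kappa^2 trajectories of the given
// duration with both dipoles diffusing on the sphere and the separation
// direction fixed along x.  Internally stepped at dt_int; kappa^2 recorded
// on a coarse uniform output grid and the exact trapezoid time-average
// accumulated per path.
// [[Rcpp::export]]
List cpp_kappa_paths(int n_paths, double duration, double dt_int, int n_out,
                     double DD, double DA) {
  NumericMatrix grid(n_paths, n_out + 1);
  NumericVector pmean(n_paths);
  double rhat[3] = {1.0, 0.0, 0.0};
  double sigD = std::sqrt(2.0 * DD), sigA = std::sqrt(2.0 * DA);
  int n_steps = (int)std::ceil(duration / dt_int);
  double h = duration / n_steps;
  double out_dt = duration / n_out;
  for (int p = 0; p < n_paths; ++p) {
    double thD, phD, thA, phA;
    uniform_sphere_(thD, phD);
    uniform_sphere_(thA, phA);
    double k2 = kappa2_(thD, phD, thA, phA, rhat);
    double k2_int = 0.0;
    grid(p, 0) = k2;
    int next_out = 1;
    for (int i = 1; i <= n_steps; ++i) {
      sphere_step_(thD, phD, sigD, h);
      sphere_step_(thA, phA, sigA, h);
      double k2n = kappa2_(thD, phD, thA, phA, rhat);
      k2_int += 0.5 * (k2 + k2n) * h;
      k2 = k2n;
      double t = i * h;
      while (next_out <= n_out && t >= next_out * out_dt - 1e-12) {
        grid(p, next_out) = k2;
        ++next_out;
      }
    }
    while (next_out <= n_out) { grid(p, next_out) = k2; ++next_out; }
    pmean[p] = k2_int / duration;
    if (p % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["path_mean"] = pmean, _["grid"] = grid,
                      _["out_dt"] = out_dt);
}
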