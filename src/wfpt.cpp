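// Wiener first-passage-time core for the two-bound diffusion model.
//
// Conventions: the process starts at relative position w = z/a in (0,1),
// drifts at rate v with within-trial noise SD s, and is absorbed at the
// upper bound (a) or lower bound (0).  All times are total RTs in seconds;
// the decision clock starts after the non-decision time ter.  Densities are
// "defective": each bound's density integrates to that bound's choice
// probability, not 1.
//
// Internally everything is rescaled to s = 1 (a' = a/s, v' = v/s), which
// leaves first-passage times and choice probabilities unchanged.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double WFPT_EPS = 1e-10;

// Density of the standard process (v = 0, a = 1, start w) hitting the lower
// bound at decision time u, via the better-converging of the small-time and
// large-time series (Navarro & Fuss 2009 style term-count selection).
static double f01_lower(double u, double w, double err = 1e-8) {
  if (u <= 0.0) return 0.0;

  // required terms, small-time representation
  double ks = 2.0;
  if (M_PI * u * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * std::sqrt(2.0 * M_PI * u) * err));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  }
  // required terms, large-time representation
  double kl = 1.0 / (M_PI * std::sqrt(u));
  if (M_PI * u * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * err) / (M_PI * M_PI * u));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(u)));
  }

  double f = 0.0;
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    for (int k = -(K - 1) / 2; k <= K / 2; k++) {
      double wk = w + 2.0 * k;
      f += wk * std::exp(-wk * wk / (2.0 * u));
    }
    f /= std::sqrt(2.0 * M_PI * u * u * u);
  } else {
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; k++) {
      f += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) * std::sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return f > 0.0 ? f : 0.0;
}

// Defective density of hitting the LOWER bound at decision time u,
// general (a, w, v), s = 1.
static double flower(double u, double a, double w, double v) {
  if (u <= 0.0) return 0.0;
  double scaled = f01_lower(u / (a * a), w) / (a * a);
  return std::exp(-v * a * w - v * v * u / 2.0) * scaled;
}

// density at total time t on the requested bound (upper = true/false)
static double dwfpt_one(double t, bool upper, double a, double w,
                        double ter, double v, double s) {
  double u = t - ter;
  if (u <= 0.0) return 0.0;
  double as = a / s, vs = v / s;
  if (upper) return flower(u, as, 1.0 - w, -vs);
  return flower(u, as, w, vs);
}

// P(absorb at upper bound): (1 - exp(-2 v a w / s^2)) / (1 - exp(-2 v a / s^2))
static double p_upper(double a, double w, double v, double s) {
  double as = a / s, vs = v / s;
  double x = 2.0 * vs * as;
  if (std::fabs(x) < 1e-9) return w;  // v -> 0 limit
  return std::expm1(-x * w) / std::expm1(-x);
}

// Defective CDF at decision time u of the LOWER bound (a, w, v; s = 1).
// Tail of the large-time series integrated term-by-term; falls back to
// Gauss-Legendre quadrature of the density when the series converges slowly.
static double gl64_lower(double u, double a, double w, double v);

static double plower(double u, double a, double w, double v) {
  if (u <= 0.0) return 0.0;
  double pl = 1.0 - p_upper(a * 1.0, w, v, 1.0); // s=1 here
  double ut = u / (a * a);
  if (ut < 0.02) return gl64_lower(u, a, w, v);
  double tail = 0.0;
  double pref = std::exp(-v * a * w);
  for (int k = 1; k <= 20000; k++) {
    double lam = v * v / 2.0 + k * k * M_PI * M_PI / (2.0 * a * a);
    double env = (M_PI * k / (a * a)) * std::exp(-lam * u) / lam;
    tail += env * std::sin(k * M_PI * w);
    // envelope bound is sign-independent (sin vanishes at even k for w=0.5)
    if (env < 1e-13 && k > 3) break;
  }
  double val = pl - pref * tail;
  if (val < 0.0) val = 0.0;
  if (val > pl) val = pl;
  return val;
}

// 64-node Gauss-Legendre on [0, u] of the lower-bound density (s = 1).
static double gl64_lower(double u, double a, double w, double v) {
  static const double gx[32] = {
    0.0243502926634244, 0.0729931217877990, 0.1214628192961206, 0.1696444204239928,
    0.2174236437400071, 0.2646871622087674, 0.3113228719902110, 0.3572201583376681,
    0.4022701579639916, 0.4463660172534641, 0.4894031457070530, 0.5312794640198946,
    0.5718956462026340, 0.6111553551723933, 0.6489654712546573, 0.6852363130542333,
    0.7198818501716109, 0.7528199072605319, 0.7839723589433414, 0.8132653151227975,
    0.8406292962525803, 0.8659993981540928, 0.8893154459951141, 0.9105221370785028,
    0.9295691721319396, 0.9464113748584028, 0.9610087996520538, 0.9733268277899110,
    0.9833362538846260, 0.9910133714767443, 0.9963401167719553, 0.9993050417357722 };
  static const double gw[32] = {
    0.0486909570091397, 0.0485754674415034, 0.0483447622348030, 0.0479993885964583,
    0.0475401657148303, 0.0469681828162100, 0.0462847965813144, 0.0454916279274181,
    0.0445905581637566, 0.0435837245293235, 0.0424735151236536, 0.0412625632426235,
    0.0399537411327203, 0.0385501531786156, 0.0370551285402400, 0.0354722132568824,
    0.0338051618371416, 0.0320579283548516, 0.0302346570724025, 0.0283396726142595,
    0.0263774697150547, 0.0243527025687109, 0.0222701738083833, 0.0201348231535302,
    0.0179517157756973, 0.0157260304760247, 0.0134630478967186, 0.0111681394601311,
    0.0088467598263639, 0.0065044579689784, 0.0041470332605625, 0.0017832807216964 };
  double c = u / 2.0, acc = 0.0;
  for (int i = 0; i < 32; i++) {
    acc += gw[i] * (flower(c * (1.0 - gx[i]), a, w, v) +
                    flower(c * (1.0 + gx[i]), a, w, v));
  }
  return acc * c;
}

static double pwfpt_one(double t, bool upper, double a, double w,
                        double ter, double v, double s) {
  double u = t - ter;
  if (u <= 0.0) return 0.0;
  double as = a / s, vs = v / s;
  if (upper) return plower(u, as, 1.0 - w, -vs);
  return plower(u, as, w, vs);
}

// [[Rcpp::export]]
NumericVector dwfpt_cpp(NumericVector t, bool upper, double a, double z_rel,
                        double ter, double v, double s) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++)
    out[i] = dwfpt_one(t[i], upper, a, z_rel, ter, v, s);
  return out;
}

// [[Rcpp::export]]
NumericVector pwfpt_cpp(NumericVector t, bool upper, double a, double z_rel,
                        double ter, double v, double s) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++)
    out[i] = pwfpt_one(t[i], upper, a, z_rel, ter, v, s);
  return out;
}

// [[Rcpp::export]]
double choice_prob_cpp(bool upper, double a, double z_rel, double v, double s) {
  double pu = p_upper(a, z_rel, v, s);
  return upper ? pu : 1.0 - pu;
}

// [[Rcpp::export]]
NumericVector swfpt_cpp(NumericVector t, double a, double z_rel, double ter,
                        double v, double s) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double sv = 1.0 - pwfpt_one(t[i], true, a, z_rel, ter, v, s)
                    - pwfpt_one(t[i], false, a, z_rel, ter, v, s);
    if (sv < 0.0) sv = 0.0;
    if (sv > 1.0) sv = 1.0;
    out[i] = sv;
  }
  return out;
}

// Euler-Maruyama first-passage simulator with Brownian-bridge crossing
// correction (catches boundary excursions between grid points).  Uses R's
// RNG so results are reproducible under set.seed().  Returns a matrix with
// columns (response, rt): response 1 = upper, 0 = lower, NA = timeout.
// [[Rcpp::export]]
NumericMatrix sim_wfpt_cpp(int n, double a, double z_rel, double ter,
                           NumericVector v, double s, double deadline,
                           double dt) {
  RNGScope scope;
  NumericMatrix out(n, 2);
  double sdt = s * std::sqrt(dt);
  double tmax = deadline - ter;
  for (int i = 0; i < n; i++) {
    double vi = v.size() == 1 ? v[0] : v[i];
    double x = z_rel * a, tdec = 0.0;
    int resp = NA_INTEGER;
    bool done = false;
    while (tdec < tmax) {
      double xn = x + vi * dt + sdt * norm_rand();
      tdec += dt;
      if (xn >= a) { resp = 1; done = true; }
      else if (xn <= 0.0) { resp = 0; done = true; }
      else {
        // bridge crossing probabilities within the step
        double pu = std::exp(-2.0 * (a - x) * (a - xn) / (s * s * dt));
        if (unif_rand() < pu) { resp = 1; done = true; }
        else {
          double plo = std::exp(-2.0 * x * xn / (s * s * dt));
          if (unif_rand() < plo) { resp = 0; done = true; }
        }
      }
      if (done) break;
      x = xn;
    }
    if (done && ter + tdec <= deadline) {
      out(i, 0) = resp;
      out(i, 1) = ter + tdec;
    } else {
      out(i, 0) = NA_REAL;
      out(i, 1) = NA_REAL;
    }
  }
  return out;
}

// Summed trial log-likelihood for one task's trials under one-or-more
// candidate subject parameter vectors (rows of `par`: a, z_rel, ter,
// v_mean, v_diff).  Trial covariates: difficulty (1 easy, 2 hard),
// dir_sign (+1 rightward, -1 leftward), response (1 right/upper,
// 0 left/lower, NA timeout), rt (total seconds, NA for timeout).
// Timeouts contribute log S(deadline); responded trials with rt <= ter
// contribute `penalty`.  Drift is signed by the stimulus: v = dir_sign *
// (v_mean +/- v_diff/2).
// [[Rcpp::export]]
NumericVector wfpt_loglik_cpp(NumericMatrix par, IntegerVector difficulty,
                              NumericVector dir_sign, NumericVector response,
                              NumericVector rt, double s, double deadline,
                              double penalty) {
  int m = par.nrow(), n = difficulty.size();
  NumericVector out(m);
  for (int j = 0; j < m; j++) {
    double a = par(j, 0), w = par(j, 1), ter = par(j, 2);
    double vmean = par(j, 3), vdiff = par(j, 4);
    double ll = 0.0;
    // survivor cache over (difficulty, direction): drift magnitude is all
    // that matters for S since S is symmetric in (v, w) <-> (-v, 1-w)? It
    // is not when w != 0.5, so cache the 4 signed combinations.
    double scache[4];
    bool shave[4] = {false, false, false, false};
    for (int i = 0; i < n; i++) {
      int d = difficulty[i];
      double vd = (d == 1) ? (vmean + vdiff / 2.0) : (vmean - vdiff / 2.0);
      double vtrial = dir_sign[i] * vd;
      if (NumericVector::is_na(response[i]) || NumericVector::is_na(rt[i])) {
        int key = (d - 1) * 2 + (dir_sign[i] > 0 ? 1 : 0);
        if (!shave[key]) {
          double sv = 1.0 - pwfpt_one(deadline, true, a, w, ter, vtrial, s)
                          - pwfpt_one(deadline, false, a, w, ter, vtrial, s);
          if (sv < WFPT_EPS) sv = WFPT_EPS;
          scache[key] = std::log(sv);
          shave[key] = true;
        }
        ll += scache[key];
      } else {
        if (rt[i] <= ter) { ll += penalty; continue; }
        double f = dwfpt_one(rt[i], response[i] > 0.5, a, w, ter, vtrial, s);
        ll += (f > WFPT_EPS * 1e-20) ? std::log(f) : penalty;
      }
    }
    out[j] = ll;
  }
  return out;
}
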