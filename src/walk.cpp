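#include <Rcpp.h>
using namespace Rcpp;

// Gaussian fitness w = exp(-omega * (o - z)^2)
static inline double gauss_fitness(double z, double o, double omega) {
  double d = o - z;
  return std::exp(-omega * d * d);
}

// Kimura fixation probability, effectively infinite population:
// 1 - exp(-2s) for s > 0, else 0.
static inline double pi_infinite(double s) {
  return (s > 0.0) ? -std::expm1(-2.0 * s) : 0.0;
}

// Kimura fixation probability for population size N:
// (1 - exp(-2s)) / (1 - exp(-4Ns)), limit 1/(2N) at s = 0.
static inline double pi_finite(double s, double N) {
  double x = 4.0 * N * s;
  if (std::fabs(x) < 1e-8) return 1.0 / (2.0 * N);
  if (s > 0.0) return std::expm1(-2.0 * s) / std::expm1(-x);
  double a = -2.0 * s, b = -x; // both positive for s < 0
  if (b < 700.0) return std::expm1(a) / std::expm1(b);
  // expm1(b) would overflow; use expm1(a)/expm1(b) ~ exp(a-b)*(1-exp(-a))
  return std::exp(a - b) * (-std::expm1(-a));
}

// N < 0 encodes an infinite population
static inline double pfix(double s, double N) {
  return (N < 0.0) ? pi_infinite(s) : pi_finite(s, N);
}

// Mutation effect draw. dist: 0 = normal, 1 = uniform, 2 = exponential.
// All three are symmetric about zero with E|m| = sigma * sqrt(2/pi).
static inline double draw_effect_raw(int dist, double sigma) {
  double mbar, mag, u;
  switch (dist) {
  case 0:
    return R::rnorm(0.0, sigma);
  case 1:
    mbar = sigma * std::sqrt(2.0 / M_PI);
    return R::runif(-2.0 * mbar, 2.0 * mbar); // E|U(-b,b)| = b/2
  case 2:
    mbar = sigma * std::sqrt(2.0 / M_PI);
    mag = R::exp_rand() * mbar;
    u = R::unif_rand();
    return (u < 0.5) ? mag : -mag;
  default:
    stop("unknown mutation distribution code");
  }
  return 0.0; // not reached
}

// One proposal-resolution round for a party with current fitness w at z.
// Consumes one effect draw and one uniform; returns the event and updates
// z/w via references.
struct Event {
  double effect, s, z_after;
  bool fixed;
};

static inline Event propose_round(double &z, double &w, double o, double omega,
                                  double sigma, int dist, double N) {
  if (w <= 0.0)
    stop("current fitness underflowed to zero; selection coefficient undefined");
  Event ev;
  ev.effect = draw_effect_raw(dist, sigma);
  double wm = gauss_fitness(z + ev.effect, o, omega);
  ev.s = wm / w - 1.0;
  double u = R::unif_rand();
  ev.fixed = (u < pfix(ev.s, N));
  if (ev.fixed) {
    z += ev.effect;
    w = wm;
  }
  ev.z_after = z;
  return ev;
}

// [[Rcpp::export]]
List cpp_walk_standard(int n_iter, double z0, double o1, double omega,
                       double sigma, int dist, double N) {
  IntegerVector iteration(n_iter);
  NumericVector effect(n_iter), s(n_iter), z_after(n_iter), w1_after(n_iter);
  LogicalVector fixed(n_iter);
  double z = z0, w = gauss_fitness(z, o1, omega);
  for (int t = 0; t < n_iter; ++t) {
    Event ev = propose_round(z, w, o1, omega, sigma, dist, N);
    iteration[t] = t + 1;
    effect[t] = ev.effect;
    s[t] = ev.s;
    fixed[t] = ev.fixed;
    z_after[t] = z;
    w1_after[t] = w;
  }
  return List::create(_["iteration"] = iteration, _["effect"] = effect,
                      _["s"] = s, _["fixed"] = fixed, _["z_after"] = z_after,
                      _["w1_after"] = w1_after);
}

// [[Rcpp::export]]
List cpp_walk_conflict(int n_iter, double z0, double o1, double o2,
                       double omega1, double omega2, double sigma1,
                       double sigma2, int dist, double N1, double N2, int r) {
  int per_iter = r + 1, n = n_iter * per_iter;
  IntegerVector iteration(n), party(n);
  NumericVector effect(n), s(n), z_after(n), w1_after(n), w2_after(n);
  LogicalVector fixed(n);
  double z = z0;
  double w1 = gauss_fitness(z, o1, omega1);
  double w2 = gauss_fitness(z, o2, omega2);
  int k = 0;
  for (int t = 0; t < n_iter; ++t) {
    bool party1_first = (R::unif_rand() < 0.5);
    for (int block = 0; block < 2; ++block) {
      bool p1_block = (block == 0) ? party1_first : !party1_first;
      int rounds = p1_block ? r : 1;
      for (int j = 0; j < rounds; ++j) {
        Event ev;
        if (p1_block) {
          ev = propose_round(z, w1, o1, omega1, sigma1, dist, N1);
          w2 = gauss_fitness(z, o2, omega2);
        } else {
          ev = propose_round(z, w2, o2, omega2, sigma2, dist, N2);
          w1 = gauss_fitness(z, o1, omega1);
        }
        iteration[k] = t + 1;
        party[k] = p1_block ? 1 : 2;
        effect[k] = ev.effect;
        s[k] = ev.s;
        fixed[k] = ev.fixed;
        z_after[k] = z;
        w1_after[k] = w1;
        w2_after[k] = w2;
        ++k;
      }
    }
  }
  return List::create(_["iteration"] = iteration, _["party"] = party,
                      _["effect"] = effect, _["s"] = s, _["fixed"] = fixed,
                      _["z_after"] = z_after, _["w1_after"] = w1_after,
                      _["w2_after"] = w2_after);
}

// Moving-optimum walk paired to a conflict run: at the start of iteration t
// the optimum is displaced by delta[t] (the magnitude of the opponent's net
// change to z in the paired run) in a coin-flip direction, then the focal
// party performs r proposal rounds. No coin is consumed when delta[t] == 0.
// [[Rcpp::export]]
List cpp_walk_abiotic(int n_iter, double z0, double o1_init, double omega,
                      double sigma, int dist, double N, int r,
                      NumericVector delta) {
  if (delta.size() != n_iter)
    stop("paired displacement vector length must equal n_iter");
  int n = n_iter * r;
  IntegerVector iteration(n);
  NumericVector effect(n), s(n), z_after(n), o1_after(n), w1_after(n);
  LogicalVector fixed(n);
  double z = z0, o1 = o1_init;
  double w = gauss_fitness(z, o1, omega);
  int k = 0;
  for (int t = 0; t < n_iter; ++t) {
    double d = delta[t];
    if (d < 0.0) stop("displacement magnitudes must be nonnegative");
    if (d > 0.0) {
      double u = R::unif_rand();
      o1 += (u < 0.5) ? d : -d;
      w = gauss_fitness(z, o1, omega);
    }
    for (int j = 0; j < r; ++j) {
      Event ev = propose_round(z, w, o1, omega, sigma, dist, N);
      iteration[k] = t + 1;
      effect[k] = ev.effect;
      s[k] = ev.s;
      fixed[k] = ev.fixed;
      z_after[k] = z;
      o1_after[k] = o1;
      w1_after[k] = w;
      ++k;
    }
  }
  return List::create(_["iteration"] = iteration, _["effect"] = effect,
                      _["s"] = s, _["fixed"] = fixed, _["z_after"] = z_after,
                      _["o1_after"] = o1_after, _["w1_after"] = w1_after);
}
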