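// Fast explicit-Euler core for the hypocotyl auxin transport / growth model.
// The pure-R step() path in R/dynamics.R implements the same update; a test
// asserts bitwise-level agreement between the two engines.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Regime {
  double par;          // fluence rate during the light phase (uE)
  double light_hours;  // 24 = continuous, 16 = long day
  double fr_onset_h;   // hours since germination; R_PosInf = never (white)
};

inline double par_at(const Regime& rg, double t) {
  if (rg.light_hours >= 24.0) return rg.par;
  double tod = t - 24.0 * std::floor(t / 24.0);
  return (tod < rg.light_hours) ? rg.par : 0.0;
}

// closed-form integral of the piecewise-constant PAR schedule
inline double cumlight_at(const Regime& rg, double t) {
  if (rg.light_hours >= 24.0) return rg.par * t;
  double days = std::floor(t / 24.0);
  double tod = t - 24.0 * days;
  return rg.par * (days * rg.light_hours + std::min(tod, rg.light_hours));
}

inline double sigmoid_f(double x, double u, double a, bool clamp) {
  double d = x - u;
  if (clamp && d < 0.0) d = 0.0;
  double d2 = d * d;
  return d2 / (a + d2);
}

inline double monod_f(double x, double u, double b, bool clamp) {
  double d = x - u;
  if (clamp && d < 0.0) d = 0.0;
  return d / (b + d);
}

// relative phytochrome signal: 1 before FR onset, first-order decay
// (half-life 30 min) to the residual plateau eps afterwards
inline double ifr_at(double t, double onset, double eps, double ifrmax) {
  if (!(t >= onset)) return 1.0;
  double s = t - onset;
  double s_star = -std::log2(eps) / 2.0;
  if (s <= s_star) return ifrmax * std::pow(2.0, -2.0 * s);
  return eps * ifrmax;
}

}  // namespace

// [[Rcpp::export]]
List sim_core_cpp(NumericMatrix q0, NumericVector l0vec, double t0,
                  int n_steps, double dt, int save_stride,
                  List pars, List regime, List geno,
                  NumericVector ledger0, bool root_closed) {
  const int L = q0.nrow();        // layers, 1 = epidermis ... L = endodermis
  const int R = q0.ncol();        // rows, last = root compartment
  const int RH = R - 1;           // hypocotyl rows

  const double lambda = pars["lambda_growth"];
  const double u_mu   = pars["u_mu"];
  const double a1     = pars["a1"];
  const double mu     = pars["mu_input"];
  const double Ic0    = pars["I_c0"];
  const double u_c    = pars["u_c"];
  const double b1     = pars["b1"];
  const double beta   = pars["beta"];
  const double u_fr   = pars["u_fr"];
  const double a2     = pars["a2"];
  const double ifrmax = pars["I_fr_max"];
  const double eps    = pars["epsilon"];
  const double eta    = pars["eta"];
  const double u_I    = pars["u_I"];
  const double a3     = pars["a3"];
  const double Pnp    = pars["P_np"];
  const double Ppb    = pars["P_polar_bottom"];
  const double Ppo    = pars["P_polar_out"];
  const double l0     = pars["l0"];
  const bool clamp    = pars["clamp_regulatory"];
  const bool on_conc  = pars["transport_on_concentration"];

  const double g_syn = geno["synthesis_factor"];
  const double g_np  = geno["nonpolar_factor"];
  const double g_pol = geno["polar_factor"];
  const double g_in  = geno["input_factor"];

  Regime rg;
  rg.par = regime["par_intensity"];
  rg.light_hours = regime["light_hours"];
  rg.fr_onset_h = regime["fr_onset_h"];

  // face permeabilities (identical for every cell; assumption of constant P)
  const double P_bot = g_np * Pnp + g_pol * Ppb;
  const double P_top = g_np * Pnp;
  const double P_out = g_np * Pnp + g_pol * Ppo;
  const double P_in  = g_np * Pnp;

  NumericMatrix q(clone(q0));
  NumericVector l(clone(l0vec));  // hypocotyl rows only; root length fixed l0

  double cum_input = ledger0[0];
  double cum_deg   = ledger0[1];
  double cum_root  = ledger0[2];
  double clip_total = 0.0;

  const int n_save = n_steps / save_stride + 1 +
                     ((n_steps % save_stride) ? 1 : 0);
  NumericVector save_t(n_save);
  NumericMatrix save_l(n_save, RH);
  NumericVector save_q(static_cast<R_xlen_t>(n_save) * L * R);
  NumericMatrix ledger(n_save, 5);  // t, input, degraded, root, total_q
  int isave = 0;

  std::vector<double> rate(static_cast<size_t>(L) * R);
  std::vector<double> growth(RH);

  double t = t0;
  for (int step = 0; step <= n_steps; ++step) {
    if (step % save_stride == 0 || step == n_steps) {
      save_t[isave] = t;
      double tot = 0.0;
      for (int r = 0; r < RH; ++r) {
        save_l(isave, r) = l[r];
        for (int ly = 0; ly < L; ++ly) tot += q(ly, r);
      }
      for (int r = 0; r < R; ++r)
        for (int ly = 0; ly < L; ++ly)
          save_q[static_cast<R_xlen_t>(isave) * L * R + r * L + ly] = q(ly, r);
      ledger(isave, 0) = t;
      ledger(isave, 1) = cum_input;
      ledger(isave, 2) = cum_deg;
      ledger(isave, 3) = cum_root;
      ledger(isave, 4) = tot;
      ++isave;
    }
    if (step == n_steps) break;

    const double I = par_at(rg, t);
    const double S3 = sigmoid_f(I, u_I, a3, clamp);
    const double ifr = ifr_at(t, rg.fr_onset_h, eps, ifrmax);
    const double alpha = 1.0 - sigmoid_f(beta * ifr, u_fr, a2, clamp);
    const double input_rate =
        g_in * g_syn * mu * alpha *
        monod_f(Ic0 + cumlight_at(rg, t), u_c, b1, clamp);

    std::fill(rate.begin(), rate.end(), 0.0);
    double deg_rate_tot = 0.0, root_rate = 0.0;

    for (int r = 0; r < RH; ++r) {
      const double lr = l[r];
      for (int ly = 0; ly < L; ++ly) {
        const double qd = on_conc ? q(ly, r) / lr : q(ly, r);
        const size_t i = static_cast<size_t>(r) * L + ly;
        // bottom face (toward root); closed only if root_closed at row RH-1
        if (!(root_closed && r == RH - 1)) {
          const double f = P_bot * qd;
          rate[i] -= f;
          rate[i + L] += f;
          if (r == RH - 1) root_rate += f;
        }
        if (r > 0) {  // top face
          const double f = P_top * qd;
          rate[i] -= f;
          rate[i - L] += f;
        }
        if (ly > 0) {  // outward face (toward epidermis)
          const double f = P_out * qd;
          rate[i] -= f;
          rate[i - 1] += f;
        }
        if (ly < L - 1) {  // inward face (toward endodermis)
          const double f = P_in * qd;
          rate[i] -= f;
          rate[i + 1] += f;
        }
        // degradation, proportional to concentration and light
        const double dg = eta * (q(ly, r) / lr) * S3;
        rate[i] -= dg;
        deg_rate_tot += dg;
      }
    }
    // root row: pure sink, no outflow, no degradation, no growth

    // growth from the pre-step state; only epidermal concentration matters
    for (int r = 0; r < RH; ++r)
      growth[r] = lambda * sigmoid_f(q(0, r) / l[r], u_mu, a1, clamp);

    // Euler update
    for (int r = 0; r < R; ++r)
      for (int ly = 0; ly < L; ++ly) {
        const size_t i = static_cast<size_t>(r) * L + ly;
        double qn = q(ly, r) + dt * rate[i];
        if (ly == L - 1 && r == 0) qn += dt * input_rate;
        if (qn < 0.0) {
          clip_total += -qn;
          qn = 0.0;
        }
        q(ly, r) = qn;
      }
    for (int r = 0; r < RH; ++r) l[r] += dt * growth[r];

    cum_input += dt * input_rate;
    cum_deg += dt * deg_rate_tot;
    cum_root += dt * root_rate;
    t = t0 + (step + 1) * dt;
  }

  return List::create(
      _["q"] = q, _["l"] = l, _["t"] = t,
      _["save_t"] = save_t[Range(0, isave - 1)],
      _["save_l"] = save_l(Range(0, isave - 1), _),
      _["save_q"] = save_q, _["n_save"] = isave,
      _["ledger"] = ledger(Range(0, isave - 1), _),
      _["cum_input"] = cum_input, _["cum_deg"] = cum_deg,
      _["cum_root"] = cum_root, _["clip_total"] = clip_total);
}
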