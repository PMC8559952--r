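#include <Rcpp.h>
using namespace Rcpp;

// Trial log-likelihood core shared by both model families.
// choice coding: 0 = default, 1 = alternative (missing removed upstream).
// family: 1 = stable (softmax on value difference, variability = tau),
//         2 = variable (random preference probit, variability = sigma).
static double phase_ll(const NumericVector &py, const NumericVector &po,
                       const IntegerVector &ch, double mu_deg, double vari,
                       double kappa, double eps, int family) {
  const int n = py.size();
  double ll = 0.0;
  const double tanmu = std::tan(mu_deg * M_PI / 180.0);
  for (int t = 0; t < n; ++t) {
    double pD;
    if (family == 1) {
      double dv = (100.0 - kappa - py[t]) + tanmu * (50.0 - po[t]);
      pD = 1.0 / (1.0 + std::exp(-dv / vari));
    } else {
      if (po[t] == 50.0) {
        double adv = py[t] - 100.0 + kappa;
        pD = adv > 0 ? 0.0 : (adv < 0 ? 1.0 : 0.5);
      } else {
        double ta = std::atan((py[t] - 100.0 + kappa) / (50.0 - po[t])) *
                    180.0 / M_PI;
        double z = (ta - mu_deg) / vari;
        if (po[t] < 50.0) z = -z;
        pD = R::pnorm(z, 0.0, 1.0, 1, 0);
      }
    }
    double p = (1.0 - eps) * pD + eps / 2.0;
    double pobs = (ch[t] == 0) ? p : 1.0 - p;
    if (pobs < 1e-300) pobs = 1e-300;
    ll += std::log(pobs);
  }
  return ll;
}

// Exposed for the single-source-of-truth check against the R reference
// implementation (natural-scale parameters).
// [[Rcpp::export]]
double phase_loglik_cpp(NumericVector pi_self, NumericVector pi_other,
                        IntegerVector choice, double attitude,
                        double variability, double bias_kappa,
                        double lapse_epsilon, int family) {
  return phase_ll(pi_self, pi_other, choice, attitude, variability,
                  bias_kappa, lapse_epsilon, family);
}

static inline double nat_eps(double eta) {
  return 0.5 / (1.0 + std::exp(-eta));
}

// One Metropolis-within-Gibbs sweep over all subjects and subject-level
// parameter components. theta columns (sampling scale):
//   0 mu_before, 1 mu_after, 2 log(var)_before, 3 log(var)_after,
//   4 kappa_before, 5 kappa_after, 6 logit(eps/0.5)_before, 7 ..._after.
// scheme: 0 full, 1 shared attitude (col 1 mirrors 0), 2 shared
// variability (col 3 mirrors 2). Tied components are updated once against
// both phases and mirrored. theta, cur_ll and acc are updated in place.
// [[Rcpp::export]]
void subject_sweep_cpp(List subj, NumericMatrix theta, NumericVector gm,
                       NumericVector gs, NumericMatrix prop_sd, int family,
                       int scheme, NumericMatrix cur_ll, IntegerMatrix acc) {
  const int n = subj.size();
  for (int i = 0; i < n; ++i) {
    List s = subj[i];
    NumericVector pyb = s["py_before"], pob = s["po_before"];
    IntegerVector chb = s["ch_before"];
    NumericVector pya = s["py_after"], poa = s["po_after"];
    IntegerVector cha = s["ch_after"];
    for (int j = 0; j < 8; ++j) {
      if (scheme == 1 && j == 1) continue;  // mirrored attitude column
      if (scheme == 2 && j == 3) continue;  // mirrored variability column
      bool tied = (scheme == 1 && j == 0) || (scheme == 2 && j == 2);
      double cur = theta(i, j);
      double prop = cur + R::rnorm(0.0, prop_sd(i, j));
      if ((j == 0 || j == 1) && std::fabs(prop) >= 89.999) continue;
      bool bef = tied || j == 0 || j == 2 || j == 4 || j == 6;
      bool aft = tied || j == 1 || j == 3 || j == 5 || j == 7;
      double save = theta(i, j);
      theta(i, j) = prop;
      if (tied) theta(i, j + 1) = prop;
      double ll_b_new = cur_ll(i, 0), ll_a_new = cur_ll(i, 1);
      if (bef && pyb.size() > 0)
        ll_b_new = phase_ll(pyb, pob, chb, theta(i, 0),
                            std::exp(theta(i, 2)), theta(i, 4),
                            nat_eps(theta(i, 6)), family);
      if (aft && pya.size() > 0)
        ll_a_new = phase_ll(pya, poa, cha, theta(i, 1),
                            std::exp(theta(i, 3)), theta(i, 5),
                            nat_eps(theta(i, 7)), family);
      double logr = (ll_b_new - cur_ll(i, 0)) + (ll_a_new - cur_ll(i, 1)) +
                    R::dnorm(prop, gm[j], gs[j], 1) -
                    R::dnorm(cur, gm[j], gs[j], 1);
      if (std::log(R::runif(0.0, 1.0)) < logr) {
        cur_ll(i, 0) = ll_b_new;
        cur_ll(i, 1) = ll_a_new;
        acc(i, j) += 1;
      } else {
        theta(i, j) = save;
        if (tied) theta(i, j + 1) = save;
      }
    }
  }
}

// Per-subject per-phase log-likelihoods at given parameters (n x 2).
// [[Rcpp::export]]
NumericMatrix all_phase_ll_cpp(List subj, NumericMatrix theta, int family) {
  const int n = subj.size();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    List s = subj[i];
    NumericVector pyb = s["py_before"], pob = s["po_before"];
    IntegerVector chb = s["ch_before"];
    NumericVector pya = s["py_after"], poa = s["po_after"];
    IntegerVector cha = s["ch_after"];
    if (pyb.size() > 0)
      out(i, 0) = phase_ll(pyb, pob, chb, theta(i, 0), std::exp(theta(i, 2)),
                           theta(i, 4), nat_eps(theta(i, 6)), family);
    if (pya.size() > 0)
      out(i, 1) = phase_ll(pya, poa, cha, theta(i, 1), std::exp(theta(i, 3)),
                           theta(i, 5), nat_eps(theta(i, 7)), family);
  }
  return out;
}

// Total log-likelihood over subjects at given subject-level parameters
// (sampling scale), used for the DIC plug-in deviance.
// [[Rcpp::export]]
double total_loglik_cpp(List subj, NumericMatrix theta, int family) {
  const int n = subj.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    List s = subj[i];
    NumericVector pyb = s["py_before"], pob = s["po_before"];
    IntegerVector chb = s["ch_before"];
    NumericVector pya = s["py_after"], poa = s["po_after"];
    IntegerVector cha = s["ch_after"];
    if (pyb.size() > 0)
      ll += phase_ll(pyb, pob, chb, theta(i, 0), std::exp(theta(i, 2)),
                     theta(i, 4), nat_eps(theta(i, 6)), family);
    if (pya.size() > 0)
      ll += phase_ll(pya, poa, cha, theta(i, 1), std::exp(theta(i, 3)),
                     theta(i, 5), nat_eps(theta(i, 7)), family);
  }
  return ll;
}
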