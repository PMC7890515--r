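// Joint log posterior and analytic gradient of the hierarchical graded
// response model on the unconstrained scale, evaluated in one pass over the
// observations. Parameter packing (must match the R side in grm-fit.R):
//   beta[K], tau_raw[3], [delta0], [theta_raw[J]],
//   [zb_photo[I], (zd_photo[I]), log_sd_pb, (log_sd_pd, rho_raw_p)],
//   [zb_species[S], (zd_species[S]), log_sd_sb, (log_sd_sd, rho_raw_s)]
// Bracketed blocks are present only when the corresponding flag is set;
// parenthesised sub-blocks only when discrimination is modelled.
// Transforms: tau ordered via first element + exp increments; sds via exp;
// correlations via tanh; photo/species pairs are non-centered.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x >= 0.0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

static inline double log_sigmoid(double x) {
  if (x > 0.0) return -std::log1p(std::exp(-x));
  return x - std::log1p(std::exp(x));
}

// log(sigmoid(cu) - sigmoid(cl)) for cu > cl, stable for extreme arguments:
// = log sig(cu) + log sig(-cl) + log(1 - exp(cl - cu))
static inline double log_sigmoid_diff(double cu, double cl) {
  double d = cu - cl;
  double tail = (d > 1e-10) ? std::log(-std::expm1(-d)) : std::log(d);
  return log_sigmoid(cu) + log_sigmoid(-cl) + tail;
}

// [[Rcpp::export]]
List grm_lp_grad(NumericVector q, IntegerVector y, NumericMatrix X,
                 IntegerVector pid, IntegerVector ph, IntegerVector sp,
                 int J, int I, int S,
                 bool has_participant, bool has_photo, bool has_species,
                 bool has_disc, double sd_participant,
                 double beta_sd, double tau_sd, double delta0_sd,
                 double sd_scale, double lkj_eta) {
  const int N = y.size();
  const int K = X.ncol();
  const double *Q = q.begin();
  int pos = 0;

  const double *beta = Q + pos; pos += K;
  const double *tr = Q + pos; pos += 3;
  const int i_delta0 = has_disc ? pos : -1;
  const double delta0 = has_disc ? Q[pos++] : 0.0;
  const int i_theta = has_participant ? pos : -1;
  const double *theta_raw = has_participant ? Q + pos : NULL;
  if (has_participant) pos += J;

  int i_zbp = -1, i_zdp = -1, i_lspb = -1, i_lspd = -1, i_rrp = -1;
  double sd_pb = 0, sd_pd = 0, rho_p = 0, c_p = 1;
  const double *zbp = NULL, *zdp = NULL;
  if (has_photo) {
    i_zbp = pos; zbp = Q + pos; pos += I;
    if (has_disc) { i_zdp = pos; zdp = Q + pos; pos += I; }
    i_lspb = pos; sd_pb = std::exp(Q[pos++]);
    if (has_disc) {
      i_lspd = pos; sd_pd = std::exp(Q[pos++]);
      i_rrp = pos; rho_p = std::tanh(Q[pos++]);
      c_p = std::sqrt(std::max(1.0 - rho_p * rho_p, 1e-12));
    }
  }
  int i_zbs = -1, i_zds = -1, i_lssb = -1, i_lssd = -1, i_rrs = -1;
  double sd_sb = 0, sd_sd = 0, rho_s = 0, c_s = 1;
  const double *zbs = NULL, *zds = NULL;
  if (has_species) {
    i_zbs = pos; zbs = Q + pos; pos += S;
    if (has_disc) { i_zds = pos; zds = Q + pos; pos += S; }
    i_lssb = pos; sd_sb = std::exp(Q[pos++]);
    if (has_disc) {
      i_lssd = pos; sd_sd = std::exp(Q[pos++]);
      i_rrs = pos; rho_s = std::tanh(Q[pos++]);
      c_s = std::sqrt(std::max(1.0 - rho_s * rho_s, 1e-12));
    }
  }
  if (pos != q.size()) stop("parameter vector has wrong length");

  double tau[3];
  const double e1 = std::exp(tr[1]), e2 = std::exp(tr[2]);
  tau[0] = tr[0]; tau[1] = tau[0] + e1; tau[2] = tau[1] + e2;

  std::vector<double> b_p, d_p, b_s, d_s;
  if (has_photo) {
    b_p.resize(I); d_p.assign(I, 0.0);
    for (int i = 0; i < I; ++i) {
      b_p[i] = sd_pb * zbp[i];
      if (has_disc) d_p[i] = sd_pd * (rho_p * zbp[i] + c_p * zdp[i]);
    }
  }
  if (has_species) {
    b_s.resize(S); d_s.assign(S, 0.0);
    for (int s = 0; s < S; ++s) {
      b_s[s] = sd_sb * zbs[s];
      if (has_disc) d_s[s] = sd_sd * (rho_s * zbs[s] + c_s * zds[s]);
    }
  }

  NumericVector grad(q.size());
  double *G = grad.begin();
  double lp = 0.0;
  double dtau[3] = {0.0, 0.0, 0.0};

  for (int n = 0; n < N; ++n) {
    double eta = 0.0;
    for (int k = 0; k < K; ++k) eta += X(n, k) * beta[k];
    int jp = 0, ip = 0, is = 0;
    if (has_participant) { jp = pid[n] - 1; eta += sd_participant * theta_raw[jp]; }
    if (has_photo) { ip = ph[n] - 1; eta += b_p[ip]; }
    if (has_species) { is = sp[n] - 1; eta += b_s[is]; }
    double la = delta0;
    if (has_disc && has_photo) la += d_p[ip];
    if (has_disc && has_species) la += d_s[is];
    const double a = has_disc ? std::exp(la) : 1.0;

    const double c1 = a * (tau[0] - eta);
    const double c2 = a * (tau[1] - eta);
    const double c3 = a * (tau[2] - eta);

    double deta = 0.0, dla = 0.0;
    switch (y[n]) {
    case 0: {
      lp += log_sigmoid(c1);
      const double s1 = sigmoid(-c1);
      dtau[0] += a * s1; deta -= a * s1; dla += c1 * s1;
      break;
    }
    case 3: {
      lp += log_sigmoid(-c3);
      const double s3 = sigmoid(c3);
      dtau[2] -= a * s3; deta += a * s3; dla -= c3 * s3;
      break;
    }
    case 1: {
      const double logP = log_sigmoid_diff(c2, c1);
      lp += logP;
      const double ru = std::exp(log_sigmoid(c2) + log_sigmoid(-c2) - logP);
      const double rl = std::exp(log_sigmoid(c1) + log_sigmoid(-c1) - logP);
      dtau[1] += a * ru; dtau[0] -= a * rl;
      deta -= a * (ru - rl); dla += c2 * ru - c1 * rl;
      break;
    }
    case 2: {
      const double logP = log_sigmoid_diff(c3, c2);
      lp += logP;
      const double ru = std::exp(log_sigmoid(c3) + log_sigmoid(-c3) - logP);
      const double rl = std::exp(log_sigmoid(c2) + log_sigmoid(-c2) - logP);
      dtau[2] += a * ru; dtau[1] -= a * rl;
      deta -= a * (ru - rl); dla += c3 * ru - c2 * rl;
      break;
    }
    default:
      stop("scores must be integers in 0..3");
    }

    for (int k = 0; k < K; ++k) G[k] += deta * X(n, k);
    if (has_participant) G[i_theta + jp] += deta * sd_participant;
    if (has_photo) {
      G[i_zbp + ip] += deta * sd_pb;
      G[i_lspb] += deta * b_p[ip];
      if (has_disc) {
        G[i_zbp + ip] += dla * sd_pd * rho_p;
        G[i_zdp + ip] += dla * sd_pd * c_p;
        G[i_lspd] += dla * d_p[ip];
        G[i_rrp] += dla * sd_pd * (zbp[ip] - rho_p / c_p * zdp[ip]) *
          (1.0 - rho_p * rho_p);
      }
    }
    if (has_species) {
      G[i_zbs + is] += deta * sd_sb;
      G[i_lssb] += deta * b_s[is];
      if (has_disc) {
        G[i_zbs + is] += dla * sd_sd * rho_s;
        G[i_zds + is] += dla * sd_sd * c_s;
        G[i_lssd] += dla * d_s[is];
        G[i_rrs] += dla * sd_sd * (zbs[is] - rho_s / c_s * zds[is]) *
          (1.0 - rho_s * rho_s);
      }
    }
    if (has_disc) G[i_delta0] += dla;
  }

  // priors and transform jacobians
  for (int k = 0; k < K; ++k) {
    lp += -0.5 * beta[k] * beta[k] / (beta_sd * beta_sd);
    G[k] += -beta[k] / (beta_sd * beta_sd);
  }
  for (int k = 0; k < 3; ++k) {
    lp += -0.5 * tau[k] * tau[k] / (tau_sd * tau_sd);
    dtau[k] += -tau[k] / (tau_sd * tau_sd);
  }
  lp += tr[1] + tr[2];  // jacobian of the ordered transform
  G[K] += dtau[0] + dtau[1] + dtau[2];
  G[K + 1] += (dtau[1] + dtau[2]) * e1 + 1.0;
  G[K + 2] += dtau[2] * e2 + 1.0;
  if (has_disc) {
    lp += -0.5 * delta0 * delta0 / (delta0_sd * delta0_sd);
    G[i_delta0] += -delta0 / (delta0_sd * delta0_sd);
  }
  if (has_participant) {
    for (int j = 0; j < J; ++j) {
      lp += -0.5 * theta_raw[j] * theta_raw[j];
      G[i_theta + j] += -theta_raw[j];
    }
  }
  // z ~ N(0,1); sd ~ half-Normal(0, sd_scale) with log-transform jacobian;
  // rho ~ LKJ(eta) for a 2x2 correlation with tanh jacobian
  if (has_photo) {
    for (int i = 0; i < I; ++i) {
      lp += -0.5 * zbp[i] * zbp[i]; G[i_zbp + i] += -zbp[i];
      if (has_disc) { lp += -0.5 * zdp[i] * zdp[i]; G[i_zdp + i] += -zdp[i]; }
    }
    lp += -0.5 * sd_pb * sd_pb / (sd_scale * sd_scale) + Q[i_lspb];
    G[i_lspb] += -sd_pb * sd_pb / (sd_scale * sd_scale) + 1.0;
    if (has_disc) {
      lp += -0.5 * sd_pd * sd_pd / (sd_scale * sd_scale) + Q[i_lspd];
      G[i_lspd] += -sd_pd * sd_pd / (sd_scale * sd_scale) + 1.0;
      lp += lkj_eta * std::log1p(-rho_p * rho_p);
      G[i_rrp] += -2.0 * lkj_eta * rho_p;
    }
  }
  if (has_species) {
    for (int s = 0; s < S; ++s) {
      lp += -0.5 * zbs[s] * zbs[s]; G[i_zbs + s] += -zbs[s];
      if (has_disc) { lp += -0.5 * zds[s] * zds[s]; G[i_zds + s] += -zds[s]; }
    }
    lp += -0.5 * sd_sb * sd_sb / (sd_scale * sd_scale) + Q[i_lssb];
    G[i_lssb] += -sd_sb * sd_sb / (sd_scale * sd_scale) + 1.0;
    if (has_disc) {
      lp += -0.5 * sd_sd * sd_sd / (sd_scale * sd_scale) + Q[i_lssd];
      G[i_lssd] += -sd_sd * sd_sd / (sd_scale * sd_scale) + 1.0;
      lp += lkj_eta * std::log1p(-rho_s * rho_s);
      G[i_rrs] += -2.0 * lkj_eta * rho_s;
    }
  }

  return List::create(Named("lp") = lp, Named("grad") = grad);
}
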