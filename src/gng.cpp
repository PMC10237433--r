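#include <Rcpp.h>
using namespace Rcpp;

// Model variants share one 7-slot natural parameter layout:
//   0 xi, 1 eps, 2 b, 3 pi_rew, 4 pi_pun, 5 rho_rew, 6 rho_pun
// M1 collapses pi_rew==pi_pun and rho_rew==rho_pun; M2 collapses the pi pair.
// Cues: 1 go-to-win, 2 go-to-avoid, 3 nogo-to-win, 4 nogo-to-avoid;
// reward domain = {1,3}, punishment = {2,4}.

static inline int npar(int variant) {
  return variant == 1 ? 5 : (variant == 2 ? 6 : 7);
}

// transform codes per unconstrained slot: 0 = probit (unit interval),
// 1 = identity, 2 = exp (positive)
static void transform_codes(int variant, int* code) {
  code[0] = 0; code[1] = 0; code[2] = 1; code[3] = 1;
  if (variant == 1) { code[4] = 2; }
  else if (variant == 2) { code[4] = 2; code[5] = 2; }
  else { code[4] = 1; code[5] = 2; code[6] = 2; }
}

static void to_natural(const double* u, int variant, double* nat) {
  int K = npar(variant);
  int code[7];
  transform_codes(variant, code);
  for (int k = 0; k < K; k++) {
    if (code[k] == 0) nat[k] = R::pnorm(u[k], 0.0, 1.0, 1, 0);
    else if (code[k] == 2) nat[k] = exp(u[k]);
    else nat[k] = u[k];
  }
}

static void expand7(const double* p, int variant, double* e) {
  e[0] = p[0]; e[1] = p[1]; e[2] = p[2];
  if (variant == 1) {          // xi eps b pi rho
    e[3] = p[3]; e[4] = p[3]; e[5] = p[4]; e[6] = p[4];
  } else if (variant == 2) {   // xi eps b pi rho_rew rho_pun
    e[3] = p[3]; e[4] = p[3]; e[5] = p[4]; e[6] = p[5];
  } else {                     // xi eps b pi_rew pi_pun rho_rew rho_pun
    for (int k = 3; k < 7; k++) e[k] = p[k];
  }
}

// forward pass over one subject's ordered session; fills pointwise log-lik
// (and optionally one-step-ahead p(go)) and returns the total
static double forward_pass(const int* cue, const int* act, const int* fb,
                           int n, const double* e7, double* pointwise,
                           double* pgo_out) {
  double Q[2][4] = {{0, 0, 0, 0}, {0, 0, 0, 0}};
  double V[4] = {0, 0, 0, 0};
  const double xi = e7[0], eps = e7[1], b = e7[2];
  double total = 0.0;
  for (int t = 0; t < n; t++) {
    int s = cue[t] - 1;
    bool rew = (cue[t] == 1 || cue[t] == 3);
    double piv = rew ? e7[3] : e7[4];
    double rho = rew ? e7[5] : e7[6];
    double wdiff = (Q[1][s] + b + piv * V[s]) - Q[0][s];
    double pgo = 1.0 / (1.0 + exp(-wdiff));
    pgo = pgo * (1.0 - xi) + xi / 2.0;
    if (pgo_out) pgo_out[t] = pgo;
    double p = act[t] == 1 ? pgo : 1.0 - pgo;
    double lp = log(p > 1e-300 ? p : 1e-300);
    if (pointwise) pointwise[t] = lp;
    total += lp;
    double pe = rho * fb[t];
    Q[act[t]][s] += eps * (pe - Q[act[t]][s]);
    V[s] += eps * (pe - V[s]);
  }
  return total;
}

static double subj_ll_u(const int* cue, const int* act, const int* fb, int n,
                        const double* u, int variant) {
  double nat[7], e7[7];
  to_natural(u, variant, nat);
  expand7(nat, variant, e7);
  return forward_pass(cue, act, fb, n, e7, nullptr, nullptr);
}

// [[Rcpp::export]]
List cpp_subject_loglik(IntegerVector cue, IntegerVector action,
                        IntegerVector feedback, NumericVector pars_natural,
                        int variant) {
  int n = cue.size();
  if (pars_natural.size() != npar(variant))
    stop("parameter vector has wrong length for this model variant");
  double e7[7];
  expand7(REAL(pars_natural), variant, e7);
  NumericVector pw(n);
  double total = forward_pass(INTEGER(cue), INTEGER(action),
                              INTEGER(feedback), n, e7, REAL(pw), nullptr);
  return List::create(_["total"] = total, _["pointwise"] = pw);
}

// one-step-ahead p(go) per trial, averaged over posterior draws of one
// subject's natural-scale parameters (draws x npar matrix)
// [[Rcpp::export]]
NumericVector cpp_onestep_mean(IntegerVector cue, IntegerVector action,
                               IntegerVector feedback, NumericMatrix draws,
                               int variant) {
  int n = cue.size(), S = draws.nrow();
  if (draws.ncol() != npar(variant))
    stop("draws matrix has wrong number of columns for this model variant");
  std::vector<double> pgo(n), acc(n, 0.0), par(draws.ncol());
  double e7[7];
  for (int s = 0; s < S; s++) {
    for (int k = 0; k < draws.ncol(); k++) par[k] = draws(s, k);
    expand7(par.data(), variant, e7);
    forward_pass(INTEGER(cue), INTEGER(action), INTEGER(feedback), n, e7,
                 nullptr, pgo.data());
    for (int t = 0; t < n; t++) acc[t] += pgo[t];
  }
  NumericVector out(n);
  for (int t = 0; t < n; t++) out[t] = acc[t] / S;
  return out;
}

// One MCMC chain for the hierarchical model, non-centered with interweaved
// centered updates:
//   theta_u[i,k] = mu[k] + sigma[k] * z[i,k]; natural params per ModelSpec
//   step A: adaptive random-walk Metropolis on each z[i,k] (subject likelihood)
//   step B: conjugate Gibbs draw of mu[k] | theta_u (likelihood untouched)
//   step C: Metropolis on log sigma[k] | theta_u, mu (likelihood untouched)
// Priors: mu[k] ~ N(0, prior_mu_sd[k]); sigma[k] ~ half-N(0, prior_sigma_sd);
// z ~ N(0,1). Uses R's RNG (seeded from R).
// [[Rcpp::export]]
List cpp_mcmc_chain(IntegerVector cue, IntegerVector action,
                    IntegerVector feedback, IntegerVector subj_start,
                    IntegerVector subj_len, int variant, int n_warmup,
                    int n_keep, int thin, NumericVector prior_mu_sd,
                    double prior_sigma_sd, NumericVector mu_init,
                    NumericVector sigma_init) {
  const int N = subj_start.size();
  const int K = npar(variant);
  if (prior_mu_sd.size() != K || mu_init.size() != K || sigma_init.size() != K)
    stop("hyperparameter vectors must have length equal to the parameter count");
  const int* cu = INTEGER(cue);
  const int* ac = INTEGER(action);
  const int* fb = INTEGER(feedback);

  std::vector<double> mu(mu_init.begin(), mu_init.end());
  std::vector<double> sigma(sigma_init.begin(), sigma_init.end());
  std::vector<double> z(N * K), th(N * K), lik(N), urow(K);
  for (int i = 0; i < N * K; i++) z[i] = norm_rand() * 0.1;
  for (int i = 0; i < N; i++) {
    for (int k = 0; k < K; k++) {
      th[i * K + k] = mu[k] + sigma[k] * z[i * K + k];
      urow[k] = th[i * K + k];
    }
    lik[i] = subj_ll_u(cu + subj_start[i], ac + subj_start[i],
                       fb + subj_start[i], subj_len[i], urow.data(), variant);
  }

  // adaptive proposal scales (log), batch adaptation during warmup
  std::vector<double> lstep_z(N * K, log(0.5)), lstep_eta(K, log(0.3));
  std::vector<int> acc_z(N * K, 0), acc_eta(K, 0);
  const int batch = 50;
  int batch_no = 0;

  NumericMatrix draws_mu(n_keep, K), draws_sigma(n_keep, K);
  NumericMatrix draws_theta(n_keep, N * K), pointwise(n_keep, N);
  int kept = 0;
  const int total_sweeps = n_warmup + n_keep * thin;

  for (int sweep = 0; sweep < total_sweeps; sweep++) {
    bool warm = sweep < n_warmup;

    // A: subject-level offsets
    for (int i = 0; i < N; i++) {
      for (int k = 0; k < K; k++) urow[k] = th[i * K + k];
      for (int k = 0; k < K; k++) {
        double z0 = z[i * K + k];
        double z1 = z0 + exp(lstep_z[i * K + k]) * norm_rand();
        double u_old = urow[k];
        urow[k] = mu[k] + sigma[k] * z1;
        double ll1 = subj_ll_u(cu + subj_start[i], ac + subj_start[i],
                               fb + subj_start[i], subj_len[i], urow.data(),
                               variant);
        double la = ll1 - lik[i] - 0.5 * (z1 * z1 - z0 * z0);
        if (log(unif_rand()) < la) {
          z[i * K + k] = z1;
          th[i * K + k] = urow[k];
          lik[i] = ll1;
          if (warm) acc_z[i * K + k]++;
        } else {
          urow[k] = u_old;
        }
      }
    }

    // B: conjugate Gibbs on mu[k] given theta_u (centered step)
    for (int k = 0; k < K; k++) {
      double s2 = sigma[k] * sigma[k];
      double tau2 = prior_mu_sd[k] * prior_mu_sd[k];
      double sum_th = 0.0;
      for (int i = 0; i < N; i++) sum_th += th[i * K + k];
      double prec = 1.0 / tau2 + N / s2;
      double mean = (sum_th / s2) / prec;
      double mu_new = mean + norm_rand() / sqrt(prec);
      for (int i = 0; i < N; i++)
        z[i * K + k] = (th[i * K + k] - mu_new) / sigma[k];
      mu[k] = mu_new;
    }

    // C: Metropolis on eta = log sigma[k] given theta_u, mu
    for (int k = 0; k < K; k++) {
      double ss = 0.0;
      for (int i = 0; i < N; i++) {
        double d = th[i * K + k] - mu[k];
        ss += d * d;
      }
      double eta0 = log(sigma[k]);
      double eta1 = eta0 + exp(lstep_eta[k]) * norm_rand();
      double s0 = sigma[k], s1 = exp(eta1);
      double lt0 = -s0 * s0 / (2.0 * prior_sigma_sd * prior_sigma_sd)
                   - N * eta0 - ss / (2.0 * s0 * s0) + eta0;
      double lt1 = -s1 * s1 / (2.0 * prior_sigma_sd * prior_sigma_sd)
                   - N * eta1 - ss / (2.0 * s1 * s1) + eta1;
      if (log(unif_rand()) < lt1 - lt0) {
        sigma[k] = s1;
        for (int i = 0; i < N; i++)
          z[i * K + k] = (th[i * K + k] - mu[k]) / s1;
        if (warm) acc_eta[k]++;
      }
    }

    // batch adaptation toward ~0.44 scalar-update acceptance
    if (warm && (sweep + 1) % batch == 0) {
      batch_no++;
      double delta = std::min(0.1, 1.0 / sqrt((double)batch_no));
      for (int j = 0; j < N * K; j++) {
        double rate = (double)acc_z[j] / batch;
        lstep_z[j] += (rate > 0.44 ? delta : -delta);
        lstep_z[j] = std::max(-7.0, std::min(3.0, lstep_z[j]));
        acc_z[j] = 0;
      }
      for (int k = 0; k < K; k++) {
        double rate = (double)acc_eta[k] / batch;
        lstep_eta[k] += (rate > 0.44 ? delta : -delta);
        lstep_eta[k] = std::max(-7.0, std::min(3.0, lstep_eta[k]));
        acc_eta[k] = 0;
      }
    }

    if (!warm && ((sweep - n_warmup) % thin) == (thin - 1) && kept < n_keep) {
      for (int k = 0; k < K; k++) {
        draws_mu(kept, k) = mu[k];
        draws_sigma(kept, k) = sigma[k];
      }
      for (int j = 0; j < N * K; j++) draws_theta(kept, j) = th[j];
      for (int i = 0; i < N; i++) pointwise(kept, i) = lik[i];
      kept++;
    }
  }

  return List::create(_["mu"] = draws_mu, _["sigma"] = draws_sigma,
                      _["theta"] = draws_theta, _["pointwise"] = pointwise);
}
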