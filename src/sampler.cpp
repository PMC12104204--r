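// Adaptive Metropolis-within-Gibbs sampler for the one-dimensional SECR
// model. One "case" is an individual-year; cases are conditionally
// independent given the population parameters (mu, omega, beta_e), so the
// per-case likelihood factorises over latitude bins:
//   S[j, l] ~ Poisson(lambda[j, l])
//   lambda  = 0 when effort 0 or A = 0, else
//             exp(R_j + beta_e * e_scaled[j, l] - d^2 / (2 sigma2_j))
//   sigma2_j = exp(mu + M_j),  M_j ~ N(0, omega^2),  R_j ~ N(0, 1)
//   C_j ~ Uniform(lat_min, lat_max),  A_j ~ Bernoulli(presence_prob)
// C, M, R, mu, omega, beta_e take random-walk Metropolis updates whose step
// sizes adapt towards 44% acceptance during burn-in only; A takes an exact
// two-point Gibbs update from its full conditional. When A = 0 the case's
// C, M, R drop out of the likelihood and are refreshed by exact draws from
// their priors (their full conditionals). Stored draws report the pinned
// absent-state values (absent_center, absent_sigma2) whenever A = 0.
#include <Rcpp.h>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct Model {
  const IntegerMatrix &S;
  const NumericMatrix &E; // scaled effort, 0 = not surveyed
  const NumericVector &cent;
  const NumericMatrix &lgS; // lgamma(S + 1), precomputed
  const LogicalVector &anyS;
  int J, L;
  double beta_e;

  Model(const IntegerMatrix &S_, const NumericMatrix &E_,
        const NumericVector &cent_, const NumericMatrix &lgS_,
        const LogicalVector &anyS_)
      : S(S_), E(E_), cent(cent_), lgS(lgS_), anyS(anyS_), J(S_.nrow()),
        L(S_.ncol()), beta_e(0.0) {}

  // log-likelihood of case j given its latent state and the globals
  double case_ll(int j, double Cj, double Mj, double Rj, int Aj,
                 double mu) const {
    if (Aj == 0) return anyS[j] ? NEG_INF : 0.0;
    double inv2s2 = 0.5 / std::exp(mu + Mj);
    double ll = 0.0;
    for (int l = 0; l < L; ++l) {
      double e = E(j, l);
      if (e > 0.0) {
        double d = cent[l] - Cj;
        double loglam = Rj + beta_e * e - d * d * inv2s2;
        ll += S(j, l) * loglam - std::exp(loglam) - lgS(j, l);
      } else if (S(j, l) > 0) {
        return NEG_INF; // sighting without effort: impossible state
      }
    }
    return ll;
  }
};

struct Adapt {
  double lstep;   // log step size
  int acc, tries; // within current batch
  Adapt(double s0) : lstep(std::log(s0)), acc(0), tries(0) {}
  double step() const { return std::exp(lstep); }
  void tally(bool accepted) {
    ++tries;
    if (accepted) ++acc;
  }
  void maybe_adapt(int batch_size, int batch_no) {
    if (tries < batch_size) return;
    double rate = double(acc) / tries;
    double delta = std::min(0.25, 1.0 / std::sqrt(double(batch_no)));
    lstep += (rate > 0.44) ? delta : -delta;
    acc = 0;
    tries = 0;
  }
};

// [[Rcpp::export]]
List secr_chain_cpp(IntegerMatrix S, NumericMatrix Esc, NumericVector cent,
                    double lat_min, double lat_max, int n_iter, int burn_in,
                    int thin, List priors, List fixed, double absent_center,
                    double absent_sigma2, List init) {
  const int J = S.nrow(), L = S.ncol();
  NumericMatrix lgS(J, L);
  LogicalVector anyS(J);
  for (int j = 0; j < J; ++j) {
    bool any = false;
    for (int l = 0; l < L; ++l) {
      lgS(j, l) = R::lgammafn(S(j, l) + 1.0);
      if (S(j, l) > 0) any = true;
    }
    anyS[j] = any;
  }
  Model m(S, Esc, cent, lgS, anyS);

  const double mu_mean = priors["mu_mean"], mu_sd = priors["mu_sd"];
  const double omega_sd = priors["omega_sd"];
  const double be_mean = priors["beta_e_mean"], be_sd = priors["beta_e_sd"];
  const double ppres = priors["presence_prob"];

  const bool fix_mu = fixed.containsElementNamed("mu");
  const bool fix_omega = fixed.containsElementNamed("omega");
  const bool fix_be = fixed.containsElementNamed("beta_e");
  const bool fix_R = fixed.containsElementNamed("R");
  NumericVector R_fix;
  if (fix_R) R_fix = as<NumericVector>(fixed["R"]);

  NumericVector C = clone(as<NumericVector>(init["C"]));
  NumericVector M = clone(as<NumericVector>(init["M"]));
  NumericVector Rv = clone(as<NumericVector>(init["R"]));
  IntegerVector A = clone(as<IntegerVector>(init["A"]));
  double mu = fix_mu ? double(fixed["mu"]) : double(init["mu"]);
  double omega = fix_omega ? double(fixed["omega"]) : double(init["omega"]);
  m.beta_e = fix_be ? double(fixed["beta_e"]) : double(init["beta_e"]);
  if (fix_R)
    for (int j = 0; j < J; ++j) Rv[j] = R_fix[j];

  std::vector<double> cll(J);
  for (int j = 0; j < J; ++j)
    cll[j] = m.case_ll(j, C[j], M[j], Rv[j], A[j], mu);

  std::vector<Adapt> stC(J, Adapt(0.02)), stM(J, Adapt(0.5)), stR(J, Adapt(0.3));
  Adapt stMu(0.2), stOm(0.2), stBe(0.05);
  const int batch = 50;
  int batch_no = 1;

  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix outC(n_keep, J), outS2(n_keep, J), outR(n_keep, J);
  IntegerMatrix outA(n_keep, J);
  NumericVector outMu(n_keep), outOm(n_keep), outBe(n_keep);
  int kept = 0;

  const bool update_M = !(fix_omega && omega == 0.0);

  for (int it = 1; it <= n_iter; ++it) {
    const bool adapting = it <= burn_in;
    for (int j = 0; j < J; ++j) {
      // activity center
      if (A[j] == 1) {
        double prop = C[j] + stC[j].step() * norm_rand();
        bool ok = prop >= lat_min && prop <= lat_max;
        double llp = ok ? m.case_ll(j, prop, M[j], Rv[j], 1, mu) : NEG_INF;
        bool acc = ok && std::log(unif_rand()) < llp - cll[j];
        if (acc) {
          C[j] = prop;
          cll[j] = llp;
        }
        if (adapting) {
          stC[j].tally(acc);
          stC[j].maybe_adapt(batch, batch_no);
        }
      } else {
        C[j] = R::runif(lat_min, lat_max);
      }
      // log-range random effect
      if (update_M) {
        if (A[j] == 1) {
          double prop = M[j] + stM[j].step() * norm_rand();
          double llp = m.case_ll(j, C[j], prop, Rv[j], 1, mu);
          double lr = llp - cll[j] - (prop * prop - M[j] * M[j]) /
                                         (2.0 * omega * omega);
          bool acc = std::log(unif_rand()) < lr;
          if (acc) {
            M[j] = prop;
            cll[j] = llp;
          }
          if (adapting) {
            stM[j].tally(acc);
            stM[j].maybe_adapt(batch, batch_no);
          }
        } else {
          M[j] = omega * norm_rand();
        }
      }
      // residency intercept, standard-normal prior
      if (!fix_R) {
        if (A[j] == 1) {
          double prop = Rv[j] + stR[j].step() * norm_rand();
          double llp = m.case_ll(j, C[j], M[j], prop, 1, mu);
          double lr = llp - cll[j] - (prop * prop - Rv[j] * Rv[j]) / 2.0;
          bool acc = std::log(unif_rand()) < lr;
          if (acc) {
            Rv[j] = prop;
            cll[j] = llp;
          }
          if (adapting) {
            stR[j].tally(acc);
            stR[j].maybe_adapt(batch, batch_no);
          }
        } else {
          Rv[j] = norm_rand();
        }
      }
      // presence indicator: exact two-point Gibbs draw
      if (anyS[j]) {
        A[j] = 1; // likelihood is zero otherwise
      } else {
        double ll1 = m.case_ll(j, C[j], M[j], Rv[j], 1, mu);
        double p1 = ppres * std::exp(ll1); // ll1 <= 0 here, no overflow
        double pr = p1 / (p1 + (1.0 - ppres));
        A[j] = (unif_rand() < pr) ? 1 : 0;
        cll[j] = A[j] ? ll1 : 0.0;
      }
    }

    // population mean log activity range
    if (!fix_mu) {
      double prop = mu + stMu.step() * norm_rand();
      double dll = 0.0;
      std::vector<double> newll(J);
      for (int j = 0; j < J; ++j) {
        if (A[j] == 1) {
          newll[j] = m.case_ll(j, C[j], M[j], Rv[j], 1, prop);
          dll += newll[j] - cll[j];
        }
      }
      dll += (R::dnorm(prop, mu_mean, mu_sd, 1) -
              R::dnorm(mu, mu_mean, mu_sd, 1));
      bool acc = std::log(unif_rand()) < dll;
      if (acc) {
        mu = prop;
        for (int j = 0; j < J; ++j)
          if (A[j] == 1) cll[j] = newll[j];
      }
      if (adapting) {
        stMu.tally(acc);
        stMu.maybe_adapt(batch, batch_no);
      }
    }

    // random-effect scale, half-normal prior; conjugate only to the M prior
    if (!fix_omega) {
      double prop = omega + stOm.step() * norm_rand();
      bool acc = false;
      if (prop > 0.0) {
        double lr = (omega * omega - prop * prop) / (2.0 * omega_sd * omega_sd);
        double sum2 = 0.0;
        for (int j = 0; j < J; ++j) sum2 += M[j] * M[j];
        lr += J * (std::log(omega) - std::log(prop)) +
              sum2 * (1.0 / (2.0 * omega * omega) - 1.0 / (2.0 * prop * prop));
        acc = std::log(unif_rand()) < lr;
        if (acc) omega = prop;
      }
      if (adapting) {
        stOm.tally(acc);
        stOm.maybe_adapt(batch, batch_no);
      }
    }

    // effort slope
    if (!fix_be) {
      double prop = m.beta_e + stBe.step() * norm_rand();
      double keep_be = m.beta_e;
      double dll = 0.0;
      std::vector<double> newll(J);
      m.beta_e = prop;
      for (int j = 0; j < J; ++j) {
        if (A[j] == 1) {
          newll[j] = m.case_ll(j, C[j], M[j], Rv[j], 1, mu);
          dll += newll[j] - cll[j];
        }
      }
      dll += (R::dnorm(prop, be_mean, be_sd, 1) -
              R::dnorm(keep_be, be_mean, be_sd, 1));
      if (std::log(unif_rand()) < dll) {
        for (int j = 0; j < J; ++j)
          if (A[j] == 1) cll[j] = newll[j];
        if (adapting) stBe.tally(true);
      } else {
        m.beta_e = keep_be;
        if (adapting) stBe.tally(false);
      }
      if (adapting) stBe.maybe_adapt(batch, batch_no);
    }

    if (adapting && it % batch == 0) ++batch_no;

    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      for (int j = 0; j < J; ++j) {
        outC(kept, j) = A[j] ? C[j] : absent_center;
        outS2(kept, j) = A[j] ? std::exp(mu + M[j]) : absent_sigma2;
        outR(kept, j) = Rv[j];
        outA(kept, j) = A[j];
      }
      outMu[kept] = mu;
      outOm[kept] = omega;
      outBe[kept] = m.beta_e;
      ++kept;
    }
  }

  return List::create(
      _["C"] = outC, _["sigma2"] = outS2, _["R"] = outR, _["A"] = outA,
      _["mu"] = outMu, _["omega"] = outOm, _["beta_e"] = outBe,
      _["n_kept"] = kept);
}
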