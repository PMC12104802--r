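#include <Rcpp.h>
using namespace Rcpp;

// Cohort log-likelihood of the interval-censored cause-specific joint model
// over a precomputed quadrature/design layout (see precompute_cohort() on the
// R side for the node "role" codes). Returns per-subject vectors for the PSA
// factor, the core-ratio factor and the event factor, so the sampler can
// recompute only the pieces a parameter block touches.
// [[Rcpp::export]]
List icjm_loglik_cpp(List pre, NumericVector beta_psa, NumericVector beta_cr,
                     NumericMatrix u, NumericVector gamma2,
                     NumericMatrix alpha_mat, NumericMatrix bcoef,
                     double sigma, bool do_long, bool do_event) {
  const int n = as<int>(pre["n"]);
  const bool two_marker = as<bool>(pre["two_marker"]);
  NumericVector ll_psa(n), ll_cr(n), ll_event(n);

  const NumericVector agec = pre["agec"], wcov = pre["wcov"];
  const double b4 = beta_psa[4];

  if (do_long) {
    // PSA: scaled Student-t(3) errors
    const IntegerVector pidx = pre["psa_idx"];
    const NumericVector py = pre["psa_y"];
    const NumericMatrix pZ = pre["psa_Z"];
    const double tconst = R::lgammafn(2.0) - R::lgammafn(1.5) -
      0.5 * std::log(3.0 * M_PI) - std::log(sigma);
    for (int j = 0; j < pidx.size(); ++j) {
      const int i = pidx[j] - 1;
      double m = b4 * agec[i];
      for (int p = 0; p < 4; ++p)
        m += pZ(j, p) * (beta_psa[p] + u(i, p));
      const double r = (py[j] - m) / sigma;
      ll_psa[i] += tconst - 2.0 * std::log1p(r * r / 3.0);
    }
    if (two_marker) {
      const IntegerVector cidx = pre["cr_idx"];
      const NumericVector cpos = pre["cr_pos"], ctot = pre["cr_tot"],
        clch = pre["cr_lch"];
      const NumericMatrix cZ = pre["cr_Z"];
      for (int j = 0; j < cidx.size(); ++j) {
        const int i = cidx[j] - 1;
        double eta = 0.0;
        for (int p = 0; p < 3; ++p)
          eta += cZ(j, p) * (beta_cr[p] + u(i, p + 4));
        // pos*eta - tot*log(1 + exp(eta)), computed stably
        const double lse = eta > 0 ? eta + std::log1p(std::exp(-eta))
                                   : std::log1p(std::exp(eta));
        ll_cr[i] += clch[j] + cpos[j] * eta - ctot[j] * lse;
      }
    }
  }

  if (do_event) {
    const IntegerVector nidx = pre["node_idx"], nev = pre["node_event"],
      nrole = pre["node_role"], ngrp = pre["node_grp"],
      delta = pre["delta"];
    const NumericVector nw = pre["node_w"], ntt = pre["node_t"],
      nt2 = pre["node_t2"];
    const NumericMatrix nB = pre["node_B"], nL = pre["node_L"],
      nD = pre["node_D"];
    const int n_groups = as<int>(pre["n_groups"]);
    const int nb = nD.ncol();
    const int nn = nidx.size();
    const bool cr_assoc = two_marker &&
      (alpha_mat(0, 2) != 0.0 || alpha_mat(1, 2) != 0.0);

    std::vector<double> loghaz(nn);
    std::vector<double> cumgrp(n_groups, 0.0);
    // pass 1: log-hazards at all nodes; inner nodes accumulate their
    // group's cumulative hazard, role-0 nodes their subject's survival term
    for (int j = 0; j < nn; ++j) {
      const int i = nidx[j] - 1, k = nev[j];
      double m = b4 * agec[i], mlag = m;
      for (int p = 0; p < 4; ++p) {
        const double c = beta_psa[p] + u(i, p);
        m += nB(j, p) * c;
        mlag += nL(j, p) * c;
      }
      double lh = gamma2[k] * wcov[i] + alpha_mat(k, 0) * m +
        alpha_mat(k, 1) * (m - mlag);
      if (cr_assoc) {
        double mcr = beta_cr[0] + u(i, 4) + (beta_cr[1] + u(i, 5)) * ntt[j] +
          (beta_cr[2] + u(i, 6)) * nt2[j];
        lh += alpha_mat(k, 2) * mcr;
      }
      for (int p = 0; p < nb; ++p) lh += nD(j, p) * bcoef(p, k);
      loghaz[j] = lh;
      if (nrole[j] == 0) ll_event[i] -= nw[j] * std::exp(lh);
      else if (nrole[j] == 2) cumgrp[ngrp[j]] += nw[j] * std::exp(lh);
    }
    // pass 2: outer delta = 1 nodes and delta = 2 log-hazard points
    std::vector<double> integ(n, 0.0);
    for (int j = 0; j < nn; ++j) {
      const int i = nidx[j] - 1;
      if (nrole[j] == 1)
        integ[i] += nw[j] * std::exp(loghaz[j] - cumgrp[ngrp[j]]);
      else if (nrole[j] == 3)
        ll_event[i] += loghaz[j];
    }
    for (int i = 0; i < n; ++i)
      if (delta[i] == 1) ll_event[i] += std::log(integ[i]);
  }

  return List::create(_["psa"] = ll_psa, _["cr"] = ll_cr,
                      _["event"] = ll_event);
}
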