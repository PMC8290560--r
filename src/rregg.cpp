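// Pedigree kernels and the random-regression Gibbs sampler.
// All random draws use R's RNG (norm_rand / R::rchisq), so chains are
// reproducible bit-for-bit under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Tabular (recursive) numerator relationship matrix.
// sire/dam are 1-based indices, 0 = unknown; parents precede offspring.
// [[Rcpp::export]]
arma::mat tabular_A_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  arma::mat A(n, n, arma::fill::zeros);
  for (int j = 0; j < n; ++j) {
    int s = sire[j] - 1, d = dam[j] - 1;
    for (int i = 0; i < j; ++i) {
      double a = 0.0;
      if (s >= 0) a += 0.5 * A(i, s);
      if (d >= 0) a += 0.5 * A(i, d);
      A(i, j) = A(j, i) = a;
    }
    A(j, j) = 1.0 + ((s >= 0 && d >= 0) ? 0.5 * A(s, d) : 0.0);
  }
  return A;
}

// Meuwissen & Luo inbreeding coefficients without forming A.
// [[Rcpp::export]]
NumericVector inbreeding_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= 0 && d >= 0)
      D[i] = 0.5 - 0.25 * (F[s] + F[d]);
    else if (s >= 0)
      D[i] = 0.75 - 0.25 * F[s];
    else if (d >= 0)
      D[i] = 0.75 - 0.25 * F[d];
    else
      D[i] = 1.0;
    if (s < 0 && d < 0) { F[i] = 0.0; continue; }
    // accumulate L_ij over ancestors, largest index first so contributions
    // to each ancestor are complete before it is popped
    std::map<int, double, std::greater<int>> coeff;
    coeff[i] = 1.0;
    double aii = 0.0;
    while (!coeff.empty()) {
      auto it = coeff.begin();
      int j = it->first;
      double c = it->second;
      coeff.erase(it);
      aii += c * c * D[j];
      int js = sire[j] - 1, jd = dam[j] - 1;
      if (js >= 0) coeff[js] += 0.5 * c;
      if (jd >= 0) coeff[jd] += 0.5 * c;
    }
    F[i] = aii - 1.0;
  }
  return F;
}

static arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z[i] = norm_rand();
  return z;
}

// Draw from N(B^{-1} rhs, B^{-1}) given precision B. Jitters the diagonal on
// Cholesky failure; increments *rejects on each jitter.
static arma::vec sample_mvn_prec(arma::mat B, const arma::vec& rhs, int* rejects) {
  arma::mat U;
  double jit = 0.0;
  while (!arma::chol(U, B)) {
    jit = (jit == 0.0) ? 1e-8 * arma::trace(B) / B.n_rows : jit * 10.0;
    B.diag() += jit;
    ++(*rejects);
  }
  arma::vec mu = arma::solve(arma::trimatu(U), arma::solve(arma::trimatl(U.t()), rhs));
  return mu + arma::solve(arma::trimatu(U), rnorm_vec(B.n_rows));
}

// Inverse-Wishart draw via the Bartlett construction on W ~ Wishart(S^{-1}, df).
static arma::mat riwish(const arma::mat& S, double df, int* rejects) {
  int q = S.n_rows;
  arma::mat Sinv = arma::inv_sympd((S + S.t()) / 2.0);
  arma::mat L;
  arma::mat Ssym = (Sinv + Sinv.t()) / 2.0;
  double jit = 0.0;
  while (!arma::chol(L, Ssym, "lower")) {
    jit = (jit == 0.0) ? 1e-10 * arma::trace(Ssym) / q : jit * 10.0;
    Ssym.diag() += jit;
    ++(*rejects);
  }
  arma::mat Abar(q, q, arma::fill::zeros);
  for (int i = 0; i < q; ++i) {
    Abar(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) Abar(i, j) = norm_rand();
  }
  arma::mat LA = L * Abar;
  arma::mat W = LA * LA.t();
  arma::mat C = arma::inv_sympd((W + W.t()) / 2.0);
  return (C + C.t()) / 2.0;
}

// Gibbs sampler for the random-regression model
//   y = (HxW) + (WxAFE) + b_week * bw + phi' alpha_animal + phi' pe_hen + e
// with Var(alpha) = K x C (K = A or H), Var(pe) = I x P, heterogeneous
// residual variances by period. Indices are 0-based; afe = -1 marks the
// reference class (no coefficient).
// [[Rcpp::export]]
List gibbs_rr_cpp(const arma::vec& y,
                  const arma::uvec& week,
                  const arma::uvec& period,
                  const arma::uvec& hw,
                  const arma::ivec& afe,
                  const arma::vec& bw,
                  const arma::uvec& hen,
                  const arma::uvec& hen_animal,
                  const arma::mat& Phi,
                  const arma::sp_mat& Kinv,
                  const arma::mat& C0, double dfC,
                  const arma::mat& P0, double dfP,
                  double res_df0,
                  int n_hw, int n_afe, int nperiod,
                  const arma::mat& Cstart, const arma::mat& Pstart,
                  const arma::vec& rstart,
                  int rounds, int burnin, int thin) {
  const int nrec = y.n_elem;
  const int q = Phi.n_cols;
  const int nweek = Phi.n_rows;
  const int N = Kinv.n_rows;
  const int nh = hen_animal.n_elem;

  // record lists
  std::vector<std::vector<int>> rec_hw(n_hw), rec_afe(std::max(n_afe, 1)),
      rec_week(nweek), rec_hen(nh);
  for (int r = 0; r < nrec; ++r) {
    rec_hw[hw[r]].push_back(r);
    if (afe[r] >= 0) rec_afe[afe[r]].push_back(r);
    rec_week[week[r]].push_back(r);
    rec_hen[hen[r]].push_back(r);
  }
  // animal -> hen (or -1)
  std::vector<int> animal_hen(N, -1);
  for (int h = 0; h < nh; ++h) animal_hen[hen_animal[h]] = h;

  // covariates transposed so each week's row is a contiguous column
  arma::mat PhiT = Phi.t(); // q x nweek

  // per-hen, per-period sums of phi phi' (residual weights vary by round)
  arma::cube TT(q, q, (size_t)nh * nperiod, arma::fill::zeros);
  for (int h = 0; h < nh; ++h)
    for (int r : rec_hen[h]) {
      arma::vec ph = PhiT.col(week[r]);
      TT.slice((size_t)h * nperiod + period[r]) += ph * ph.t();
    }

  // state; coefficient vectors stored as columns for contiguous access
  arma::vec b_hw(n_hw, arma::fill::zeros), b_afe(std::max(n_afe, 1), arma::fill::zeros),
      b_sl(nweek, arma::fill::zeros);
  arma::mat a(q, N, arma::fill::zeros), p(q, nh, arma::fill::zeros);
  arma::mat C = Cstart, P = Pstart;
  arma::vec rv = rstart;
  arma::vec e = y;
  int rejects = 0;

  const int nsave = (rounds - burnin) / thin;
  const int ntri = q * (q + 1) / 2;
  arma::mat Cs(nsave, ntri), Ps(nsave, ntri), Rs(nsave, nperiod);
  int isave = 0;

  arma::vec rinv(nperiod);

  for (int round = 1; round <= rounds; ++round) {
    if (round % 500 == 0) Rcpp::checkUserInterrupt();
    for (int k = 0; k < nperiod; ++k) rinv[k] = 1.0 / rv[k];
    arma::mat Cinv = arma::inv_sympd((C + C.t()) / 2.0);
    arma::mat Pinv = arma::inv_sympd((P + P.t()) / 2.0);

    // fixed effects: hatch-week x week cells
    for (int l = 0; l < n_hw; ++l) {
      if (rec_hw[l].empty()) continue;
      double prec = 0.0, m = 0.0, old = b_hw[l];
      for (int r : rec_hw[l]) {
        double w = rinv[period[r]];
        prec += w;
        m += w * (e[r] + old);
      }
      double bnew = m / prec + norm_rand() / std::sqrt(prec);
      for (int r : rec_hw[l]) e[r] -= (bnew - old);
      b_hw[l] = bnew;
    }
    // week x AFE cells (reference class has no coefficient)
    for (int l = 0; l < n_afe; ++l) {
      if (rec_afe[l].empty()) continue;
      double prec = 0.0, m = 0.0, old = b_afe[l];
      for (int r : rec_afe[l]) {
        double w = rinv[period[r]];
        prec += w;
        m += w * (e[r] + old);
      }
      double bnew = m / prec + norm_rand() / std::sqrt(prec);
      for (int r : rec_afe[l]) e[r] -= (bnew - old);
      b_afe[l] = bnew;
    }
    // body-weight slope per week of lay
    for (int t = 0; t < nweek; ++t) {
      if (rec_week[t].empty()) continue;
      double prec = 0.0, m = 0.0, old = b_sl[t];
      for (int r : rec_week[t]) {
        double w = rinv[period[r]];
        prec += w * bw[r] * bw[r];
        m += w * bw[r] * (e[r] + bw[r] * old);
      }
      if (prec <= 0.0) continue;
      double bnew = m / prec + norm_rand() / std::sqrt(prec);
      for (int r : rec_week[t]) e[r] -= bw[r] * (bnew - old);
      b_sl[t] = bnew;
    }

    // additive coefficients, blocked per animal
    for (int j = 0; j < N; ++j) {
      double kjj = 0.0;
      arma::vec s(q, arma::fill::zeros);
      for (arma::sp_mat::const_col_iterator it = Kinv.begin_col(j);
           it != Kinv.end_col(j); ++it) {
        int l = it.row();
        if (l == j)
          kjj = *it;
        else
          s += (*it) * a.unsafe_col(l);
      }
      arma::mat B = kjj * Cinv;
      arma::vec rhs = -(Cinv * s);
      int h = animal_hen[j];
      if (h >= 0) {
        for (int k = 0; k < nperiod; ++k)
          B += rinv[k] * TT.slice((size_t)h * nperiod + k);
        const double* aj = a.colptr(j);
        for (int r : rec_hen[h]) {
          const double* ph = PhiT.colptr(week[r]);
          double dot = 0.0;
          for (int k = 0; k < q; ++k) dot += ph[k] * aj[k];
          double coef = rinv[period[r]] * (e[r] + dot);
          double* rp = rhs.memptr();
          for (int k = 0; k < q; ++k) rp[k] += coef * ph[k];
        }
      }
      arma::vec anew = sample_mvn_prec(B, rhs, &rejects);
      if (h >= 0) {
        arma::vec da = anew - a.col(j);
        const double* dp = da.memptr();
        for (int r : rec_hen[h]) {
          const double* ph = PhiT.colptr(week[r]);
          double dot = 0.0;
          for (int k = 0; k < q; ++k) dot += ph[k] * dp[k];
          e[r] -= dot;
        }
      }
      a.col(j) = anew;
    }

    // permanent environmental coefficients per hen
    for (int h = 0; h < nh; ++h) {
      arma::mat B = Pinv;
      for (int k = 0; k < nperiod; ++k)
        B += rinv[k] * TT.slice((size_t)h * nperiod + k);
      const double* pold = p.colptr(h);
      arma::vec rhs(q, arma::fill::zeros);
      double* rp = rhs.memptr();
      for (int r : rec_hen[h]) {
        const double* ph = PhiT.colptr(week[r]);
        double dot = 0.0;
        for (int k = 0; k < q; ++k) dot += ph[k] * pold[k];
        double coef = rinv[period[r]] * (e[r] + dot);
        for (int k = 0; k < q; ++k) rp[k] += coef * ph[k];
      }
      arma::vec pnew = sample_mvn_prec(B, rhs, &rejects);
      arma::vec dvec = pnew - p.col(h);
      const double* dp = dvec.memptr();
      for (int r : rec_hen[h]) {
        const double* ph = PhiT.colptr(week[r]);
        double dot = 0.0;
        for (int k = 0; k < q; ++k) dot += ph[k] * dp[k];
        e[r] -= dot;
      }
      p.col(h) = pnew;
    }

    // coefficient covariances: inverse-Wishart full conditionals
    arma::mat Sa = C0 + a * (Kinv * a.t());
    C = riwish((Sa + Sa.t()) / 2.0, dfC + N, &rejects);
    arma::mat Sp = P0 + p * p.t();
    P = riwish((Sp + Sp.t()) / 2.0, dfP + nh, &rejects);

    // heterogeneous residual variances: scaled inverse chi-square per period
    arma::vec sse(nperiod, arma::fill::zeros);
    arma::vec cnt(nperiod, arma::fill::zeros);
    for (int r = 0; r < nrec; ++r) {
      sse[period[r]] += e[r] * e[r];
      cnt[period[r]] += 1.0;
    }
    for (int k = 0; k < nperiod; ++k) {
      double df = cnt[k] + res_df0;
      if (df < 1.0) df = 1.0;
      rv[k] = sse[k] / R::rchisq(df);
      if (rv[k] < 1e-12) rv[k] = 1e-12;
    }

    if (round > burnin && (round - burnin) % thin == 0 && isave < nsave) {
      int col = 0;
      for (int i = 0; i < q; ++i)
        for (int j2 = i; j2 < q; ++j2) {
          Cs(isave, col) = C(i, j2);
          Ps(isave, col) = P(i, j2);
          ++col;
        }
      Rs.row(isave) = rv.t();
      ++isave;
    }
  }

  return List::create(
      _["C"] = Cs, _["P"] = Ps, _["residual"] = Rs,
      _["pd_rejections"] = rejects, _["n_saved"] = isave);
}
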