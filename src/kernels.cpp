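// Dense per-iteration kernels for the variational EM.
// All pair sums run over ordered pairs (i, j), i != j, restricted to the
// observed (training) mask. Rates are floored before taking logs so the
// Ising couplings/fields stay finite when delta0 = 0 or memberships vanish.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double log_rate(double x, double floor_) {
  return std::log(x > floor_ ? x : floor_);
}

// Ising couplings J and fields h of the node-type posterior.
// J_ij = [log Pois(A_ij; S_ij) + log Pois(A_ij; M_ij) - 2 log Pois(A_ij; delta0)] / 4
// h_i  = 1/4 sum_j [lS_ij - lM_ij + lS_ji - lM_ji] + 1/2 [log mu - log(1 - mu)]
// The A_ij! term cancels across the three branches and is dropped.
// [[Rcpp::export]]
Rcpp::List cpp_ising_fields(const arma::mat& A, const arma::mat& mask,
                            const arma::mat& M, const arma::vec& s,
                            double c, double beta, double delta0, double mu,
                            double rate_floor, double mu_floor) {
  const uword N = A.n_rows;
  mat J(N, N, fill::zeros);
  vec h(N, fill::zeros);
  const double logc = log_rate(c, rate_floor);
  const double logd = log_rate(delta0, rate_floor);
  const double muc = std::min(std::max(mu, mu_floor), 1.0 - mu_floor);
  const double hprior = 0.5 * (std::log(muc) - std::log(1.0 - muc));
  for (uword j = 0; j < N; ++j) {
    for (uword i = 0; i < N; ++i) {
      if (i == j || mask(i, j) == 0.0) continue;
      const double d = s(i) - s(j) - 1.0;
      const double en = 0.5 * beta * d * d;
      const double Sij = c * std::exp(-en);
      const double a = A(i, j);
      const double lS = a * (logc - en) - Sij;
      const double lM = a * log_rate(M(i, j), rate_floor) - M(i, j);
      const double lD = a * logd - delta0;
      J(i, j) = 0.25 * (lS + lM - 2.0 * lD);
      const double diff = 0.25 * (lS - lM);
      h(i) += diff;
      h(j) += diff;
    }
  }
  h += hprior;
  return Rcpp::List::create(Rcpp::Named("J") = J, Rcpp::Named("h") = h);
}

// As cpp_ising_fields, but returns the symmetrised coupling J + t(J) directly
// (the only form the mean-field sweeps need), avoiding an extra N^2 pass.
// [[Rcpp::export]]
Rcpp::List cpp_ising_fields_sym(const arma::mat& A, const arma::mat& mask,
                                const arma::mat& M, const arma::vec& s,
                                double c, double beta, double delta0, double mu,
                                double rate_floor, double mu_floor) {
  const uword N = A.n_rows;
  mat Jsym(N, N, fill::zeros);
  vec h(N, fill::zeros);
  const double logc = log_rate(c, rate_floor);
  const double logd = log_rate(delta0, rate_floor);
  const double muc = std::min(std::max(mu, mu_floor), 1.0 - mu_floor);
  const double hprior = 0.5 * (std::log(muc) - std::log(1.0 - muc));
  for (uword j = 0; j < N; ++j) {
    for (uword i = 0; i < N; ++i) {
      if (i == j || mask(i, j) == 0.0) continue;
      const double d = s(i) - s(j) - 1.0;
      const double en = 0.5 * beta * d * d;
      const double Sij = (en > 60.0) ? 0.0 : c * std::exp(-en);
      const double a = A(i, j);
      const double lS = a * (logc - en) - Sij;
      const double lM = a * log_rate(M(i, j), rate_floor) - M(i, j);
      const double lD = a * logd - delta0;
      const double Jij = 0.25 * (lS + lM - 2.0 * lD);
      Jsym(i, j) += Jij;
      Jsym(j, i) += Jij;
      const double diff = 0.25 * (lS - lM);
      h(i) += diff;
      h(j) += diff;
    }
  }
  h += hprior;
  return Rcpp::List::create(Rcpp::Named("Jsym") = Jsym, Rcpp::Named("h") = h);
}

// Synchronous damped mean-field sweeps of m_i = tanh(h_i + sum_j (J_ij + J_ji) m_j)
// in +/-1 magnetisation variables; Jsym = J + t(J) is precomputed by the caller.
// Damping is applied on the Q scale, equivalently linearly on m.
// [[Rcpp::export]]
Rcpp::List cpp_mf_sweeps(const arma::mat& Jsym, const arma::vec& h,
                         const arma::vec& m0, double damping, double tol,
                         int max_sweeps) {
  vec m = m0;
  double delta = datum::inf;
  int sweeps = 0;
  while (sweeps < max_sweeps) {
    vec mprop = tanh(h + Jsym * m);
    vec mnew = damping * m + (1.0 - damping) * mprop;
    delta = 0.5 * abs(mnew - m).max();  // max |Q_new - Q_old|
    m = mnew;
    ++sweeps;
    if (delta < tol) break;
  }
  return Rcpp::List::create(Rcpp::Named("m") = m,
                            Rcpp::Named("sweeps") = sweeps,
                            Rcpp::Named("delta") = delta);
}

// Pairwise expectation term of the variational bound:
//   sum_{(i,j) in mask} Q_iQ_j lS_ij + (1-Q_i)(1-Q_j) lM_ij
//                       + [Q_i(1-Q_j) + (1-Q_i)Q_j] lDelta_ij
// log-pmfs without the A_ij! term (added separately by the caller if wanted).
// [[Rcpp::export]]
double cpp_pair_elbo(const arma::mat& A, const arma::mat& mask,
                     const arma::vec& Q, const arma::mat& M,
                     const arma::vec& s, double c, double beta,
                     double delta0, double rate_floor) {
  const uword N = A.n_rows;
  const double logc = log_rate(c, rate_floor);
  const double logd = log_rate(delta0, rate_floor);
  double acc = 0.0;
  for (uword j = 0; j < N; ++j) {
    for (uword i = 0; i < N; ++i) {
      if (i == j || mask(i, j) == 0.0) continue;
      const double d = s(i) - s(j) - 1.0;
      const double en = 0.5 * beta * d * d;
      const double a = A(i, j);
      const double Sij = (en > 60.0) ? 0.0 : c * std::exp(-en);
      const double lS = a * (logc - en) - Sij;
      const double lM = a * log_rate(M(i, j), rate_floor) - M(i, j);
      const double lD = a * logd - delta0;
      const double qq = Q(i) * Q(j);
      const double pp = (1.0 - Q(i)) * (1.0 - Q(j));
      acc += qq * lS + pp * lM + (1.0 - qq - pp) * lD;
    }
  }
  return acc;
}

// Sequential multiplicative updates for (u, v, w) where every edge term is
// weighted by (1-Q_i)(1-Q_j) and restricted to the mask; exponential priors
// add +lambda to the denominators. Zero rows stay zero.
//
// Numerator sums only involve observed edges (O(E K^2) via the edge list);
// denominator sums factorize through mask matrix-vector products (the
// O(N^2 K) BLAS part), which is what keeps the per-iteration cost at
// O(E K^2 + N^2) instead of a constant number of dense N^2 passes.
// [[Rcpp::export]]
Rcpp::List cpp_membership_update(const arma::umat& edge_ij,
                                 const arma::vec& edge_w,
                                 const arma::mat& mask, const arma::vec& Q,
                                 arma::mat u, arma::mat v, arma::mat w,
                                 double lambda_uv, double lambda_w,
                                 double rate_floor, int n_reps) {
  const uword N = u.n_rows;
  const uword K = u.n_cols;
  const uword E = edge_ij.n_rows;
  const vec qm = 1.0 - Q;

  for (int rep = 0; rep < n_reps; ++rep) {
    // u update
    {
      mat VW = v * w.t();  // VW(j, k) = sum_h v_jh w_kh
      mat num(N, K, fill::zeros);
      for (uword e = 0; e < E; ++e) {
        const uword i = edge_ij(e, 0), j = edge_ij(e, 1);
        const double Mij = dot(u.row(i) * w, v.row(j));
        const double r =
            qm(i) * qm(j) * edge_w(e) / std::max(Mij, rate_floor);
        num.row(i) += r * VW.row(j);
      }
      mat den = mask * (VW.each_col() % qm);  // sum_j mask_ij qm_j VW(j, k)
      den.each_col() %= qm;
      u = (u % num) / (den + lambda_uv);
      u.replace(datum::nan, 0.0);
    }
    // v update (with fresh u)
    {
      mat UW = u * w;  // UW(i, h) = sum_k u_ik w_kh
      mat num(N, K, fill::zeros);
      for (uword e = 0; e < E; ++e) {
        const uword i = edge_ij(e, 0), j = edge_ij(e, 1);
        const double Mij = dot(UW.row(i), v.row(j));
        const double r =
            qm(i) * qm(j) * edge_w(e) / std::max(Mij, rate_floor);
        num.row(j) += r * UW.row(i);
      }
      mat den = mask.t() * (UW.each_col() % qm);
      den.each_col() %= qm;
      v = (v % num) / (den + lambda_uv);
      v.replace(datum::nan, 0.0);
    }
    // w update (with fresh u, v)
    {
      mat UW = u * w;
      mat num(K, K, fill::zeros);
      for (uword e = 0; e < E; ++e) {
        const uword i = edge_ij(e, 0), j = edge_ij(e, 1);
        const double Mij = dot(UW.row(i), v.row(j));
        const double r =
            qm(i) * qm(j) * edge_w(e) / std::max(Mij, rate_floor);
        num += r * (u.row(i).t() * v.row(j));
      }
      mat T = mask * (v.each_col() % qm);        // N x K
      mat den = (u.each_col() % qm).t() * T;     // K x K
      w = (w % num) / (den + lambda_w);
      w.replace(datum::nan, 0.0);
    }
  }

  return Rcpp::List::create(Rcpp::Named("u") = u, Rcpp::Named("v") = v,
                            Rcpp::Named("w") = w);
}

// One-pass profile decomposition of the ranking block at fixed Q. All
// c-dependent quantities are linear in c, so the kernel returns the count
// part and the rate part separately:
//   obj(c)  = log(c) sumQQA - sumQQAen - c sumQQE
//   grad(c) = gA - c gE
//   B(c)    = Ba - c Be  (residuals; W = B + t(B) and b returned split too)
// which lets the caller evaluate the closed-form c and everything at it from
// a single sweep.
// [[Rcpp::export]]
Rcpp::List cpp_ranking_profile(const arma::mat& A, const arma::mat& mask,
                               const arma::vec& Q, const arma::vec& s,
                               double beta, double rate_floor,
                               bool want_system) {
  const uword N = A.n_rows;
  mat Wa, We, WeH;
  if (want_system) {
    Wa.zeros(N, N);
    We.zeros(N, N);
    WeH.zeros(N, N);  // Hessian rate part: qq e (1 - beta d^2), symmetrised
  }
  vec ba(N, fill::zeros), be(N, fill::zeros);
  vec gA(N, fill::zeros), gE(N, fill::zeros);
  double sumQQA = 0.0, sumQQE = 0.0, sumQQAen = 0.0;
  for (uword j = 0; j < N; ++j) {
    for (uword i = 0; i < N; ++i) {
      if (i == j || mask(i, j) == 0.0) continue;
      const double qq = Q(i) * Q(j);
      if (qq == 0.0) continue;
      const double d = s(i) - s(j) - 1.0;
      const double en = 0.5 * beta * d * d;
      const double qe = (en > 30.0) ? 0.0 : qq * std::exp(-en);
      if (qe > 0.0) {
        if (want_system) {
          We(i, j) += qe;
          We(j, i) += qe;
          const double qh = qe * (1.0 - beta * d * d);
          WeH(i, j) += qh;
          WeH(j, i) += qh;
        }
        be(i) += qe;
        be(j) -= qe;
        gE(i) -= beta * qe * d;
        gE(j) += beta * qe * d;
        sumQQE += qe;
      }
      const double a = A(i, j);
      if (a > 0.0) {
        const double qa = qq * a;
        if (want_system) {
          Wa(i, j) += qa;
          Wa(j, i) += qa;
        }
        ba(i) += qa;
        ba(j) -= qa;
        gA(i) -= beta * qa * d;
        gA(j) += beta * qa * d;
        sumQQA += qa;
        sumQQAen += qa * en;
      }
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("Wa") = Wa, Rcpp::Named("We") = We,
      Rcpp::Named("WeH") = WeH, Rcpp::Named("ba") = ba,
      Rcpp::Named("be") = be, Rcpp::Named("gA") = gA, Rcpp::Named("gE") = gE,
      Rcpp::Named("sumQQA") = sumQQA, Rcpp::Named("sumQQE") = sumQQE,
      Rcpp::Named("sumQQAen") = sumQQAen);
}

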