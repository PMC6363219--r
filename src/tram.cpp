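#include <Rcpp.h>
using namespace Rcpp;

// Discrete TRAM (dTRAM) self-consistent estimator.
//
// For each thermodynamic ensemble k the biased stationary weights are
// pi^k_i  propto  gamma^k_i * w_i   with  gamma^k_i = exp(-b^k_i),
// b^k_i the bias energy of microstate i in ensemble k (kBT units), and w the
// unknown unbiased stationary weights. The reversible transition matrix of
// ensemble k with stationary vector pi^k has the closed form
//   T^k_ij = (c^k_ij + c^k_ji) * pi^k_j / (nu^k_i pi^k_j + nu^k_j pi^k_i),
//   T^k_ii = c^k_ii / nu^k_i,
// with nu^k_i Lagrange multipliers enforcing row-stochasticity. The sweep
// alternates the nu self-map (row normalization) with the multiplicative w
// update obtained from the likelihood gradient wrt log w_i:
//   w_i <- (total incoming off-diagonal counts of i) /
//          sum_k sum_{j!=i} (c^k_ij + c^k_ji) nu^k_j gamma^k_i / den^k_ij,
//   den^k_ij = nu^k_i gamma^k_j w_j + nu^k_j gamma^k_i w_i.
//
// Pair counts are unordered (i < j, 0-based) with s = c_ij + c_ji; `diagc`,
// `inc` and `rowc` are K x M matrices of diagonal, incoming off-diagonal and
// total row counts per ensemble; logbias is the K x M bias matrix (kBT).
//
// [[Rcpp::export]]
List dtram_cpp(List pair_i, List pair_j, List pair_s,
               NumericMatrix diagc, NumericMatrix inc, NumericMatrix rowc,
               NumericMatrix logbias, int M, double tol, int max_iter) {
  const int K = pair_i.size();

  // gamma with a per-ensemble offset (the estimator is invariant under a
  // constant bias shift; subtracting the minimum avoids underflow)
  NumericMatrix gamma(K, M);
  for (int k = 0; k < K; ++k) {
    double bmin = R_PosInf;
    for (int i = 0; i < M; ++i) bmin = std::min(bmin, logbias(k, i));
    for (int i = 0; i < M; ++i) gamma(k, i) = std::exp(-(logbias(k, i) - bmin));
  }

  std::vector<IntegerVector> pi_(K), pj_(K);
  std::vector<NumericVector> ps_(K);
  for (int k = 0; k < K; ++k) {
    pi_[k] = pair_i[k]; pj_[k] = pair_j[k]; ps_[k] = pair_s[k];
  }

  NumericVector inc_tot(M);
  for (int i = 0; i < M; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += inc(k, i);
    inc_tot[i] = s;
  }

  // init: w uniform, nu = row counts
  NumericVector w(M, 1.0 / M);
  NumericMatrix nu(K, M);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < M; ++i) nu(k, i) = std::max(rowc(k, i), 1e-10);

  std::vector<double> ll_trace;
  double ll_old = R_NegInf;
  bool converged = false;
  int iter;

  NumericMatrix nu_new(K, M);
  NumericVector wden(M), rowsum(M);

  for (iter = 1; iter <= max_iter; ++iter) {
    std::fill(nu_new.begin(), nu_new.end(), 0.0);
    std::fill(wden.begin(), wden.end(), 0.0);
    double ll = 0.0;

    for (int k = 0; k < K; ++k) {
      const int P = pi_[k].size();
      std::fill(rowsum.begin(), rowsum.end(), 0.0);
      for (int p = 0; p < P; ++p) {
        const int i = pi_[k][p], j = pj_[k][p];
        const double s = ps_[k][p];
        const double aij = nu(k, i) * gamma(k, j) * w[j];
        const double aji = nu(k, j) * gamma(k, i) * w[i];
        const double den = aij + aji;
        if (den <= 0) continue;
        nu_new(k, i) += s * aij / den;
        nu_new(k, j) += s * aji / den;
        wden[i] += s * nu(k, j) * gamma(k, i) / den;
        wden[j] += s * nu(k, i) * gamma(k, j) / den;
        rowsum[i] += s * gamma(k, j) * w[j] / den;
        rowsum[j] += s * gamma(k, i) * w[i] / den;
        ll += s * std::log(s / den);
      }
      for (int i = 0; i < M; ++i) {
        const double cd = diagc(k, i);
        if (nu(k, i) > 0) rowsum[i] += cd / nu(k, i);
        if (cd > 0) ll += cd * std::log(cd / nu(k, i));
        if (inc(k, i) > 0) ll += inc(k, i) * std::log(gamma(k, i) * w[i]);
        if (rowc(k, i) > 0 && rowsum[i] > 0) ll -= rowc(k, i) * std::log(rowsum[i]);
        nu_new(k, i) += cd;
      }
    }

    std::copy(nu_new.begin(), nu_new.end(), nu.begin());
    double wsum = 0.0;
    for (int i = 0; i < M; ++i) {
      if (wden[i] > 0 && inc_tot[i] > 0) w[i] = inc_tot[i] / wden[i];
      wsum += w[i];
    }
    for (int i = 0; i < M; ++i) w[i] /= wsum;

    ll_trace.push_back(ll);
    if (iter > 1 && std::abs(ll - ll_old) < tol) { converged = true; break; }
    ll_old = ll;
  }

  return List::create(
      _["w"] = w, _["nu"] = nu,
      _["loglik"] = NumericVector(ll_trace.begin(), ll_trace.end()),
      _["iterations"] = std::min(iter, max_iter),
      _["converged"] = converged);
}

// Reversible transition matrix of one ensemble at the dTRAM fixed point.
// Off-diagonals from the closed form; diagonal as the row remainder.
// [[Rcpp::export]]
NumericMatrix dtram_transition_cpp(IntegerVector pair_i, IntegerVector pair_j,
                                   NumericVector pair_s, NumericVector nu_k,
                                   NumericVector gamma_k, NumericVector w) {
  const int M = w.size();
  NumericMatrix T(M, M);
  const int P = pair_i.size();
  for (int p = 0; p < P; ++p) {
    const int i = pair_i[p], j = pair_j[p];
    const double s = pair_s[p];
    const double aij = nu_k[i] * gamma_k[j] * w[j];
    const double aji = nu_k[j] * gamma_k[i] * w[i];
    const double den = aij + aji;
    if (den <= 0) continue;
    T(i, j) = s * gamma_k[j] * w[j] / den;
    T(j, i) = s * gamma_k[i] * w[i] / den;
  }
  for (int i = 0; i < M; ++i) {
    double rs = 0.0;
    for (int j = 0; j < M; ++j) if (j != i) rs += T(i, j);
    T(i, i) = std::max(0.0, 1.0 - rs);
  }
  // renormalize rows (guards rounding when off-diagonals exceed 1)
  for (int i = 0; i < M; ++i) {
    double rs = 0.0;
    for (int j = 0; j < M; ++j) rs += T(i, j);
    if (rs > 0) for (int j = 0; j < M; ++j) T(i, j) /= rs;
    else T(i, i) = 1.0;
  }
  return T;
}
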