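// Greedy hard-partition solver: the beta -> infinity limit of the
// redundancy-partitioning update. Elements are visited in seeded random
// order and moved to the component whose gain in the equally-weighted
// average component redundancy is largest; a pass with no accepted move
// terminates a restart. Subset redundancy is the Gaussian lower bound
// evaluated by Cholesky log-determinants of principal submatrices.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

double logdet_sub(const arma::mat& P, const arma::uvec& cols) {
  arma::mat sub = P.submat(cols, cols);
  double ld = 0.0, sign = 0.0;
  bool ok = arma::log_det(ld, sign, sub);
  if (ok && sign > 0.0 && std::isfinite(ld)) return ld;
  // numerically singular principal submatrix: tiny ridge, escalating
  for (double eps = 1e-8; eps <= 1e-4; eps *= 10.0) {
    arma::mat reg = (1.0 - eps) * sub + eps * arma::eye(sub.n_rows, sub.n_cols);
    ok = arma::log_det(ld, sign, reg);
    if (ok && sign > 0.0 && std::isfinite(ld)) return ld;
  }
  stop("singular correlation submatrix in hard-partition solver");
  return 0.0;  // unreachable
}

struct RedundancyEval {
  const arma::mat& P;
  const std::vector<arma::uvec>& elem_cols;
  const arma::vec& blk_logdet;
  const arma::vec& denom;

  double operator()(const std::vector<int>& members) const {
    const std::size_t na = members.size();
    if (na <= 1) return 0.0;
    std::size_t total = 0;
    for (int e : members) total += elem_cols[e].n_elem;
    arma::uvec cols(total);
    std::size_t pos = 0;
    double blk = 0.0, den = 0.0;
    for (int e : members) {
      const arma::uvec& c = elem_cols[e];
      cols.subvec(pos, pos + c.n_elem - 1) = c;
      pos += c.n_elem;
      blk += blk_logdet[e];
      den += denom[e];
    }
    double num = -0.5 * (logdet_sub(P, cols) - blk);
    if (num <= 0.0 || den <= 0.0) return 0.0;
    return num / den;
  }
};

int rand_int(int k) {  // uniform on 0..k-1 via R's RNG
  int v = (int)(unif_rand() * k);
  return v >= k ? k - 1 : v;
}

}  // namespace

// [[Rcpp::export]]
List hard_partition_cpp(const arma::mat& P, List elem_cols_r,
                        const arma::vec& blk_logdet, const arma::vec& denom,
                        int m, int restarts, int max_passes) {
  const int n = elem_cols_r.size();
  std::vector<arma::uvec> elem_cols(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector c = elem_cols_r[i];
    arma::uvec u(c.size());
    for (int q = 0; q < c.size(); ++q) u[q] = (arma::uword)(c[q] - 1);
    elem_cols[i] = u;
  }
  RedundancyEval r_of{P, elem_cols, blk_logdet, denom};

  double best_obj = -1.0;
  IntegerVector best_labels(n);
  NumericVector best_rcomp(m);
  std::vector<double> best_trace;
  int best_passes = 0, best_restart = 0;
  const double move_tol = 1e-12;

  for (int rep = 0; rep < restarts; ++rep) {
    std::vector<int> labels(n);
    for (int i = 0; i < n; ++i) labels[i] = rand_int(m);

    std::vector<std::vector<int>> members(m);
    for (int i = 0; i < n; ++i) members[labels[i]].push_back(i);
    std::vector<double> rcomp(m);
    for (int j = 0; j < m; ++j) rcomp[j] = r_of(members[j]);

    std::vector<double> trace;
    int pass = 0;
    bool moved = true;
    while (moved && pass < max_passes) {
      moved = false;
      ++pass;
      // seeded random visit order (Fisher-Yates with R's RNG)
      std::vector<int> order(n);
      for (int i = 0; i < n; ++i) order[i] = i;
      for (int i = n - 1; i > 0; --i) std::swap(order[i], order[rand_int(i + 1)]);

      for (int idx = 0; idx < n; ++idx) {
        int i = order[idx];
        int a = labels[i];
        std::vector<int> a_without = members[a];
        a_without.erase(std::find(a_without.begin(), a_without.end(), i));
        double r_a_without = r_of(a_without);

        // ascending b with strict improvement: ties keep the lowest index
        double best_delta = move_tol;
        int best_b = -1;
        double r_b_with_best = 0.0;
        for (int b = 0; b < m; ++b) {
          if (b == a) continue;
          std::vector<int> b_with = members[b];
          b_with.push_back(i);
          double r_b_with = r_of(b_with);
          double delta = (r_a_without + r_b_with - rcomp[a] - rcomp[b]) / m;
          if (delta > best_delta) {
            best_delta = delta;
            best_b = b;
            r_b_with_best = r_b_with;
          }
        }
        if (best_b >= 0) {
          members[a] = a_without;
          members[best_b].push_back(i);
          labels[i] = best_b;
          rcomp[a] = r_a_without;
          rcomp[best_b] = r_b_with_best;
          moved = true;
        }
      }
      double obj = 0.0;
      for (int j = 0; j < m; ++j) obj += rcomp[j];
      trace.push_back(obj / m);
    }

    double obj = 0.0;
    for (int j = 0; j < m; ++j) obj += rcomp[j];
    obj /= m;
    if (obj > best_obj) {
      best_obj = obj;
      for (int i = 0; i < n; ++i) best_labels[i] = labels[i] + 1;
      for (int j = 0; j < m; ++j) best_rcomp[j] = rcomp[j];
      best_trace = trace;
      best_passes = pass;
      best_restart = rep + 1;
    }
  }

  return List::create(
    _["labels"] = best_labels,
    _["component_redundancy"] = best_rcomp,
    _["average_redundancy"] = best_obj,
    _["objective_trace"] = NumericVector(best_trace.begin(), best_trace.end()),
    _["passes"] = best_passes,
    _["best_restart"] = best_restart);
}
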