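#include <Rcpp.h>
using namespace Rcpp;

// Frequency-weighted partitioning around medoids.
// BUILD: greedy weighted cost reduction; SWAP: steepest descent, evaluating all
// (medoid, candidate) exchanges per pass with shared-gain accumulators so a full
// pass costs O(m^2 + m k). Deterministic: ties always resolve to the lowest index.
// Objective: sum_j w_j * d(j, nearest medoid).

static void update_nearest(const NumericMatrix& D, const std::vector<int>& med,
                           std::vector<int>& nearest, std::vector<double>& d1,
                           std::vector<double>& d2) {
  const int m = D.nrow(), k = (int)med.size();
  for (int j = 0; j < m; ++j) {
    double b1 = R_PosInf, b2 = R_PosInf;
    int n1 = -1;
    for (int c = 0; c < k; ++c) { // med is kept sorted ascending -> lowest index wins ties
      double d = D(j, med[c]);
      if (d < b1) { b2 = b1; b1 = d; n1 = c; }
      else if (d < b2) { b2 = d; }
    }
    nearest[j] = n1; d1[j] = b1; d2[j] = b2;
  }
}

// steepest-descent SWAP from a given initial medoid set; returns final objective
static double run_swap(const NumericMatrix& D, const NumericVector& w, int k,
                       std::vector<int>& med, int max_swap,
                       std::vector<int>& nearest, std::vector<double>& d1,
                       std::vector<double>& d2) {
  const int m = D.nrow();
  std::sort(med.begin(), med.end());
  update_nearest(D, med, nearest, d1, d2);
  std::vector<double> acc(k);
  for (int pass = 0; pass < max_swap; ++pass) {
    double best_delta = -1e-9;
    int best_mi = -1, best_h = -1;
    for (int h = 0; h < m; ++h) {
      bool is_med = false;
      for (int c : med) if (c == h) { is_med = true; break; }
      if (is_med) continue;
      double g = 0.0;
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int j = 0; j < m; ++j) {
        const double dhj = D(j, h);
        const double c1 = dhj < d1[j] ? dhj - d1[j] : 0.0;
        g += w[j] * c1;
        const double rep = (dhj < d2[j] ? dhj : d2[j]) - d1[j];
        acc[nearest[j]] += w[j] * (rep - c1);
      }
      for (int c = 0; c < k; ++c) {
        const double delta = g + acc[c];
        if (delta < best_delta) { best_delta = delta; best_mi = c; best_h = h; }
      }
    }
    if (best_h < 0) break;
    med[best_mi] = best_h;
    std::sort(med.begin(), med.end());
    update_nearest(D, med, nearest, d1, d2);
  }
  double obj = 0.0;
  for (int j = 0; j < m; ++j) obj += w[j] * d1[j];
  return obj;
}

// [[Rcpp::export]]
List weighted_pam_cpp(NumericMatrix D, NumericVector w, int k, int max_swap = 200,
                      int n_restarts = 0) {
  const int m = D.nrow();
  if (k < 1 || k > m) stop("k must be between 1 and the number of unique sequences");

  std::vector<int> med;
  med.reserve(k);
  std::vector<double> d1(m, R_PosInf), d2(m, R_PosInf);
  std::vector<int> nearest(m, -1);

  // BUILD
  {
    // first medoid: minimal weighted total distance
    int best = 0;
    double bestcost = R_PosInf;
    for (int i = 0; i < m; ++i) {
      double c = 0.0;
      for (int j = 0; j < m; ++j) c += w[j] * D(j, i);
      if (c < bestcost) { bestcost = c; best = i; }
    }
    med.push_back(best);
    for (int j = 0; j < m; ++j) d1[j] = D(j, best);
    while ((int)med.size() < k) {
      int bi = -1;
      double bgain = -1.0;
      for (int i = 0; i < m; ++i) {
        bool is_med = false;
        for (int c : med) if (c == i) { is_med = true; break; }
        if (is_med) continue;
        double gain = 0.0;
        for (int j = 0; j < m; ++j) {
          double diff = d1[j] - D(j, i);
          if (diff > 0) gain += w[j] * diff;
        }
        if (gain > bgain + 1e-12) { bgain = gain; bi = i; }
      }
      med.push_back(bi);
      for (int j = 0; j < m; ++j) if (D(j, bi) < d1[j]) d1[j] = D(j, bi);
    }
    std::sort(med.begin(), med.end());
  }

  double obj = run_swap(D, w, k, med, max_swap, nearest, d1, d2);

  // seeded random restarts (R RNG): escape rare SWAP local optima on small
  // instances; the best solution (ties to the first found) is kept
  for (int r = 0; r < n_restarts; ++r) {
    std::vector<int> cand;
    std::vector<bool> used(m, false);
    while ((int)cand.size() < k) {
      int pick = (int)std::floor(unif_rand() * m);
      if (pick >= m) pick = m - 1;
      if (!used[pick]) { used[pick] = true; cand.push_back(pick); }
    }
    std::vector<int> nearest_r(m, -1);
    std::vector<double> d1_r(m, R_PosInf), d2_r(m, R_PosInf);
    double obj_r = run_swap(D, w, k, cand, max_swap, nearest_r, d1_r, d2_r);
    if (obj_r < obj - 1e-12) {
      obj = obj_r; med = cand; nearest = nearest_r; d1 = d1_r; d2 = d2_r;
    }
  }

  IntegerVector assign(m);
  for (int j = 0; j < m; ++j) {
    assign[j] = med[nearest[j]] + 1; // assignment labelled by medoid point index (1-based)
  }
  IntegerVector med_out(k);
  for (int c = 0; c < k; ++c) med_out[c] = med[c] + 1;
  return List::create(_["medoids"] = med_out, _["assignment"] = assign,
                      _["objective"] = obj);
}
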