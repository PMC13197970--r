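#include <Rcpp.h>
using namespace Rcpp;

// Longest common subsequence length between two integer state vectors,
// classic O(|a||b|) dynamic programme with two rolling rows.
static int lcs_len(const int* a, int na, const int* b, int nb,
                   std::vector<int>& prev, std::vector<int>& cur) {
  std::fill(prev.begin(), prev.begin() + nb + 1, 0);
  for (int i = 1; i <= na; ++i) {
    cur[0] = 0;
    const int ai = a[i - 1];
    for (int j = 1; j <= nb; ++j) {
      if (ai == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = prev[j] >= cur[j - 1] ? prev[j] : cur[j - 1];
    }
    std::swap(prev, cur);
  }
  return prev[nb];
}

// [[Rcpp::export]]
int lcs_length_cpp(IntegerVector a, IntegerVector b) {
  int na = a.size(), nb = b.size();
  std::vector<int> prev(nb + 1), cur(nb + 1);
  return lcs_len(a.begin(), na, b.begin(), nb, prev, cur);
}

// Pairwise LCS distance matrix d(a,b) = |a| + |b| - 2 LCS(a,b) over the rows
// of an integer matrix of sequences (one sequence per row, equal length).
// [[Rcpp::export]]
NumericMatrix lcs_dist_matrix_cpp(IntegerMatrix seqs) {
  const int m = seqs.nrow(), L = seqs.ncol();
  // row-major copy for cache-friendly pair loops
  std::vector<int> buf((size_t)m * L);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < L; ++j) buf[(size_t)i * L + j] = seqs(i, j);
  NumericMatrix D(m, m);
  std::vector<int> prev(L + 1), cur(L + 1);
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      int l = lcs_len(&buf[(size_t)i * L], L, &buf[(size_t)j * L], L, prev, cur);
      double d = 2.0 * (L - l);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
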