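#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Exhaustive enumeration of candidate word supports of order <= k_max over the
// selected columns of a binary matrix, with exact occurrence counts and
// independent-null expectations. A support is kept when it occurs at least once
// in the data, or when it is absent but its null-expected count M * <sigma_mu>
// reaches min_expected.
//
// Returned masks encode bit j (0-based) for the j-th entry of `cols`; they are
// doubles and exact for up to 52 columns. `lexkey` orders supports of equal
// order lexicographically by their (ascending) index sequence.
// [[Rcpp::export(name = ".enum_candidates_cpp")]]
List enum_candidates_cpp(IntegerMatrix x, IntegerVector cols, int k_max,
                         double min_expected) {
  const int M = x.nrow();
  const int nc = cols.size();
  if (nc > 52) stop("candidate enumeration supports at most 52 usable columns");
  if (k_max < 1) stop("k_max must be >= 1");
  if (k_max > nc) k_max = nc;

  std::vector<uint64_t> rows(M, 0);
  std::vector<double> logf(nc);
  for (int j = 0; j < nc; ++j) {
    const int cj = cols[j] - 1;
    long s = 0;
    for (int m = 0; m < M; ++m) {
      const int v = x(m, cj);
      if (v != 0 && v != 1) stop("non-binary entry at row %d, column %d", m + 1, cj + 1);
      if (v) { rows[m] |= (uint64_t(1) << j); ++s; }
    }
    if (s == 0 || s == M)
      stop("constant column passed to the enumerator (column %d)", cj + 1);
    logf[j] = std::log(double(s) / double(M));
  }

  std::vector<double> out_mask, out_null, out_key;
  std::vector<int> out_count, out_order;
  const double keybase = double(nc) + 1.0;
  std::vector<double> keypow(k_max);
  keypow[k_max - 1] = 1.0;
  for (int i = k_max - 2; i >= 0; --i) keypow[i] = keypow[i + 1] * keybase;

  std::vector<int> c(k_max);
  for (int k = 1; k <= k_max; ++k) {
    for (int i = 0; i < k; ++i) c[i] = i;
    while (true) {
      uint64_t mask = 0;
      double lm = 0.0, key = 0.0;
      for (int i = 0; i < k; ++i) {
        mask |= (uint64_t(1) << c[i]);
        lm += logf[c[i]];
        key += double(c[i] + 1) * keypow[i];
      }
      int count = 0;
      for (int m = 0; m < M; ++m)
        if ((rows[m] & mask) == mask) ++count;
      const double nullmean = std::exp(lm);
      if (count > 0 || double(M) * nullmean >= min_expected) {
        out_mask.push_back(double(mask));
        out_count.push_back(count);
        out_null.push_back(nullmean);
        out_order.push_back(k);
        out_key.push_back(key);
      }
      // next combination in lexicographic order
      int i = k - 1;
      while (i >= 0 && c[i] == nc - k + i) --i;
      if (i < 0) break;
      ++c[i];
      for (int j = i + 1; j < k; ++j) c[j] = c[j - 1] + 1;
    }
  }

  return List::create(_["mask"] = wrap(out_mask),
                      _["order"] = wrap(out_order),
                      _["n_mu"] = wrap(out_count),
                      _["null_mean"] = wrap(out_null),
                      _["lexkey"] = wrap(out_key));
}
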