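#include <Rcpp.h>
using namespace Rcpp;

// Lag-correlation tandem scan. For each lag p, positions matching their
// p-shifted neighbour (N never matches) are computed; runs of matches are
// merged around seed runs (length >= max(4, min(p, 12))) by best-first
// absorption of neighbouring gap+run pairs while the overall purity stays
// >= purity_min. Candidate segments are returned in match-position
// coordinates (1-based start/end), with purity; the caller handles the
// harmonic resolution and motif calls.

// [[Rcpp::export(name = ".tandem_scan")]]
DataFrame tandem_scan(std::string s, int max_period, double purity_min,
                      int min_len) {
  const int n = s.size();
  std::vector<int> out_start, out_end, out_period;
  std::vector<double> out_purity;
  const int max_p = std::min(max_period, n / 2);

  std::vector<int> run_start, run_len;
  std::vector<char> run_val;

  for (int p = 1; p <= max_p; ++p) {
    const int m = n - p;
    // run-length encode the match vector on the fly
    run_start.clear(); run_len.clear(); run_val.clear();
    int i = 0;
    int max_true_run = 0;
    while (i < m) {
      bool v = (s[i] == s[i + p]) && s[i] != 'N';
      int j = i + 1;
      while (j < m && (((s[j] == s[j + p]) && s[j] != 'N') == v)) ++j;
      run_start.push_back(i + 1);          // 1-based
      run_len.push_back(j - i);
      run_val.push_back(v ? 1 : 0);
      if (v && j - i > max_true_run) max_true_run = j - i;
      i = j;
    }
    const int seed_min = std::max(4, std::min(p, 12));
    if (max_true_run < seed_min) continue;

    const int nr = run_len.size();
    std::vector<char> used(nr, 0);
    for (int si = 0; si < nr; ++si) {
      if (!run_val[si] || run_len[si] < seed_min || used[si]) continue;
      int lo = si, hi = si;
      double matches = run_len[si], total = run_len[si];
      for (;;) {
        double pr = -1.0, pl = -1.0;
        if (hi + 2 < nr && run_val[hi + 2])
          pr = (matches + run_len[hi + 2]) /
               (total + run_len[hi + 1] + run_len[hi + 2]);
        if (lo - 2 >= 0 && run_val[lo - 2])
          pl = (matches + run_len[lo - 2]) /
               (total + run_len[lo - 1] + run_len[lo - 2]);
        double best = std::max(pr, pl);
        if (best < purity_min) break;
        if (pr == pl) {                    // symmetric tie: absorb both
          matches += run_len[hi + 2] + run_len[lo - 2];
          total += run_len[hi + 1] + run_len[hi + 2] +
                   run_len[lo - 1] + run_len[lo - 2];
          hi += 2; lo -= 2;
        } else if (pr > pl) {
          matches += run_len[hi + 2];
          total += run_len[hi + 1] + run_len[hi + 2];
          hi += 2;
        } else {
          matches += run_len[lo - 2];
          total += run_len[lo - 1] + run_len[lo - 2];
          lo -= 2;
        }
      }
      for (int k = lo; k <= hi; ++k) used[k] = 1;
      double purity = matches / total;
      int seg_start = run_start[lo];
      int seg_end = run_start[hi] + run_len[hi] - 1;
      // segment [i, j] in match positions covers sequence [i, j + p]
      if (purity >= purity_min &&
          (seg_end - seg_start + 1 + p) >= std::max(2 * p, min_len)) {
        out_start.push_back(seg_start);
        out_end.push_back(seg_end);
        out_period.push_back(p);
        out_purity.push_back(purity);
      }
    }
  }
  return DataFrame::create(_["start"] = out_start, _["end"] = out_end,
                           _["period"] = out_period,
                           _["purity"] = out_purity);
}
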