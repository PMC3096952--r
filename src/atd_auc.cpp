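#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Average time-dependent AUCROC from staircase ROC curves at each death
// event time: cumulative cases (time <= t, event), dynamic controls
// (time > t), patients censored at or before t excluded at that time.
// A Fenwick tree over rank-compressed scores makes the whole sweep
// O((n + total control queries) log n), which matters because the nested
// cross-validation scores every nested model on every fold.

namespace {

class Fenwick {
  std::vector<double> t;

public:
  explicit Fenwick(int n) : t(n + 1, 0.0) {}
  void add(int i, double v) {
    for (++i; i < static_cast<int>(t.size()); i += i & -i) t[i] += v;
  }
  double prefix(int i) const {  // sum over ranks [0, i]
    double s = 0.0;
    for (++i; i > 0; i -= i & -i) s += t[i];
    return s;
  }
};

}  // namespace

// [[Rcpp::export(name = ".atd_value")]]
double atd_value(Rcpp::NumericVector scores, Rcpp::NumericVector time,
                 Rcpp::NumericVector event, bool half = false) {
  const int n = scores.size();
  if (time.size() != n || event.size() != n)
    Rcpp::stop("'scores', 'time' and 'event' must be aligned vectors");

  std::vector<double> uniq(scores.begin(), scores.end());
  std::sort(uniq.begin(), uniq.end());
  uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
  const int m = static_cast<int>(uniq.size());
  std::vector<int> rank(n);
  for (int i = 0; i < n; ++i)
    rank[i] = static_cast<int>(
        std::lower_bound(uniq.begin(), uniq.end(), scores[i]) - uniq.begin());

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return time[a] < time[b]; });

  Fenwick cases(m);
  int nCases = 0;
  int ptr = 0;  // patients with time <= current t already absorbed
  // accumulate like base R sum(): extended precision, rounded once
  long double total = 0.0L;
  int wsum = 0;

  while (ptr < n) {
    const double t = time[ord[ptr]];
    int d = 0;
    while (ptr < n && time[ord[ptr]] == t) {
      const int j = ord[ptr];
      if (event[j] == 1.0) {
        cases.add(rank[j], 1.0);
        ++nCases;
        ++d;
      }
      ++ptr;
    }
    if (d > 0 && ptr < n) {  // controls remain beyond t
      double credit = 0.0;
      const int nControls = n - ptr;
      for (int q = ptr; q < n; ++q) {
        const int j = ord[q];
        const double leq = cases.prefix(rank[j]);
        const double less = rank[j] > 0 ? cases.prefix(rank[j] - 1) : 0.0;
        credit += (nCases - leq) + (half ? 0.5 * (leq - less) : 0.0);
      }
      total += static_cast<long double>(
          d * (credit / (static_cast<double>(nCases) * nControls)));
      wsum += d;
    }
  }
  if (wsum == 0)
    Rcpp::stop("unevaluable set: no event time with both cases and controls");
  return static_cast<double>(total) / wsum;
}
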