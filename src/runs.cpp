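#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Exact maximal repetitions ("runs"): substrings whose minimal period p
// satisfies length >= 2p and which cannot be extended in either direction
// while keeping period p. Enumerated by scanning, for each candidate
// period p, maximal stretches of positions k with s[k] == s[k+p]; a
// stretch of m matches spans a p-periodic interval of length m + p. The
// interval is kept only if p is its minimal period (otherwise the same
// interval is found at that smaller period). Positions holding 'N' never
// match, so no run crosses an N. Coordinates are 0-based half-open.

struct Run { int start, end, period; };

// [[Rcpp::export]]
List find_runs_cpp(std::string s, int min_tract) {
  const int n = static_cast<int>(s.size());
  std::vector<Run> runs;

  const int maxp = n / 2;
  for (int p = 1; p <= maxp; ++p) {
    int k = 0;
    while (k + p < n) {
      if (s[k] != 'N' && s[k] == s[k + p]) {
        const int i = k;
        while (k + p < n && s[k] != 'N' && s[k] == s[k + p]) ++k;
        const int m = k - i;           // matched positions
        if (m >= p) {                  // tract length m + p >= 2p
          const int st = i, en = i + m + p;
          if (en - st >= min_tract) {
            bool minimal = true;
            for (int q = 1; q < p && minimal; ++q) {
              bool periodic = true;
              for (int x = st; x < en - q; ++x)
                if (s[x] != s[x + q]) { periodic = false; break; }
              if (periodic) minimal = false;
            }
            if (minimal) runs.push_back({st, en, p});
          }
        }
      }
      ++k;
    }
  }

  std::sort(runs.begin(), runs.end(), [](const Run &a, const Run &b) {
    return a.start != b.start ? a.start < b.start : a.period < b.period;
  });

  const int nr = static_cast<int>(runs.size());
  IntegerVector start(nr), end(nr), period(nr);
  for (int i = 0; i < nr; ++i) {
    start[i] = runs[i].start;
    end[i] = runs[i].end;
    period[i] = runs[i].period;
  }
  return List::create(_["start"] = start, _["end"] = end,
                      _["period"] = period);
}

// Batch interface: one call per candidate read set keeps R-side loop
// overhead out of per-sample processing.
// [[Rcpp::export]]
List find_runs_batch_cpp(CharacterVector seqs, int min_tract) {
  const int n = seqs.size();
  std::vector<int> idx, start, end, period;
  for (int i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) continue;
    std::string s = as<std::string>(seqs[i]);
    List r = find_runs_cpp(s, min_tract);
    IntegerVector st = r["start"], en = r["end"], pe = r["period"];
    for (int j = 0; j < st.size(); ++j) {
      idx.push_back(i + 1);  // 1-based read index for R
      start.push_back(st[j]);
      end.push_back(en[j]);
      period.push_back(pe[j]);
    }
  }
  return List::create(_["read"] = wrap(idx), _["start"] = wrap(start),
                      _["end"] = wrap(end), _["period"] = wrap(period));
}
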