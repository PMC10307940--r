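#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Dwell-constrained DTW of a signal against a k-mer automaton.
//
// Subproblem: best cost of aligning signal points 0..i such that point i
// is aligned to state j with c further points still owed to the current
// run (c == 0 means the minimum-dwell requirement is already satisfied).
// A transition into state j at signal index i owes sreq[i] - 1 further
// points; leaving a state is only allowed from c == 0.  Ties prefer
// staying in the current state, then predecessors in the order supplied
// (lexicographic k-mer order), which makes warping paths deterministic.
//
// pred:    list of integer vectors, 0-based predecessor ids per state
// start:   0-based ids allowed at i = 0
// accept:  0-based ids allowed at i = m-1 (in tie-break order)
// sreq:    per-signal-index minimum dwell (>= 1) applying to runs that
//          *start* at that index

// [[Rcpp::export]]
List dtw_align_cpp(NumericVector signal, NumericVector level, List pred,
                   IntegerVector start, IntegerVector accept,
                   IntegerVector sreq) {
  const int m = signal.size();
  const int n = level.size();
  if (m < 1 || n < 1) stop("empty signal or automaton");
  int smax = 1;
  for (int i = 0; i < m; ++i) {
    if (sreq[i] < 1) stop("minimum dwell must be >= 1");
    if (sreq[i] > smax) smax = sreq[i];
  }
  const int C = smax;  // c ranges over 0..C-1
  const double INF = std::numeric_limits<double>::infinity();
  const double bytes = static_cast<double>(m) * n * C;
  if (bytes > 2.5e8) stop("alignment problem too large (m*n*s = %g cells)", bytes);

  std::vector<std::vector<int>> preds(n);
  for (int j = 0; j < n; ++j) preds[j] = as<std::vector<int>>(pred[j]);

  std::vector<double> prev(static_cast<size_t>(n) * C, INF);
  std::vector<double> cur(static_cast<size_t>(n) * C, INF);
  // backpointer codes: -3 none, -1 stay from (j, c+1), -2 stay from (j, 0),
  // p >= 0: entered from preds[j][p] at (i-1, 0)
  std::vector<int> bp(static_cast<size_t>(m) * n * C, -3);

  // i = 0
  {
    const int c0 = sreq[0] - 1;
    for (int a = 0; a < start.size(); ++a) {
      const int j = start[a];
      prev[static_cast<size_t>(j) * C + c0] = std::fabs(signal[0] - level[j]);
      bp[static_cast<size_t>(j) * C + c0] = -3;
    }
  }

  for (int i = 1; i < m; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    const int centry = sreq[i] - 1;
    size_t off_i = static_cast<size_t>(i) * n * C;
    for (int j = 0; j < n; ++j) {
      const double dij = std::fabs(signal[i] - level[j]);
      const size_t base = static_cast<size_t>(j) * C;
      for (int c = 0; c < C; ++c) {
        double best = INF;
        int code = -3;
        // stay in j, one point closer to satisfying the dwell
        if (c + 1 < C) {
          const double v = prev[base + c + 1];
          if (v < best) { best = v; code = -1; }
        }
        // stay in j with dwell already satisfied
        if (c == 0) {
          const double v = prev[base + 0];
          if (v < best) { best = v; code = -2; }
        }
        // enter j from a predecessor whose run is complete
        if (c == centry) {
          const std::vector<int>& pj = preds[j];
          for (size_t p = 0; p < pj.size(); ++p) {
            const double v = prev[static_cast<size_t>(pj[p]) * C + 0];
            if (v < best) { best = v; code = static_cast<int>(p); }
          }
        }
        if (best < INF) {
          cur[base + c] = best + dij;
          bp[off_i + base + c] = code;
        }
      }
    }
    std::swap(prev, cur);
  }

  // pick the best accept state with the dwell satisfied
  double best = INF;
  int bj = -1;
  for (int a = 0; a < accept.size(); ++a) {
    const int j = accept[a];
    const double v = prev[static_cast<size_t>(j) * C + 0];
    if (v < best) { best = v; bj = j; }
  }
  if (!(best < INF)) {
    return List::create(_["feasible"] = false, _["cost"] = R_PosInf,
                        _["path"] = IntegerVector(0));
  }
  // special case m == 1: prev holds i = 0 and c must equal sreq[0]-1 == 0
  // (handled naturally: if sreq[0] > 1 no state has c == 0 and the
  // alignment is reported infeasible)

  IntegerVector path(m);
  int j = bj, c = 0;
  for (int i = m - 1; i >= 0; --i) {
    path[i] = j + 1;  // back to 1-based ids
    if (i == 0) break;
    const int code = bp[static_cast<size_t>(i) * n * C +
                        static_cast<size_t>(j) * C + c];
    if (code == -1) {
      c = c + 1;
    } else if (code == -2) {
      c = 0;
    } else if (code >= 0) {
      j = preds[j][code];
      c = 0;
    } else {
      stop("internal error: broken backpointer chain");
    }
  }
  return List::create(_["feasible"] = true, _["cost"] = best,
                      _["path"] = path);
}
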