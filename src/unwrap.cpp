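#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double wrap2pi(double x) {
  return x - 2.0 * M_PI * std::floor(x / (2.0 * M_PI) + 0.5);
}

// Quality-guided flood-fill phase unwrapping.
//
// Each pixel's reliability is the negative sum of squared wrapped
// differences to its 4-neighbours (smooth regions are unwrapped first, so
// noisy/residue-laden regions cannot corrupt them). Starting from the most
// reliable pixel, pixels are popped from a max-priority queue and finalized
// as wrapped[q] + 2*pi*k with k chosen against the finalized neighbour that
// enqueued them, which guarantees the congruence contract: output minus
// input is an exact integer multiple of 2*pi everywhere.
//
// Residues (non-zero curl of the wrapped gradient around 2x2 plaquettes)
// are counted and returned; inputs containing them are unwrapped
// best-effort.
// [[Rcpp::export]]
List cpp_unwrap(NumericMatrix wrapped) {
  const int nr = wrapped.nrow(), nc = wrapped.ncol();
  const int n = nr * nc;
  NumericMatrix out(nr, nc);
  if (n == 0) return List::create(_["values"] = out, _["residues"] = 0);

  std::vector<double> qual(n, 0.0);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double w = wrapped(i, j), s = 0.0, d;
      if (i > 0)      { d = wrap2pi(wrapped(i - 1, j) - w); s += d * d; }
      if (i < nr - 1) { d = wrap2pi(wrapped(i + 1, j) - w); s += d * d; }
      if (j > 0)      { d = wrap2pi(wrapped(i, j - 1) - w); s += d * d; }
      if (j < nc - 1) { d = wrap2pi(wrapped(i, j + 1) - w); s += d * d; }
      qual[i + j * nr] = -s;
    }
  }

  int seed = 0;
  for (int k = 1; k < n; ++k) if (qual[k] > qual[seed]) seed = k;

  typedef std::pair<double, int> QItem;  // (quality, pixel index)
  std::priority_queue<QItem> pq;
  std::vector<char> state(n, 0);  // 0 free, 1 queued, 2 done
  const double *w = wrapped.begin();
  double *o = out.begin();

  o[seed] = w[seed];
  state[seed] = 2;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  int done = 1;
  int cur = seed;
  while (true) {
    int ci = cur % nr, cj = cur / nr;
    for (int t = 0; t < 4; ++t) {
      int i = ci + dr[t], j = cj + dc[t];
      if (i < 0 || i >= nr || j < 0 || j >= nc) continue;
      int q = i + j * nr;
      if (state[q] != 0) continue;
      double k = std::floor((o[cur] - w[q]) / (2.0 * M_PI) + 0.5);
      o[q] = w[q] + 2.0 * M_PI * k;
      state[q] = 1;
      pq.push(QItem(qual[q], q));
    }
    if (done == n) break;
    bool found = false;
    while (!pq.empty()) {
      QItem top = pq.top(); pq.pop();
      if (state[top.second] == 1) {
        cur = top.second;
        state[cur] = 2;
        ++done;
        found = true;
        break;
      }
    }
    if (!found) break;  // disconnected (cannot happen on a full grid)
  }

  int residues = 0;
  for (int j = 0; j + 1 < nc; ++j) {
    for (int i = 0; i + 1 < nr; ++i) {
      double s = wrap2pi(wrapped(i, j + 1) - wrapped(i, j)) +
                 wrap2pi(wrapped(i + 1, j + 1) - wrapped(i, j + 1)) +
                 wrap2pi(wrapped(i + 1, j) - wrapped(i + 1, j + 1)) +
                 wrap2pi(wrapped(i, j) - wrapped(i + 1, j));
      if (std::fabs(s) > M_PI) ++residues;
    }
  }

  return List::create(_["values"] = out, _["residues"] = residues);
}
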