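#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline double wrap2pi(double d) {
  return d - 2.0 * M_PI * std::round(d / (2.0 * M_PI));
}

// Quality-guided flood-fill phase unwrapping.
//
// Quality per pixel is the negated sum of squared wrapped differences to
// its 4-neighbours (high quality = locally smooth phase). Each connected
// component of the mask is seeded at its highest-quality pixel and grown
// through a max-heap on pixel quality; every popped pixel is unwrapped
// relative to the already-solved neighbour it was reached from.
//
// [[Rcpp::export]]
List unwrap_quality_guided(NumericMatrix wrapped, LogicalMatrix mask) {
  const int nx = wrapped.nrow(), ny = wrapped.ncol();
  const int n = nx * ny;
  std::vector<double> quality(n, -1e300);
  std::vector<int> comp(n, 0);
  std::vector<char> done(n, 0);
  NumericMatrix out(nx, ny);

  auto idx = [nx](int i, int j) { return j * nx + i; };

  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (!mask(i, j)) continue;
      double q = 0.0;
      const double w = wrapped(i, j);
      if (i > 0 && mask(i - 1, j)) { double d = wrap2pi(w - wrapped(i - 1, j)); q -= d * d; }
      if (i < nx - 1 && mask(i + 1, j)) { double d = wrap2pi(w - wrapped(i + 1, j)); q -= d * d; }
      if (j > 0 && mask(i, j - 1)) { double d = wrap2pi(w - wrapped(i, j - 1)); q -= d * d; }
      if (j < ny - 1 && mask(i, j + 1)) { double d = wrap2pi(w - wrapped(i, j + 1)); q -= d * d; }
      quality[idx(i, j)] = q;
    }
  }

  typedef std::pair<double, std::pair<int, int> > entry; // (quality, (pixel, from))
  std::priority_queue<entry> heap;
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  int ncomp = 0;

  for (int j0 = 0; j0 < ny; ++j0) {
    for (int i0 = 0; i0 < nx; ++i0) {
      if (!mask(i0, j0) || done[idx(i0, j0)]) continue;
      // new component: seed at its highest-quality pixel (scan the
      // component by a cheap BFS first)
      std::vector<int> members;
      std::queue<std::pair<int, int> > bfs;
      bfs.push(std::make_pair(i0, j0));
      // BFS over comp == 0 pixels; comp = -1 marks "queued"
      comp[idx(i0, j0)] = -1;
      int best = idx(i0, j0);
      while (!bfs.empty()) {
        std::pair<int, int> p = bfs.front(); bfs.pop();
        int i = p.first, jj = p.second, id = idx(i, jj);
        members.push_back(id);
        if (quality[id] > quality[best]) best = id;
        for (int k = 0; k < 4; ++k) {
          int ii = i + di[k], jk = jj + dj[k];
          if (ii < 0 || ii >= nx || jk < 0 || jk >= ny) continue;
          int id2 = idx(ii, jk);
          if (!mask(ii, jk) || comp[id2] != 0) continue;
          comp[id2] = -1;
          bfs.push(std::make_pair(ii, jk));
        }
      }
      ++ncomp;
      for (size_t m = 0; m < members.size(); ++m) comp[members[m]] = ncomp;
      // grow from the best seed
      int si = best % nx, sj = best / nx;
      out(si, sj) = wrapped(si, sj);
      done[best] = 1;
      heap.push(std::make_pair(quality[best], std::make_pair(best, best)));
      while (!heap.empty()) {
        entry e = heap.top(); heap.pop();
        int id = e.second.first, from = e.second.second;
        int i = id % nx, jj = id / nx;
        if (id != from) {
          if (done[id]) continue;
          int fi = from % nx, fj = from / nx;
          out(i, jj) = out(fi, fj) + wrap2pi(wrapped(i, jj) - wrapped(fi, fj));
          done[id] = 1;
        }
        for (int k = 0; k < 4; ++k) {
          int ii = i + di[k], jk = jj + dj[k];
          if (ii < 0 || ii >= nx || jk < 0 || jk >= ny) continue;
          int id2 = idx(ii, jk);
          if (!mask(ii, jk) || done[id2]) continue;
          heap.push(std::make_pair(quality[id2], std::make_pair(id2, id)));
        }
      }
    }
  }

  IntegerMatrix comp_out(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      comp_out(i, j) = mask(i, j) ? comp[idx(i, j)] : 0;

  return List::create(Named("phase") = out,
                      Named("components") = comp_out,
                      Named("n_components") = ncomp);
}
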