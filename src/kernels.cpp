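#include <Rcpp.h>
#include <vector>
#include <numeric>
using namespace Rcpp;

// ---- union-find -----------------------------------------------------------

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// 8-connected component labelling of a logical matrix, two-pass union-find.
// Returns an integer matrix, 0 = background, components labelled 1..n in
// raster order of their first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& img) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0); // parent[0] unused
  int next = 1;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!img(r, c)) continue;
      // previously visited 8-neighbours (column-major raster order)
      int best = 0;
      int nbr[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      std::vector<int> seen;
      for (auto& n : nbr) {
        int rr = n[0], cc = n[1];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          seen.push_back(l);
          if (best == 0 || l < best) best = l;
        }
      }
      if (best == 0) {
        lab(r, c) = next;
        parent.push_back(next);
        ++next;
      } else {
        lab(r, c) = best;
        for (int l : seen) uf_union(parent, best, l);
      }
    }
  }
  // second pass: resolve + compact labels in raster order
  std::vector<int> remap(next, 0);
  int out = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = uf_find(parent, l);
      if (remap[root] == 0) remap[root] = ++out;
      lab(r, c) = remap[root];
    }
  return lab;
}

// ---- Guo-Hall thinning ----------------------------------------------------
// (parallel two-subiteration scheme; unlike Zhang-Suen it does not erase
// 2-px-wide diagonal strips wholesale)

// One sub-iteration; returns number of deletions. pass = 0 or 1.
static int gh_pass(std::vector<unsigned char>& im, int nr, int nc, int pass) {
  std::vector<int> kill;
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return im[(size_t)c * nr + r];
  };
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!at(r, c)) continue;
      // neighbours clockwise from north: p2..p9
      int p2 = at(r - 1, c), p3 = at(r - 1, c + 1), p4 = at(r, c + 1),
          p5 = at(r + 1, c + 1), p6 = at(r + 1, c), p7 = at(r + 1, c - 1),
          p8 = at(r, c - 1), p9 = at(r - 1, c - 1);
      int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
              ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
      int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
      int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
      int N = N1 < N2 ? N1 : N2;
      int m = pass == 0 ? ((p6 | p7 | (!p9)) & p8)
                        : ((p2 | p3 | (!p5)) & p4);
      if (C == 1 && N >= 2 && N <= 3 && m == 0) kill.push_back(c * nr + r);
    }
  }
  for (int k : kill) im[k] = 0;
  return (int)kill.size();
}

// Guo-Hall topology-preserving thinning to a 1-px-wide 8-connected skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(const LogicalMatrix& img) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<unsigned char> im((size_t)nr * nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) im[(size_t)c * nr + r] = img(r, c) ? 1 : 0;
  for (;;) {
    int d = gh_pass(im, nr, nc, 0);
    d += gh_pass(im, nr, nc, 1);
    if (d == 0) break;
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) out(r, c) = im[(size_t)c * nr + r] != 0;
  return out;
}

// ---- DLCA -----------------------------------------------------------------

// Diffusion-limited cluster-cluster aggregation on an L x L lattice.
// Each sweep every cluster attempts a unit move in a random axial direction
// with probability size^(-1/2); boundaries reflect (blocked moves are
// dropped); clusters touching under 8-connectivity merge irreversibly.
// Uses R's RNG so results are governed by set.seed().
// Returns the label grid (labels are arbitrary positive ids).
// [[Rcpp::export]]
IntegerMatrix cpp_dlca(int n_particles, int grid_size, int max_sweeps,
                       bool stop_single) {
  const int L = grid_size;
  if (n_particles <= 0) stop("n_particles must be positive");
  if ((double)n_particles >= (double)L * L)
    stop("n_particles must be < grid_size^2");

  std::vector<int> grid((size_t)L * L, 0); // 0 empty, else cluster id+1
  // cluster storage: pixel indices per cluster; alive flag via parent
  std::vector<std::vector<int>> pix;
  std::vector<int> parent;

  // seed particles uniformly at random on empty sites
  int placed = 0;
  while (placed < n_particles) {
    int r = (int)(unif_rand() * L), c = (int)(unif_rand() * L);
    if (r >= L) r = L - 1;
    if (c >= L) c = L - 1;
    size_t id = (size_t)c * L + r;
    if (grid[id]) continue;
    grid[id] = (int)pix.size() + 1;
    pix.push_back(std::vector<int>(1, (int)id));
    parent.push_back((int)pix.size() - 1);
    ++placed;
  }

  auto root = [&](int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  };

  int n_clusters = n_particles;
  const int dr[4] = {1, -1, 0, 0};
  const int dc[4] = {0, 0, 1, -1};

  // merge the clusters of two grid cells
  auto merge = [&](int ida, int idb) {
    int a = root(ida), b = root(idb);
    if (a == b) return;
    if (pix[a].size() < pix[b].size()) std::swap(a, b);
    for (int p : pix[b]) {
      grid[p] = a + 1;
      pix[a].push_back(p);
    }
    std::vector<int>().swap(pix[b]);
    parent[b] = a;
    --n_clusters;
  };

  std::vector<int> alive(n_particles);
  std::iota(alive.begin(), alive.end(), 0);

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    if (stop_single && n_clusters <= 1) break;
    if (sweep % 256 == 0) Rcpp::checkUserInterrupt();
    // compact the alive list so late sweeps do not scan dead slots
    alive.erase(std::remove_if(alive.begin(), alive.end(),
                               [&](int i) { return parent[i] != i || pix[i].empty(); }),
                alive.end());
    for (size_t oi = 0; oi < alive.size(); ++oi) {
      int cl = alive[oi];
      if (parent[cl] != cl || pix[cl].empty()) continue;
      double p = 1.0 / std::sqrt((double)pix[cl].size());
      if (unif_rand() >= p) continue;
      int dir = (int)(unif_rand() * 4);
      if (dir > 3) dir = 3;
      int mr = dr[dir], mc = dc[dir];
      // check move: in bounds and not into a foreign cluster
      bool ok = true;
      int blocker = -1;
      for (int q : pix[cl]) {
        int r = q % L, c = q / L;
        int rr = r + mr, cc = c + mc;
        if (rr < 0 || rr >= L || cc < 0 || cc >= L) { ok = false; blocker = -1; break; }
        int g = grid[(size_t)cc * L + rr];
        if (g && root(g - 1) != cl) { ok = false; blocker = g - 1; break; }
      }
      if (!ok) {
        // blocked by another cluster: they are in contact, merge
        if (blocker >= 0) merge(cl, blocker);
        continue;
      }
      // perform the move: clear then rewrite
      for (int q : pix[cl]) grid[q] = 0;
      for (int& q : pix[cl]) {
        int r = q % L, c = q / L;
        q = (c + mc) * L + (r + mr);
      }
      for (int q : pix[cl]) grid[q] = cl + 1;
      // scan 8-neighbourhood for foreign clusters -> merge; rescan after
      // every merge since the pixel list changes
      bool merged = true;
      while (merged) {
        merged = false;
        int self = root(cl);
        for (int q : pix[self]) {
          int r = q % L, c = q / L;
          for (int a = -1; a <= 1 && !merged; ++a)
            for (int b = -1; b <= 1; ++b) {
              if (!a && !b) continue;
              int rr = r + a, cc = c + b;
              if (rr < 0 || rr >= L || cc < 0 || cc >= L) continue;
              int g = grid[(size_t)cc * L + rr];
              if (g && root(g - 1) != self) {
                merge(self, g - 1);
                merged = true;
                break;
              }
            }
          if (merged) break;
        }
      }
    }
  }

  IntegerMatrix out(L, L);
  for (int c = 0; c < L; ++c)
    for (int r = 0; r < L; ++r) out(r, c) = grid[(size_t)c * L + r];
  return out;
}
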