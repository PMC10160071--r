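#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Vietoris-Rips persistence in dimensions 0 and 1 for a Euclidean point
// cloud.
//
// H0: Kruskal's algorithm over all pairwise distances; the finite H0 deaths
// are exactly the edge lengths of a Euclidean minimum spanning tree.
//
// H1: persistent cohomology of the 2-skeleton, reducing the coboundary
// columns of the edges (processed in decreasing filtration order) with
// triangle cofacets enumerated lazily, so the triangle set is never
// materialised.  By persistence homology/cohomology duality the resulting
// (edge, triangle) pairs are the H1 persistence pairs.  The filtration is
// truncated at the enclosing radius min_i max_j d(i, j): at that value the
// complex is a cone, hence has trivial H1, so the truncation is exact.

struct DisjointSet {
  std::vector<int> parent, rank_;
  explicit DisjointSet(int n) : parent(n), rank_(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) ++rank_[a];
    return true;
  }
};

struct Edge {
  double d;
  int i, j;
};

// triangle identified by (diam, i, j, k); ordering = filtration order
struct Tri {
  double d;
  int i, j, k;
  bool operator<(const Tri& o) const {
    if (d != o.d) return d < o.d;
    if (i != o.i) return i < o.i;
    if (j != o.j) return j < o.j;
    return k < o.k;
  }
  bool operator==(const Tri& o) const {
    return i == o.i && j == o.j && k == o.k;
  }
};

static inline int64_t tri_key(int i, int j, int k, int n) {
  return ((int64_t)i * n + j) * n + k;
}

// columns kept sorted descending in filtration order: back() = minimal
// cofacet = the cohomology pivot
static void symdiff_desc(std::vector<Tri>& a, const std::vector<Tri>& b,
                         std::vector<Tri>& tmp) {
  tmp.clear();
  std::set_symmetric_difference(
      a.begin(), a.end(), b.begin(), b.end(), std::back_inserter(tmp),
      [](const Tri& x, const Tri& y) { return y < x; });
  a.swap(tmp);
}

// [[Rcpp::export]]
List vr_persistence_cpp(NumericMatrix pts, double threshold) {
  const int n = pts.nrow();
  if (n < 1) stop("point cloud must be nonempty");

  NumericVector h0_death;
  if (n == 1) {
    return List::create(_["h0_death"] = h0_death,
                        _["h1"] = NumericMatrix(0, 2),
                        _["h1_essential"] = NumericVector(0),
                        _["threshold"] = 0.0);
  }

  std::vector<double> dist((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(i, 0) - pts(j, 0), dy = pts(i, 1) - pts(j, 1);
      double d = std::sqrt(dx * dx + dy * dy);
      if (!R_finite(d)) stop("non-finite distance between points");
      dist[(size_t)i * n + j] = d;
      dist[(size_t)j * n + i] = d;
    }
  }

  double r_enc = R_PosInf;  // enclosing radius
  for (int i = 0; i < n; ++i) {
    double mx = 0.0;
    for (int j = 0; j < n; ++j) mx = std::max(mx, dist[(size_t)i * n + j]);
    r_enc = std::min(r_enc, mx);
  }
  const double thresh = (threshold > 0) ? threshold : r_enc;

  std::vector<Edge> all_edges;
  all_edges.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      all_edges.push_back({dist[(size_t)i * n + j], i, j});
  std::sort(all_edges.begin(), all_edges.end(),
            [](const Edge& a, const Edge& b) {
              if (a.d != b.d) return a.d < b.d;
              if (a.i != b.i) return a.i < b.i;
              return a.j < b.j;
            });

  // H0 (Kruskal); remember which edges enter the MST
  std::vector<char> in_mst(all_edges.size(), 0);
  {
    DisjointSet ds(n);
    std::vector<double> deaths;
    deaths.reserve(n - 1);
    for (size_t e = 0; e < all_edges.size(); ++e) {
      if (ds.unite(all_edges[e].i, all_edges[e].j)) {
        in_mst[e] = 1;
        deaths.push_back(all_edges[e].d);
        if ((int)deaths.size() == n - 1) break;
      }
    }
    h0_death = wrap(deaths);
  }

  // Largest "lens-empty" edge: an edge (a, b) whose lens (points strictly
  // closer than d(a, b) to both endpoints) is nonempty is filled by a
  // triangle at its own filtration value, so every H1 class of positive
  // persistence is born at a lens-empty edge.  (Induction on edge length:
  // any cycle is homologous to one avoiding all non-lens-empty edges, using
  // only strictly shorter ones.)
  double lens_bound = 0.0;
  for (const Edge& e : all_edges) {
    const double* di = &dist[(size_t)e.i * n];
    const double* dj = &dist[(size_t)e.j * n];
    bool filled = false;
    for (int k = 0; k < n; ++k) {
      if (k == e.i || k == e.j) continue;
      if (di[k] < e.d && dj[k] < e.d) { filled = true; break; }
    }
    if (!filled) lens_bound = std::max(lens_bound, e.d);
  }

  std::vector<double> h1_birth, h1_death, h1_ess;

  // reduce the coboundary columns of the edges under a truncation value t;
  // classes still alive at t end up in h1_ess
  auto reduce_h1 = [&](double t) {
    h1_birth.clear(); h1_death.clear(); h1_ess.clear();
    std::vector<std::vector<int> > nbr(n);
    for (const Edge& e : all_edges) {
      if (e.d > t) break;
      nbr[e.i].push_back(e.j);
      nbr[e.j].push_back(e.i);
    }
    std::vector<Tri> col, tmp;
    auto build_column = [&](int i, int j, std::vector<Tri>& out) {
      out.clear();
      const double* di = &dist[(size_t)i * n];
      const double* dj = &dist[(size_t)j * n];
      double dij = di[j];
      const std::vector<int>& small_nbr =
          (nbr[i].size() < nbr[j].size()) ? nbr[i] : nbr[j];
      for (int k : small_nbr) {
        if (k == i || k == j) continue;
        if (di[k] <= t && dj[k] <= t) {
          double d = std::max(dij, std::max(di[k], dj[k]));
          int a = i, b = j, c = k;
          if (c < a) std::swap(a, c);
          if (c < b) std::swap(b, c);
          if (b < a) std::swap(a, b);
          out.push_back({d, a, b, c});
        }
      }
      std::sort(out.begin(), out.end(),
                [](const Tri& x, const Tri& y) { return y < x; });  // descending
    };

    std::unordered_map<int64_t, int> pivot_owner;  // pivot -> store index
    std::vector<std::vector<Tri> > stored;
    for (size_t eidx = all_edges.size(); eidx-- > 0;) {
      const Edge& e = all_edges[eidx];
      if (e.d > t) continue;
      build_column(e.i, e.j, col);
      bool paired = false;
      while (!col.empty()) {
        const Tri& piv = col.back();
        int64_t key = tri_key(piv.i, piv.j, piv.k, n);
        auto it = pivot_owner.find(key);
        if (it == pivot_owner.end()) {
          if (piv.d > e.d) {
            h1_birth.push_back(e.d);
            h1_death.push_back(piv.d);
          }
          pivot_owner.emplace(key, (int)stored.size());
          stored.push_back(col);
          paired = true;
          break;
        }
        symdiff_desc(col, stored[it->second], tmp);
      }
      if (!paired && !in_mst[eidx]) h1_ess.push_back(e.d);
    }
  };

  double used = thresh;
  if (threshold > 0) {
    reduce_h1(thresh);
  } else {
    // adaptive exact mode: start just above the largest possible birth and
    // grow until no class is left alive; the enclosing radius is a certified
    // final fallback (cone => trivial H1)
    double max_mst = (h0_death.size() > 0) ? max(h0_death) : 0.0;
    used = 2.0 * std::max(lens_bound, max_mst);
    if (used <= 0 || used > r_enc) used = r_enc;
    for (;;) {
      reduce_h1(used);
      if (h1_ess.empty() || used >= r_enc) break;
      used = std::min(2.0 * used, r_enc);
    }
    h1_ess.clear();  // exact: nothing is alive at the enclosing radius
  }

  NumericMatrix h1((int)h1_birth.size(), 2);
  for (int r = 0; r < (int)h1_birth.size(); ++r) {
    h1(r, 0) = h1_birth[r];
    h1(r, 1) = h1_death[r];
  }
  return List::create(_["h0_death"] = h0_death,
                      _["h1"] = h1,
                      _["h1_essential"] = wrap(h1_ess),
                      _["threshold"] = used);
}
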