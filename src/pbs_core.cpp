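// Core lattice-graph machinery for PBS random parcellation:
// 26-neighbourhood adjacency over a voxel mask, Dijkstra geodesics,
// truncated searches for the local-density field, farthest-point seed
// placement and best-first region growing under the density-weighted
// distance D(i,j) = 2 G(i,j) / (L(i) + L(j)).
//
// Nodes are mask voxels ordered by ascending 0-based linear index
// (lin = x + sx*(y + sy*z)); all indices crossing the R boundary are
// 0-based unless noted.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
#include <cstdint>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 26-neighbourhood offsets with lattice step weights 1, sqrt(2), sqrt(3)
struct NbOffset { int dx, dy, dz; double w; };

static std::vector<NbOffset> neighbour_offsets() {
  std::vector<NbOffset> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int a = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (a == 0) continue;
        off.push_back({dx, dy, dz, std::sqrt((double)a)});
      }
  return off;
}

// [[Rcpp::export]]
IntegerVector cpp_components(IntegerVector dim, IntegerVector idx0) {
  const int sx = dim[0], sy = dim[1], sz = dim[2];
  const R_xlen_t V = idx0.size();
  const int64_t total = (int64_t)sx * sy * sz;
  std::vector<int> node_of(total, -1);
  for (R_xlen_t v = 0; v < V; ++v) node_of[idx0[v]] = (int)v;
  std::vector<NbOffset> off = neighbour_offsets();

  IntegerVector comp(V, 0);
  int ncomp = 0;
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < V; ++s) {
    if (comp[s]) continue;
    comp[s] = ++ncomp;
    stack.push_back((int)s);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int64_t lin = idx0[v];
      int x = (int)(lin % sx), y = (int)((lin / sx) % sy), z = (int)(lin / ((int64_t)sx * sy));
      for (const auto& o : off) {
        int nx = x + o.dx, ny = y + o.dy, nz = z + o.dz;
        if (nx < 0 || ny < 0 || nz < 0 || nx >= sx || ny >= sy || nz >= sz) continue;
        int u = node_of[nx + (int64_t)sx * (ny + (int64_t)sy * nz)];
        if (u >= 0 && !comp[u]) { comp[u] = ncomp; stack.push_back(u); }
      }
    }
  }
  return comp;
}

// CSR adjacency over mask voxels; idx0 must be sorted ascending.
// [[Rcpp::export]]
List cpp_build_adjacency(IntegerVector dim, IntegerVector idx0) {
  const int sx = dim[0], sy = dim[1], sz = dim[2];
  const R_xlen_t V = idx0.size();
  const int64_t total = (int64_t)sx * sy * sz;
  std::vector<int> node_of(total, -1);
  for (R_xlen_t v = 0; v < V; ++v) node_of[idx0[v]] = (int)v;
  std::vector<NbOffset> off = neighbour_offsets();

  std::vector<int> nbr;
  std::vector<double> wt;
  IntegerVector ptr(V + 1);
  nbr.reserve((size_t)V * 18);
  wt.reserve((size_t)V * 18);
  for (R_xlen_t v = 0; v < V; ++v) {
    ptr[v] = (int)nbr.size();
    int64_t lin = idx0[v];
    int x = (int)(lin % sx), y = (int)((lin / sx) % sy), z = (int)(lin / ((int64_t)sx * sy));
    for (const auto& o : off) {
      int nx = x + o.dx, ny = y + o.dy, nz = z + o.dz;
      if (nx < 0 || ny < 0 || nz < 0 || nx >= sx || ny >= sy || nz >= sz) continue;
      int u = node_of[nx + (int64_t)sx * (ny + (int64_t)sy * nz)];
      if (u >= 0) { nbr.push_back(u); wt.push_back(o.w); }
    }
  }
  ptr[V] = (int)nbr.size();
  return List::create(_["ptr"] = ptr,
                      _["nbr"] = IntegerVector(nbr.begin(), nbr.end()),
                      _["wt"] = NumericVector(wt.begin(), wt.end()));
}

typedef std::pair<double, int> HeapItem; // (dist, node)

static void dijkstra(const int* ptr, const int* nbr, const double* wt,
                     int V, const std::vector<int>& sources,
                     std::vector<double>& dist) {
  dist.assign(V, INF);
  std::priority_queue<HeapItem, std::vector<HeapItem>, std::greater<HeapItem> > pq;
  for (int s : sources) { dist[s] = 0.0; pq.push({0.0, s}); }
  while (!pq.empty()) {
    HeapItem top = pq.top(); pq.pop();
    double d = top.first; int v = top.second;
    if (d > dist[v]) continue;
    for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
      int u = nbr[e];
      double nd = d + wt[e];
      if (nd < dist[u]) { dist[u] = nd; pq.push({nd, u}); }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_dijkstra(IntegerVector ptr, IntegerVector nbr,
                           NumericVector wt, IntegerVector sources0) {
  int V = ptr.size() - 1;
  std::vector<int> src(sources0.begin(), sources0.end());
  std::vector<double> dist;
  dijkstra(ptr.begin(), nbr.begin(), wt.begin(), V, src, dist);
  return NumericVector(dist.begin(), dist.end());
}

// One full Dijkstra per source; rows = sources, columns = all nodes.
// [[Rcpp::export]]
NumericMatrix cpp_geodesic_rows(IntegerVector ptr, IntegerVector nbr,
                                NumericVector wt, IntegerVector sources0) {
  int V = ptr.size() - 1;
  int S = sources0.size();
  NumericMatrix out(S, V);
  std::vector<double> dist;
  for (int k = 0; k < S; ++k) {
    std::vector<int> src(1, sources0[k]);
    dijkstra(ptr.begin(), nbr.begin(), wt.begin(), V, src, dist);
    for (int v = 0; v < V; ++v) out(k, v) = dist[v];
  }
  return out;
}

// L(i): sum of the M smallest nonzero geodesic distances from i.
// Truncated Dijkstra settling nodes in (distance, node-index) order, so
// ties at the M-th distance resolve to the lowest linear voxel index.
// [[Rcpp::export]]
NumericVector cpp_local_density(IntegerVector ptr, IntegerVector nbr,
                                NumericVector wt, int M) {
  int V = ptr.size() - 1;
  if (M <= 0) stop("M must be positive");
  if (M >= V) stop("mask must contain more than M voxels");
  NumericVector L(V);
  const int* p = ptr.begin(); const int* nb = nbr.begin();
  const double* w = wt.begin();
  std::vector<double> dist(V, INF);
  std::vector<int> touched;
  touched.reserve(4 * M + 64);
  for (int s = 0; s < V; ++s) {
    std::priority_queue<HeapItem, std::vector<HeapItem>, std::greater<HeapItem> > pq;
    dist[s] = 0.0; touched.clear(); touched.push_back(s);
    pq.push({0.0, s});
    int settled = 0;
    double acc = 0.0;
    while (!pq.empty() && settled <= M) {
      HeapItem top = pq.top(); pq.pop();
      double d = top.first; int v = top.second;
      if (d > dist[v]) continue;
      ++settled;                       // v is settled now (source counts once)
      if (v != s) acc += d;
      if (settled > M) break;          // source + M nearest settled
      for (int e = p[v]; e < p[v + 1]; ++e) {
        int u = nb[e];
        double nd = d + w[e];
        if (nd < dist[u]) {
          if (dist[u] == INF) touched.push_back(u);
          dist[u] = nd; pq.push({nd, u});
        }
      }
    }
    if (settled <= M) stop("graph component smaller than M + 1 voxels");
    L[s] = acc;
    for (int t : touched) dist[t] = INF;
  }
  return L;
}

// Farthest-point placement under D(s,j) = 2 G(s,j) / (L(s) + L(j)).
// First seed given; each next seed maximises min_s D(s, j), ties broken
// by lowest node index. Returns 0-based seed nodes in placement order.
// [[Rcpp::export]]
IntegerVector cpp_place_seeds(IntegerVector ptr, IntegerVector nbr,
                              NumericVector wt, NumericVector L,
                              int first0, int N) {
  int V = ptr.size() - 1;
  if (N < 1 || N > V) stop("N must be between 1 and the number of voxels");
  IntegerVector seeds(N);
  std::vector<char> is_seed(V, 0);
  std::vector<double> minD(V, INF), dist;
  seeds[0] = first0; is_seed[first0] = 1;
  for (int k = 1; k < N; ++k) {
    int s = seeds[k - 1];
    std::vector<int> src(1, s);
    dijkstra(ptr.begin(), nbr.begin(), wt.begin(), V, src, dist);
    double Ls = L[s];
    for (int v = 0; v < V; ++v) {
      double d = 2.0 * dist[v] / (Ls + L[v]);
      if (d < minD[v]) minD[v] = d;
    }
    int best = -1; double bestD = -1.0;
    for (int v = 0; v < V; ++v) {
      if (is_seed[v]) continue;
      if (minD[v] > bestD) { bestD = minD[v]; best = v; }
    }
    seeds[k] = best; is_seed[best] = 1;
  }
  return seeds;
}

// Balanced iterative region growing: regions take turns in label order
// (round-robin); on its turn a region claims the unassigned frontier
// voxel with the smallest density-weighted distance from its seed
// (D = 2 g / (L(seed) + L(voxel)), g accumulated along the growth
// tree), then exposes that voxel's neighbours. A region whose frontier
// is exhausted (walled in by other regions) drops out of the cycle.
// Growing by equal voxel increments rather than equal distance is what
// keeps parcel sizes nearly equal; residual size variation comes from
// regions being blocked early. Deterministic; parcels 26-connected.
// [[Rcpp::export]]
IntegerVector cpp_grow_balanced(IntegerVector ptr, IntegerVector nbr,
                                NumericVector wt, NumericVector L,
                                IntegerVector seeds0) {
  int V = ptr.size() - 1;
  int N = seeds0.size();
  const int* p = ptr.begin(); const int* nb = nbr.begin();
  const double* w = wt.begin();
  IntegerVector label(V, 0);

  struct Cand {
    double D; int node; double g;
    bool operator>(const Cand& o) const {
      if (D != o.D) return D > o.D;
      return node > o.node;
    }
  };
  typedef std::priority_queue<Cand, std::vector<Cand>, std::greater<Cand> > Frontier;
  std::vector<Frontier> fr(N);
  std::vector<double> Lseed(N);
  std::vector<int> active;
  active.reserve(N);

  int assigned = 0;
  for (int k = 0; k < N; ++k) {
    int s = seeds0[k];
    if (label[s]) stop("duplicate seeds");
    label[s] = k + 1; ++assigned;
    Lseed[k] = L[s];
    active.push_back(k);
  }
  // expose seed neighbourhoods after all seeds are labelled
  for (int k = 0; k < N; ++k) {
    int s = seeds0[k];
    for (int e = p[s]; e < p[s + 1]; ++e) {
      int u = nb[e];
      if (!label[u])
        fr[k].push({2.0 * w[e] / (Lseed[k] + L[u]), u, w[e]});
    }
  }
  while (assigned < V && !active.empty()) {
    std::vector<int> next;
    next.reserve(active.size());
    for (int k : active) {
      Frontier& q = fr[k];
      while (!q.empty() && label[q.top().node]) q.pop();
      if (q.empty()) continue;           // region walled in
      Cand c = q.top(); q.pop();
      label[c.node] = k + 1; ++assigned;
      for (int e = p[c.node]; e < p[c.node + 1]; ++e) {
        int u = nb[e];
        if (!label[u]) {
          double g = c.g + w[e];
          q.push({2.0 * g / (Lseed[k] + L[u]), u, g});
        }
      }
      next.push_back(k);
    }
    active.swap(next);
  }
  return label;
}

// Region growing: simultaneous best-first front propagation from all
// seeds, fronts ordered by the density-weighted distance accumulated
// along the propagation tree (D = 2 g / (L(seed) + L(voxel)), g the
// geodesic length of the tree path). A voxel joins the parcel whose
// front reaches it with the smallest D; ties broken by lower seed
// label, then lower node index. Each parcel is 26-connected by
// construction (every voxel attaches through an already-labelled
// neighbour). Returns 1-based labels in seed placement order.
// [[Rcpp::export]]
IntegerVector cpp_grow(IntegerVector ptr, IntegerVector nbr,
                       NumericVector wt, NumericVector L,
                       IntegerVector seeds0) {
  int V = ptr.size() - 1;
  int N = seeds0.size();
  const int* p = ptr.begin(); const int* nb = nbr.begin();
  const double* w = wt.begin();
  IntegerVector label(V, 0);
  std::vector<double> gbest(V, INF);

  // heap items: (D, label, node, g)
  struct Item {
    double D; int lab; int node; double g;
    bool operator>(const Item& o) const {
      if (D != o.D) return D > o.D;
      if (lab != o.lab) return lab > o.lab;
      return node > o.node;
    }
  };
  std::priority_queue<Item, std::vector<Item>, std::greater<Item> > pq;
  std::vector<double> Lseed(N);
  for (int k = 0; k < N; ++k) {
    int s = seeds0[k];
    if (label[s]) stop("duplicate seeds");
    Lseed[k] = L[s];
    pq.push({0.0, k + 1, s, 0.0});
  }
  int assigned = 0;
  while (!pq.empty() && assigned < V) {
    Item it = pq.top(); pq.pop();
    int v = it.node;
    if (label[v]) continue;
    label[v] = it.lab; gbest[v] = it.g; ++assigned;
    double Ls = Lseed[it.lab - 1];
    for (int e = p[v]; e < p[v + 1]; ++e) {
      int u = nb[e];
      if (label[u]) continue;
      double g = it.g + w[e];
      pq.push({2.0 * g / (Ls + L[u]), it.lab, u, g});
    }
  }
  return label;
}
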