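// Persistence pairing for a filtered simplicial complex of dimension <= 2
// by the standard boundary-matrix column reduction over GF(2), with
// R = D V bookkeeping restricted to edge columns so that every
// 1-dimensional class carries the representative cycle it was born with.
//
// The stream is assumed sorted by (filtration value, dimension,
// lexicographic vertices) and face-closed; both are validated in R.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// symmetric difference of two ascending index lists (GF(2) column add)
static std::vector<int> symdiff(const std::vector<int>& a,
                                const std::vector<int>& b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) out.push_back(a[i++]);
    else if (b[j] < a[i]) out.push_back(b[j++]);
    else { ++i; ++j; }
  }
  while (i < a.size()) out.push_back(a[i++]);
  while (j < b.size()) out.push_back(b[j++]);
  return out;
}

// [[Rcpp::export]]
List ph_reduce_cpp(IntegerVector dim, IntegerMatrix verts, NumericVector value,
                   int n_vertices) {
  const int m = dim.size();
  std::vector<int> vertex_pos(n_vertices, -1);
  std::unordered_map<long long, int> edge_pos;
  edge_pos.reserve(2 * m);
  const long long n = n_vertices;

  for (int j = 0; j < m; ++j) {
    if (dim[j] == 0) {
      vertex_pos[verts(j, 0)] = j;
    } else if (dim[j] == 1) {
      edge_pos[(long long)verts(j, 0) * n + verts(j, 1)] = j;
    }
  }

  // low_inv[l] = index of the reduced column whose lowest row is l
  std::vector<int> low_inv(m, -1);
  std::vector<std::vector<int>> R_col(m);
  // V bookkeeping for edge columns only: V_col[j] = edges summed into col j
  std::unordered_map<int, std::vector<int>> V_col;

  std::vector<double> vertex_death(m, R_PosInf);      // by vertex position
  std::vector<int> creators1;                          // edge positions, birth order
  std::unordered_map<int, double> death1;              // creator edge -> death
  std::unordered_map<int, std::vector<int>> rep1;      // creator edge -> cycle edges

  std::vector<int> col;
  for (int j = 0; j < m; ++j) {
    const int dj = dim[j];
    if (dj == 0) continue;

    col.clear();
    if (dj == 1) {
      int a = vertex_pos[verts(j, 0)], b = vertex_pos[verts(j, 1)];
      if (a < 0 || b < 0) stop("face closure violated: missing vertex of edge at position %d", j + 1);
      if (a >= j || b >= j) stop("face closure violated: vertex after edge at position %d", j + 1);
      if (a > b) std::swap(a, b);
      col.push_back(a); col.push_back(b);
    } else {
      long long k01 = (long long)verts(j, 0) * n + verts(j, 1);
      long long k02 = (long long)verts(j, 0) * n + verts(j, 2);
      long long k12 = (long long)verts(j, 1) * n + verts(j, 2);
      auto e01 = edge_pos.find(k01), e02 = edge_pos.find(k02), e12 = edge_pos.find(k12);
      if (e01 == edge_pos.end() || e02 == edge_pos.end() || e12 == edge_pos.end())
        stop("face closure violated: missing edge of triangle at position %d", j + 1);
      col.push_back(e01->second); col.push_back(e02->second); col.push_back(e12->second);
      std::sort(col.begin(), col.end());
      if (col.back() >= j) stop("face closure violated: edge after triangle at position %d", j + 1);
    }

    std::vector<int> v;
    if (dj == 1) v.push_back(j);

    std::vector<int> work = col;
    while (!work.empty()) {
      int low = work.back();
      int k = low_inv[low];
      if (k < 0) break;
      work = symdiff(work, R_col[k]);
      if (dj == 1) v = symdiff(v, V_col[k]);
    }

    if (work.empty()) {
      if (dj == 1) {             // edge closes a loop: a 1-class is born
        creators1.push_back(j);
        rep1[j] = v;
      }                          // a trivial triangle column would start a
                                 // 2-class; dimension 2 homology is not tracked
    } else {
      int low = work.back();
      low_inv[low] = j;
      R_col[j] = std::move(work);
      if (dj == 1) {
        V_col[j] = std::move(v);
        // edge merges two components: vertex `low` (the younger) dies
        vertex_death[low] = value[j];
      } else {
        // triangle fills the 1-class created by edge `low`
        death1[low] = value[j];
      }
    }
  }

  // dim-0 intervals: one per vertex (elder rule), birth 0
  IntegerVector v0(n_vertices);
  NumericVector d0(n_vertices);
  for (int v = 0; v < n_vertices; ++v) {
    v0[v] = v;
    d0[v] = vertex_death[vertex_pos[v]];
  }

  const int n1 = creators1.size();
  NumericVector b1(n1), dd1(n1);
  List reps(n1);
  for (int i = 0; i < n1; ++i) {
    int e = creators1[i];
    b1[i] = value[e];
    auto it = death1.find(e);
    dd1[i] = (it == death1.end()) ? R_PosInf : it->second;
    const std::vector<int>& cyc = rep1[e];
    IntegerMatrix edges(cyc.size(), 2);
    for (size_t k = 0; k < cyc.size(); ++k) {
      edges(k, 0) = verts(cyc[k], 0);
      edges(k, 1) = verts(cyc[k], 1);
    }
    reps[i] = edges;
  }

  return List::create(
    _["vertex"] = v0, _["death0"] = d0,
    _["birth1"] = b1, _["death1"] = dd1, _["reps"] = reps);
}
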