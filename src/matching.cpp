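#include <Rcpp.h>
#include <functional>
#include <map>
using namespace Rcpp;

// Greedy one-to-one matching of two sorted integer band lists within +/- tol.
// Two-pointer sweep: match when |a[i]-b[j]| <= tol, otherwise advance the
// pointer at the smaller mobility (ties resolved toward the lower mobility by
// construction). For tol = 0 this is exact multiset intersection.
static int match_count_sorted(const int* a, int na, const int* b, int nb,
                              int tol) {
  int i = 0, j = 0, m = 0;
  while (i < na && j < nb) {
    int d = a[i] - b[j];
    if (d < 0) d = -d;
    if (d <= tol) {
      ++m; ++i; ++j;
    } else if (a[i] < b[j]) {
      ++i;
    } else {
      ++j;
    }
  }
  return m;
}

// [[Rcpp::export]]
int match_count_cpp(IntegerVector a, IntegerVector b, int tol) {
  return match_count_sorted(INTEGER(a), a.size(), INTEGER(b), b.size(), tol);
}

// Matched index pairs (1-based) under the same greedy sweep.
// [[Rcpp::export]]
IntegerMatrix match_pairs_cpp(IntegerVector a, IntegerVector b, int tol) {
  int na = a.size(), nb = b.size();
  std::vector<int> ia, ib;
  int i = 0, j = 0;
  while (i < na && j < nb) {
    int d = a[i] - b[j];
    if (d < 0) d = -d;
    if (d <= tol) {
      ia.push_back(i + 1); ib.push_back(j + 1); ++i; ++j;
    } else if (a[i] < b[j]) {
      ++i;
    } else {
      ++j;
    }
  }
  IntegerMatrix out(ia.size(), 2);
  for (size_t r = 0; r < ia.size(); ++r) { out(r, 0) = ia[r]; out(r, 1) = ib[r]; }
  return out;
}

// All-pairs significant overlaps. fps is a list of sorted integer vectors.
// p = (2 tol + 1) / GL; per pair q = 1 - (1-p)^nH and
// S = P(Binom(nL, q) >= m), the Sulston probability of m or more chance
// coincidences. Returns pairs with S <= cutoff as (i, j, m, S).
// [[Rcpp::export]]
DataFrame overlap_edges_cpp(List fps, int tol, double gl, double cutoff) {
  int n = fps.size();
  std::vector<const int*> ptr(n);
  std::vector<int> len(n);
  std::vector<IntegerVector> keep(n);
  for (int i = 0; i < n; ++i) {
    keep[i] = as<IntegerVector>(fps[i]);
    ptr[i] = INTEGER(keep[i]);
    len[i] = keep[i].size();
  }
  double p = (2.0 * tol + 1.0) / gl;
  std::vector<int> vi, vj, vm;
  std::vector<double> vs;
  for (int i = 0; i < n - 1; ++i) {
    if (len[i] == 0) continue;
    for (int j = i + 1; j < n; ++j) {
      if (len[j] == 0) continue;
      int m = match_count_sorted(ptr[i], len[i], ptr[j], len[j], tol);
      if (m == 0) continue;
      int nL = len[i] < len[j] ? len[i] : len[j];
      int nH = len[i] < len[j] ? len[j] : len[i];
      double q = 1.0 - std::pow(1.0 - p, (double)nH);
      double S = R::pbinom(m - 1.0, (double)nL, q, 0, 0);
      if (S <= cutoff) {
        vi.push_back(i + 1); vj.push_back(j + 1);
        vm.push_back(m); vs.push_back(S);
      }
    }
  }
  return DataFrame::create(_["i"] = vi, _["j"] = vj, _["m"] = vm, _["S"] = vs);
}

// Consensus-band clustering for one contig. fps: list of sorted integer
// band vectors (contig members, in order); ea/eb: 1-based member indices of
// the significant edges, pre-sorted strongest-first; off: member offsets
// (band units). Bands matched between two clones are united into one
// consensus cluster unless (a) the two clusters already share a clone, or
// (b) their feasible position intervals (intersection of member clone
// spans, with slack) are disjoint. Returns a 1-based cluster index per
// band slot (slots flattened in member order).
// [[Rcpp::export]]
IntegerVector cb_clusters_cpp(List fps, IntegerVector ea, IntegerVector eb,
                              int tol, NumericVector off, double slack) {
  int n = fps.size();
  std::vector<IntegerVector> keep(n);
  std::vector<const int*> ptr(n);
  std::vector<int> len(n), base(n);
  int total = 0;
  for (int i = 0; i < n; ++i) {
    keep[i] = as<IntegerVector>(fps[i]);
    ptr[i] = INTEGER(keep[i]);
    len[i] = keep[i].size();
    base[i] = total;
    total += len[i];
  }
  std::vector<int> parent(total), sz(total, 1);
  std::vector<double> lo(total), hi(total);
  std::vector<std::vector<int> > members(total);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < len[i]; ++s) {
      int slot = base[i] + s;
      parent[slot] = slot;
      lo[slot] = off[i];
      hi[slot] = off[i] + len[i];
      members[slot].push_back(i);
    }
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  int ne = ea.size();
  for (int r = 0; r < ne; ++r) {
    int a = ea[r] - 1, b = eb[r] - 1;
    int i = 0, j = 0;
    while (i < len[a] && j < len[b]) {
      int d = ptr[a][i] - ptr[b][j];
      int ad = d < 0 ? -d : d;
      if (ad <= tol) {
        int ra = find(base[a] + i), rb = find(base[b] + j);
        if (ra != rb) {
          if (sz[ra] < sz[rb]) std::swap(ra, rb);
          bool shared = false;
          for (size_t u = 0; u < members[rb].size() && !shared; ++u)
            for (size_t v = 0; v < members[ra].size(); ++v)
              if (members[rb][u] == members[ra][v]) { shared = true; break; }
          double nlo = std::max(lo[ra], lo[rb]);
          double nhi = std::min(hi[ra], hi[rb]);
          if (!shared && nlo <= nhi + slack) {
            parent[rb] = ra;
            sz[ra] += sz[rb];
            members[ra].insert(members[ra].end(), members[rb].begin(),
                               members[rb].end());
            members[rb].clear();
            lo[ra] = nlo; hi[ra] = nhi;
          }
        }
        ++i; ++j;
      } else if (ptr[a][i] < ptr[b][j]) {
        ++i;
      } else {
        ++j;
      }
    }
  }
  IntegerVector out(total);
  std::map<int, int> relab;
  for (int s = 0; s < total; ++s) {
    int r = find(s);
    std::map<int, int>::iterator it = relab.find(r);
    int id;
    if (it == relab.end()) { id = relab.size() + 1; relab[r] = id; }
    else id = it->second;
    out[s] = id;
  }
  return out;
}
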