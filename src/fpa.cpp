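#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <map>
#include <set>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

// Nodes of one degree, bucketed by tree order R (depth); depth keys ascending.
struct DegClass {
  std::map<int, std::vector<int> > buckets;
  long count;
  DegClass() : count(0) {}
};

// Snapshot of the candidate pool for one growth step. Together the segments
// describe the top-n nodes under the ordering (degree desc, depth asc, random
// among ties):
//   kind 0: an entire degree class (all depths)
//   kind 1: an entire depth bucket of the boundary degree
//   kind 2: a uniform-random cnt-subset of the boundary depth bucket
// Sampling proportionally to degree over this snapshot is distributionally
// identical to materialising the ranked pool: within a degree class every
// member has the same weight, and the random subset of the cut bucket is
// exchangeable, so drawing "uniform within the bucket" with the subset's
// residual weight reproduces the law of a draw without listing the subset.
struct Seg {
  int kind;
  int degree;
  int depth;  // only for kind 1/2
  long cnt;   // remaining selectable members
  double w;   // remaining weight = degree * cnt
};

inline long rint_below(double u, long n) {
  long k = (long)(u * (double)n);
  return k >= n ? n - 1 : (k < 0 ? 0 : k);
}

// Pool size n_{j-1} = max(1, ceil(f*e)); the epsilon guards against binary
// representation of f pushing an exact product just above an integer.
inline long pool_n(long e, double f) {
  long k = (long)std::ceil(f * (double)e - 1e-9);
  if (k < 1) k = 1;
  if (k > e) k = e;
  return k;
}

class Growth {
public:
  Growth(int n, int m, double f, int m0)
      : n_(n), m_(m), f_(f), m0_(m0), nn_(0),
        deg_(n, 0), parent_(n, -1), depth_(n, 0), pos_(n, 0) {
    size_t emax = (size_t)(m0 - 1) + (size_t)(n - m0) * (size_t)m;
    esrc_.reserve(emax);
    edst_.reserve(emax);
    // Seed star on m0 nodes: node 0 is the centre/root.
    deg_[0] = m0 - 1;
    parent_[0] = -1;
    depth_[0] = 0;
    for (int v = 1; v < m0; ++v) {
      deg_[v] = 1;
      parent_[v] = 0;
      depth_[v] = 1;
      esrc_.push_back(0);
      edst_.push_back(v);
    }
    nn_ = m0;
    for (int v = 0; v < m0; ++v) bucket_insert(v);
  }

  void run() {
    while (nn_ < n_) step();
  }

  List result() const {
    size_t ne = esrc_.size();
    IntegerMatrix edges((int)ne, 2);
    for (size_t i = 0; i < ne; ++i) {
      edges((int)i, 0) = esrc_[i] + 1;
      edges((int)i, 1) = edst_[i] + 1;
    }
    IntegerVector deg(deg_.begin(), deg_.end());
    IntegerVector par(n_), dep(depth_.begin(), depth_.end());
    for (int v = 0; v < n_; ++v)
      par[v] = parent_[v] < 0 ? NA_INTEGER : parent_[v] + 1;
    return List::create(_["edges"] = edges, _["degree"] = deg,
                        _["parent"] = par, _["depth"] = dep);
  }

private:
  int n_, m_;
  double f_;
  int m0_, nn_;
  std::vector<int> deg_, parent_, depth_, pos_;
  std::vector<int> esrc_, edst_;
  std::unordered_map<int, DegClass> classes_;
  std::set<int> degset_;

  void bucket_insert(int v) {
    DegClass &dc = classes_[deg_[v]];
    if (dc.count == 0) degset_.insert(deg_[v]);
    std::vector<int> &b = dc.buckets[depth_[v]];
    pos_[v] = (int)b.size();
    b.push_back(v);
    dc.count++;
  }

  void bucket_remove(int v) {
    DegClass &dc = classes_[deg_[v]];
    std::vector<int> &b = dc.buckets[depth_[v]];
    int p = pos_[v];
    int last = b.back();
    b[p] = last;
    pos_[last] = p;
    b.pop_back();
    if (b.empty()) dc.buckets.erase(depth_[v]);
    dc.count--;
    if (dc.count == 0) {
      classes_.erase(deg_[v]);
      degset_.erase(deg_[v]);
    }
  }

  // Top-n snapshot: walk occupied degrees from the highest down; split the
  // boundary degree class by depth (lower depth first), cutting the last
  // bucket randomly.
  std::vector<Seg> build_pool(long npool, double &W) {
    std::vector<Seg> segs;
    W = 0.0;
    long covered = 0;
    for (std::set<int>::reverse_iterator it = degset_.rbegin();
         it != degset_.rend() && covered < npool; ++it) {
      int d = *it;
      DegClass &dc = classes_[d];
      if (covered + dc.count <= npool) {
        Seg s = {0, d, 0, dc.count, (double)d * dc.count};
        segs.push_back(s);
        covered += dc.count;
      } else {
        long t = npool - covered;
        for (std::map<int, std::vector<int> >::iterator bk = dc.buckets.begin();
             bk != dc.buckets.end() && t > 0; ++bk) {
          long bs = (long)bk->second.size();
          if (t >= bs) {
            Seg s = {1, d, bk->first, bs, (double)d * bs};
            segs.push_back(s);
            t -= bs;
          } else {
            Seg s = {2, d, bk->first, t, (double)d * t};
            segs.push_back(s);
            t = 0;
          }
        }
        covered = npool;
      }
    }
    for (size_t i = 0; i < segs.size(); ++i) W += segs[i].w;
    return segs;
  }

  int pick_member(const Seg &s, const std::vector<int> &drawn) {
    for (;;) {
      int v = -1;
      if (s.kind == 0) {
        DegClass &dc = classes_[s.degree];
        long idx = rint_below(unif_rand(), dc.count);
        for (std::map<int, std::vector<int> >::iterator bk = dc.buckets.begin();
             bk != dc.buckets.end(); ++bk) {
          if (idx < (long)bk->second.size()) {
            v = bk->second[idx];
            break;
          }
          idx -= (long)bk->second.size();
        }
      } else {
        std::vector<int> &b = classes_[s.degree].buckets[s.depth];
        v = b[rint_below(unif_rand(), (long)b.size())];
      }
      if (std::find(drawn.begin(), drawn.end(), v) == drawn.end()) return v;
    }
  }

  void collect_all(const Seg &s, std::vector<int> &out) {
    if (s.kind == 0) {
      DegClass &dc = classes_[s.degree];
      for (std::map<int, std::vector<int> >::iterator bk = dc.buckets.begin();
           bk != dc.buckets.end(); ++bk)
        out.insert(out.end(), bk->second.begin(), bk->second.end());
    } else if (s.kind == 1) {
      std::vector<int> &b = classes_[s.degree].buckets[s.depth];
      out.insert(out.end(), b.begin(), b.end());
    } else {
      // random cnt-subset of the cut bucket (partial Fisher-Yates)
      std::vector<int> b = classes_[s.degree].buckets[s.depth];
      long B = (long)b.size();
      for (long i = 0; i < s.cnt; ++i) {
        long idx = i + rint_below(unif_rand(), B - i);
        std::swap(b[i], b[idx]);
        out.push_back(b[i]);
      }
    }
  }

  void step() {
    int j = nn_;
    long e = j;
    long npool = pool_n(e, f_);
    double W = 0.0;
    std::vector<Seg> segs = build_pool(npool, W);

    std::vector<int> cand;
    std::vector<int> none;
    if (npool <= (long)m_) {
      // degenerate early steps: the whole pool is drawn
      for (size_t i = 0; i < segs.size(); ++i) collect_all(segs[i], cand);
    } else {
      // m independent degree-proportional draws (Eq.-per-link semantics);
      // duplicate endpoints collapse after redirection
      for (int t = 0; t < m_; ++t) {
        double u = unif_rand() * W;
        size_t si = 0;
        double acc = 0.0;
        for (size_t k = 0; k < segs.size(); ++k) {
          if (segs[k].cnt == 0) continue;
          acc += segs[k].w;
          si = k;
          if (u <= acc) break;  // else numerical fallback: last segment
        }
        cand.push_back(pick_member(segs[si], none));
      }
    }

    // parent-comparison redirection, then de-duplication of endpoints
    std::vector<int> ends;
    for (size_t i = 0; i < cand.size(); ++i) {
      int c = cand[i];
      int r = c;
      if (parent_[c] >= 0 && deg_[c] > deg_[parent_[c]]) r = parent_[c];
      if (std::find(ends.begin(), ends.end(), r) == ends.end())
        ends.push_back(r);
    }

    parent_[j] = ends[0];
    depth_[j] = depth_[ends[0]] + 1;
    for (size_t i = 0; i < ends.size(); ++i) {
      esrc_.push_back(j);
      edst_.push_back(ends[i]);
    }
    // degrees were frozen during the step; update them now
    for (size_t i = 0; i < ends.size(); ++i) {
      int u2 = ends[i];
      bucket_remove(u2);
      deg_[u2]++;
      bucket_insert(u2);
    }
    deg_[j] = (int)ends.size();
    bucket_insert(j);
    nn_++;
  }
};

}  // namespace

// [[Rcpp::export]]
List fpa_generate_cpp(int n, int m, double f, int m0) {
  if (m < 1) stop("m must be >= 1");
  if (!(f > 0.0 && f <= 1.0)) stop("f must be in (0, 1]");
  if (m0 < 2 || m0 < m + 1) stop("m0 must satisfy m0 >= max(2, m + 1)");
  if (n <= m0) stop("n must exceed the seed size m0");
  Growth g(n, m, f, m0);
  g.run();
  return g.result();
}

// Random sequential box covering. `head`/`adj` is the CSR adjacency of an
// undirected graph (0-based); for each r in r_values and each of n_rep
// independent seed sequences, uncovered seeds are drawn uniformly and each
// cluster absorbs every still-uncovered node within full-network shortest-path
// distance <= r-1 of its seed. Returns the cluster counts (n_rep x length(r)).
// [[Rcpp::export]]
IntegerMatrix box_cover_cpp(IntegerVector head, IntegerVector adj,
                            IntegerVector r_values, int n_rep) {
  int n = head.size() - 1;
  if (n < 1) stop("empty graph");
  if (n_rep < 1) stop("n_rep must be >= 1");
  IntegerMatrix qc(n_rep, r_values.size());
  std::vector<int> covered(n), avail(n), queue(n), mark(n, -1), bdist(n, 0);
  int bfs_id = 0;
  for (int ri = 0; ri < r_values.size(); ++ri) {
    int r = r_values[ri];
    if (r < 1) stop("r must be >= 1");
    for (int rep = 0; rep < n_rep; ++rep) {
      std::fill(covered.begin(), covered.end(), 0);
      for (int i = 0; i < n; ++i) avail[i] = i;
      long a = n, ncov = 0;
      int q = 0;
      while (ncov < n) {
        long idx = rint_below(unif_rand(), a);
        int s = avail[idx];
        avail[idx] = avail[--a];
        if (covered[s]) continue;  // uniform over uncovered, by rejection
        ++q;
        ++bfs_id;
        int qh = 0, qt = 0;
        queue[qt++] = s;
        mark[s] = bfs_id;
        bdist[s] = 0;
        covered[s] = 1;
        ++ncov;
        while (qh < qt) {
          int v = queue[qh++];
          if (bdist[v] >= r - 1) continue;
          for (int ei = head[v]; ei < head[v + 1]; ++ei) {
            int w = adj[ei];
            if (mark[w] == bfs_id) continue;
            mark[w] = bfs_id;
            bdist[w] = bdist[v] + 1;
            queue[qt++] = w;
            if (!covered[w]) {
              covered[w] = 1;
              ++ncov;
            }
          }
        }
      }
      qc(rep, ri) = q;
    }
  }
  return qc;
}
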