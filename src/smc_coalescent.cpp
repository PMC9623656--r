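#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Sequentially Markov coalescent (SMC) over a grid of discrete loci.
//
// Time is measured in units of 2N generations, so with k lineages the
// coalescence rate is k(k-1)/2.  Between adjacent loci at genetic distance
// d Morgans, recombination hits the current tree at rate (rho/2) * L with
// rho = 4 * Ne * d and L the total branch length; each hit triggers a
// subtree-prune-regraft move (prune the branch above the recombination
// point, re-coalesce the floating lineage into the remaining tree).
// Mutations are dropped per locus as Poisson((theta_l/2) * L), each placed
// uniformly on the branches; every mutation yields one biallelic site whose
// derived allele is carried by the leaves below it.  All randomness comes
// from R's RNG stream, so set.seed() on the R side gives bit-identical
// output.

namespace {

struct Tree {
  int n;  // leaves (haplotypes)
  std::vector<int> parent, lchild, rchild;
  std::vector<double> tm;
  int root;
  explicit Tree(int n_)
      : n(n_), parent(2 * n_ - 1, -1), lchild(2 * n_ - 1, -1),
        rchild(2 * n_ - 1, -1), tm(2 * n_ - 1, 0.0), root(-1) {}
  int size() const { return 2 * n - 1; }
};

double total_length(const Tree& T) {
  double L = 0.0;
  for (int v = 0; v < T.size(); ++v)
    if (v != T.root) L += T.tm[T.parent[v]] - T.tm[v];
  return L;
}

// Standard Kingman coalescent tree for n leaves.
void kingman(Tree& T) {
  const int n = T.n;
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  double t = 0.0;
  int nxt = n;
  for (int k = n; k > 1; --k) {
    t += R::rexp(2.0 / (static_cast<double>(k) * (k - 1)));
    int i = static_cast<int>(R::unif_rand() * k);
    if (i == k) i = k - 1;
    int a = active[i];
    active[i] = active[k - 1];
    int j = static_cast<int>(R::unif_rand() * (k - 1));
    if (j == k - 1) j = k - 2;
    int b = active[j];
    T.tm[nxt] = t;
    T.lchild[nxt] = a;
    T.rchild[nxt] = b;
    T.parent[a] = nxt;
    T.parent[b] = nxt;
    active[j] = nxt;
    ++nxt;
  }
  T.root = nxt - 1;
  T.parent[T.root] = -1;
}

// Pick a point uniformly on the branches; returns the node below the chosen
// branch and writes the height of the point into *height.
int pick_point(const Tree& T, double* height) {
  const int nn = T.size();
  std::vector<double> cum(nn, 0.0);
  double L = 0.0;
  for (int v = 0; v < nn; ++v) {
    double bl = (v == T.root) ? 0.0 : (T.tm[T.parent[v]] - T.tm[v]);
    L += bl;
    cum[v] = L;
  }
  double u = R::unif_rand() * L;
  int v = static_cast<int>(
      std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
  if (v >= nn) v = nn - 1;
  while (v == T.root) {  // zero-length "branch"; step off it
    v = (v + 1) % nn;
  }
  double before = (v == 0) ? 0.0 : cum[v - 1];
  *height = T.tm[v] + (u - before);
  if (*height < T.tm[v]) *height = T.tm[v];
  return v;
}

void mark_subtree(const Tree& T, int v, std::vector<char>& mark) {
  std::vector<int> st;
  st.push_back(v);
  while (!st.empty()) {
    int u = st.back();
    st.pop_back();
    mark[u] = 1;
    if (T.lchild[u] >= 0) {
      st.push_back(T.lchild[u]);
      st.push_back(T.rchild[u]);
    }
  }
}

// One SMC' recombination event.  A recombination point is chosen uniformly
// on the branches; the lineage above the point detaches and re-coalesces
// with the lineages of the local tree, where in the interval up to the old
// parent node the original (not yet pruned) branch counts as a partner:
// back-coalescence onto it leaves the tree unchanged.  Unlike the plain
// SMC, this move has the Kingman coalescent as its exact stationary
// distribution, so the marginal tree at every locus stays coalescent.
void spr_once(Tree& T) {
  const int nn = T.size();
  double tr;
  int v = pick_point(T, &tr);
  int p = T.parent[v];
  int s = (T.lchild[p] == v) ? T.rchild[p] : T.lchild[p];
  int g = T.parent[p];
  double tp = T.tm[p];

  // counting is done on the notional pruned tree (p removed, sibling branch
  // extended to the grandparent) without mutating T yet
  std::vector<char> mark(nn, 0);
  mark_subtree(T, v, mark);  // floating lineage
  mark[p] = 1;
  int eff_root = (p == T.root) ? s : T.root;
  auto eff_parent = [&](int w) {
    int pw = T.parent[w];
    return (pw == p) ? g : pw;
  };
  auto crosses = [&](int w, double t) {
    if (mark[w] || T.tm[w] > t) return false;
    if (w == eff_root) return true;
    int pw = eff_parent(w);
    return pw >= 0 && T.tm[pw] > t;
  };

  // pruned-tree lineage count is piecewise constant above tr: it drops by
  // one at each remaining internal node time and stays 1 above the root;
  // the old branch adds one extra partner below its parent time tp.
  std::vector<double> bp;
  int k = 0;
  for (int w = 0; w < nn; ++w) {
    if (mark[w]) continue;
    if (T.lchild[w] >= 0 && T.tm[w] > tr) bp.push_back(T.tm[w]);
    if (crosses(w, tr)) ++k;
  }
  std::sort(bp.begin(), bp.end());

  double t = tr, tc = tr;
  std::size_t bi = 0;
  int extra = (tr < tp) ? 1 : 0;
  for (;;) {
    double nxt = (bi < bp.size()) ? bp[bi] : R_PosInf;
    if (extra && tp < nxt) nxt = tp;
    double e = R::rexp(1.0 / (k + extra));
    if (t + e < nxt) { tc = t + e; break; }
    t = nxt;
    if (extra && nxt == tp) {
      extra = 0;
    } else {
      ++bi;
      if (k > 1) --k;
    }
  }

  if (extra && R::unif_rand() * (k + 1) < 1.0) {
    return;  // back-coalescence onto the original branch: tree unchanged
  }

  std::vector<int> crossing;
  for (int w = 0; w < nn; ++w)
    if (crosses(w, tc)) crossing.push_back(w);
  int ci = static_cast<int>(R::unif_rand() * crossing.size());
  if (ci >= static_cast<int>(crossing.size()))
    ci = static_cast<int>(crossing.size()) - 1;
  int w = crossing[ci];

  // now mutate: prune p, then regraft the floating lineage onto branch w
  T.parent[s] = g;
  if (g >= 0) {
    if (T.lchild[g] == p) T.lchild[g] = s; else T.rchild[g] = s;
  }
  if (p == T.root) T.root = s;

  int q = (w == T.root) ? -1 : T.parent[w];
  T.tm[p] = tc;
  T.lchild[p] = v;
  T.rchild[p] = w;
  T.parent[v] = p;
  T.parent[w] = p;
  T.parent[p] = q;
  if (q >= 0) {
    if (T.lchild[q] == w) T.lchild[q] = p; else T.rchild[q] = p;
  } else {
    T.root = p;
  }
}

void leaves_below(const Tree& T, int v, std::vector<int>& out) {
  out.clear();
  std::vector<int> st;
  st.push_back(v);
  while (!st.empty()) {
    int u = st.back();
    st.pop_back();
    if (T.lchild[u] < 0) {
      out.push_back(u);
    } else {
      st.push_back(T.lchild[u]);
      st.push_back(T.rchild[u]);
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".smc_chromosome")]]
List smc_chromosome(int n_hap, int n_loci, double morgans, double ne,
                    double theta) {
  if (n_hap < 2) stop("need at least 2 haplotypes");
  if (n_loci < 1) stop("need at least 1 locus");
  Tree T(n_hap);
  kingman(T);

  const double d = morgans / n_loci;          // inter-locus distance
  const double theta_l = theta / n_loci;      // per-locus scaled mutation rate
  std::vector<std::vector<int>> carriers;
  std::vector<double> pos;
  std::vector<int> buf;

  for (int l = 0; l < n_loci; ++l) {
    if (l > 0 && ne > 0) {
      // recombination along the chromosome as a genuine point process:
      // the exponential distance to the next event is redrawn from the
      // *current* tree length after every move, so the tree process stays
      // stationary (a fixed-count batch would sample the length-biased
      // jump chain instead).
      double dist = d;
      for (;;) {
        double L = total_length(T);
        double x = R::rexp(1.0 / (2.0 * ne * L));
        if (x > dist) break;
        dist -= x;
        spr_once(T);
      }
    }
    double L = total_length(T);
    int K = static_cast<int>(R::rpois(0.5 * theta_l * L));
    double locus_pos = (l + 0.5) * d;
    for (int m = 0; m < K; ++m) {
      double h;
      int v = pick_point(T, &h);
      leaves_below(T, v, buf);
      carriers.push_back(buf);
      pos.push_back(locus_pos + d * ((m + 1.0) / (K + 1.0) - 0.5));
    }
  }

  const int S = static_cast<int>(carriers.size());
  IntegerMatrix A(n_hap, S);
  for (int s = 0; s < S; ++s)
    for (std::size_t i = 0; i < carriers[s].size(); ++i)
      A(carriers[s][i], s) = 1;
  return List::create(_["alleles"] = A,
                      _["pos"] = NumericVector(pos.begin(), pos.end()));
}
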