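// Structured coalescent with recombination for a small number of
// demes, plus mutation models (infinite sites / HKY) applied to the
// resulting ancestral recombination graph.
//
// Conventions (matching Hudson's ms):
//   * time in units of 4N generations; pairwise coalescence rate within a
//     deme of relative size x is 2/x, i.e. k lineages coalesce at total
//     rate k(k-1)/x
//   * rho = 4Nr over the whole locus of L discrete sites; per-link
//     recombination rate rho/(L-1) per lineage per unit time, links
//     counted over the spanned (including trapped) material
//   * demographic events: join (mass lineage movement), pulse (each
//     lineage moves with probability x; the -es/-ej admixture idiom) and
//     deme size change
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Seg {
  int left, right;   // half-open [left, right) in site coordinates
  int node;          // id of the tree node at the root of this span
  int ndesc;         // number of sample leaves below `node` on this span
};

struct Lin {
  std::vector<Seg> segs;  // sorted, disjoint
  int pop;
};

struct ArgTables {
  std::vector<double> node_time;
  std::vector<int> e_left, e_right, e_parent, e_child;
};

inline int n_links(const Lin& l) {
  return l.segs.back().right - 1 - l.segs.front().left;
}

// Merge two lineages at time t.  Overlapping ancestral material coalesces
// into a fresh node (created lazily, one per event); spans that reach all
// samples are finalized and dropped from the active material.
Lin merge_lins(const Lin& A, const Lin& B, double t, int ntot, ArgTables& arg) {
  Lin C;
  C.pop = A.pop;
  std::vector<Seg> a = A.segs, b = B.segs;
  int u = -1;
  size_t i = 0, j = 0;
  while (i < a.size() || j < b.size()) {
    if (j == b.size() || (i < a.size() && a[i].right <= b[j].left)) {
      C.segs.push_back(a[i++]);
      continue;
    }
    if (i == a.size() || b[j].right <= a[i].left) {
      C.segs.push_back(b[j++]);
      continue;
    }
    const int lo = std::max(a[i].left, b[j].left);
    const int hi = std::min(a[i].right, b[j].right);
    if (a[i].left < lo) C.segs.push_back({a[i].left, lo, a[i].node, a[i].ndesc});
    if (b[j].left < lo) C.segs.push_back({b[j].left, lo, b[j].node, b[j].ndesc});
    if (u < 0) {
      u = (int) arg.node_time.size();
      arg.node_time.push_back(t);
    }
    arg.e_left.push_back(lo); arg.e_right.push_back(hi);
    arg.e_parent.push_back(u); arg.e_child.push_back(a[i].node);
    arg.e_left.push_back(lo); arg.e_right.push_back(hi);
    arg.e_parent.push_back(u); arg.e_child.push_back(b[j].node);
    const int nd = a[i].ndesc + b[j].ndesc;
    if (nd < ntot) C.segs.push_back({lo, hi, u, nd});  // else: span found its MRCA
    if (a[i].right > hi) a[i].left = hi; else ++i;
    if (b[j].right > hi) b[j].left = hi; else ++j;
  }
  return C;
}

}  // namespace

// Simulate the ancestral recombination graph.
// ev_type: 0 = join (all lineages a -> b), 1 = pulse (each lineage in a
// moves to b with probability x), 2 = set relative size of deme a to x.
// Events must be sorted by time; ties are applied in input order.
// [[Rcpp::export(name = ".sim_arg_cpp")]]
List sim_arg_cpp(IntegerVector samples_per_pop, int L, double rho,
                 NumericVector ev_time, IntegerVector ev_type,
                 IntegerVector ev_a, IntegerVector ev_b, NumericVector ev_x,
                 int n_pop) {
  if (L < 1) stop("L must be >= 1");
  const int ntot = sum(samples_per_pop);
  std::vector<double> popsize(n_pop, 1.0);
  std::vector<Lin> lins;
  ArgTables arg;
  arg.node_time.assign(ntot, 0.0);
  int id = 0;
  for (int p = 0; p < samples_per_pop.size(); ++p)
    for (int s = 0; s < samples_per_pop[p]; ++s) {
      Lin l;
      l.pop = p;
      l.segs.push_back({0, L, id, 1});
      lins.push_back(l);
      ++id;
    }
  const double rho_link = (L > 1) ? rho / (L - 1.0) : 0.0;
  double t = 0.0;
  int iev = 0;
  const int nev = ev_time.size();
  long guard = 0;

  std::vector<double> crate(n_pop);
  std::vector<int> k(n_pop);
  std::vector<int> mem;

  while (!lins.empty()) {
    if (++guard > 100000000L) stop("coalescent failed to terminate");
    std::fill(k.begin(), k.end(), 0);
    for (auto& l : lins) k[l.pop]++;
    double coal_tot = 0.0;
    for (int p = 0; p < n_pop; ++p) {
      crate[p] = (double) k[p] * (k[p] - 1) / popsize[p];
      coal_tot += crate[p];
    }
    double links_tot = 0.0;
    for (auto& l : lins) links_tot += n_links(l);
    const double rec_tot = rho_link * links_tot;
    const double tot = coal_tot + rec_tot;
    const double t_next = (iev < nev) ? ev_time[iev] : R_PosInf;
    const double dt = (tot > 0) ? exp_rand() / tot : R_PosInf;
    if (t + dt >= t_next) {
      if (!R_FINITE(t_next))
        stop("zero total event rate with no pending demographic event");
      t = t_next;
      const int ty = ev_type[iev], a = ev_a[iev], b = ev_b[iev];
      const double x = ev_x[iev];
      if (ty == 0) {
        for (auto& l : lins) if (l.pop == a) l.pop = b;
      } else if (ty == 1) {
        for (auto& l : lins) if (l.pop == a && unif_rand() < x) l.pop = b;
      } else {
        popsize[a] = x;
      }
      ++iev;
      continue;
    }
    t += dt;
    double u = unif_rand() * tot;
    if (u < rec_tot) {
      // recombination: lineage chosen proportional to spanned links
      double v = u / rho_link;
      int li = -1;
      for (size_t i2 = 0; i2 < lins.size(); ++i2) {
        const double nl = n_links(lins[i2]);
        if (v < nl) { li = (int) i2; break; }
        v -= nl;
      }
      if (li < 0) li = (int) lins.size() - 1;
      const Lin A = lins[li];
      const int nl = n_links(A);
      int brk = A.segs.front().left + 1 + (int) (unif_rand() * nl);
      if (brk > A.segs.back().right - 1) brk = A.segs.back().right - 1;
      Lin B, C;
      B.pop = C.pop = A.pop;
      for (auto& s : A.segs) {
        if (s.right <= brk) B.segs.push_back(s);
        else if (s.left >= brk) C.segs.push_back(s);
        else {
          B.segs.push_back({s.left, brk, s.node, s.ndesc});
          C.segs.push_back({brk, s.right, s.node, s.ndesc});
        }
      }
      lins[li] = B;
      lins.push_back(C);
    } else {
      // coalescence: choose deme, then an unordered pair within it
      double v = u - rec_tot;
      int p = n_pop - 1;
      for (int q = 0; q < n_pop; ++q) {
        if (v < crate[q]) { p = q; break; }
        v -= crate[q];
      }
      mem.clear();
      for (size_t i2 = 0; i2 < lins.size(); ++i2)
        if (lins[i2].pop == p) mem.push_back((int) i2);
      const int g = (int) mem.size();
      if (g < 2) continue;  // numerical guard; cannot normally happen
      int i1 = (int) (unif_rand() * g); if (i1 >= g) i1 = g - 1;
      int i2 = (int) (unif_rand() * (g - 1)); if (i2 >= g - 1) i2 = g - 2;
      if (i2 >= i1) ++i2;
      const int a1 = mem[i1], a2 = mem[i2];
      Lin C = merge_lins(lins[a1], lins[a2], t, ntot, arg);
      const int hi = std::max(a1, a2), lo = std::min(a1, a2);
      lins[hi] = lins.back(); lins.pop_back();
      lins[lo] = lins.back(); lins.pop_back();
      if (!C.segs.empty()) lins.push_back(C);
    }
  }
  return List::create(
      _["node_time"] = wrap(arg.node_time),
      _["left"] = wrap(arg.e_left), _["right"] = wrap(arg.e_right),
      _["parent"] = wrap(arg.e_parent), _["child"] = wrap(arg.e_child),
      _["n_samples"] = ntot, _["L"] = L);
}

namespace {

// Incremental left-to-right sweep over edge insertions/removals keeping a
// parent[] array current for the genomic position x.  Removals are applied
// before insertions at tied coordinates.
struct TreeSweep {
  const IntegerVector &left, &right, &parent_v, &child_v;
  std::vector<int> ins, outs;
  std::vector<int> parent;
  size_t ii = 0, oo = 0;
  TreeSweep(const IntegerVector& l, const IntegerVector& r,
            const IntegerVector& p, const IntegerVector& c, int n_nodes)
      : left(l), right(r), parent_v(p), child_v(c), parent(n_nodes, -1) {
    const int ne = l.size();
    ins.resize(ne); outs.resize(ne);
    for (int i = 0; i < ne; ++i) ins[i] = outs[i] = i;
    std::sort(ins.begin(), ins.end(),
              [&](int a, int b) { return l[a] < l[b]; });
    std::sort(outs.begin(), outs.end(),
              [&](int a, int b) { return r[a] < r[b]; });
  }
  void advance_to(double x) {
    const size_t ne = ins.size();
    while (true) {
      const double rn = (oo < ne) ? (double) right[outs[oo]] : R_PosInf;
      const double ln = (ii < ne) ? (double) left[ins[ii]] : R_PosInf;
      if (rn <= ln) {
        if (rn <= x) { parent[child_v[outs[oo]]] = -1; ++oo; continue; }
      } else {
        if (ln <= x) { parent[child_v[ins[ii]]] = parent_v[ins[ii]]; ++ii; continue; }
      }
      break;
    }
  }
};

}  // namespace

// Infinite-sites mutations: Poisson(branch length * s * span) per edge,
// each mutation at a fresh continuous position in [0, L).  `s` is the
// substitution rate per site per 4N generations (the branch scale).
// [[Rcpp::export(name = ".mutate_infinite_sites_cpp")]]
List mutate_infinite_sites_cpp(NumericVector node_time, IntegerVector left,
                               IntegerVector right, IntegerVector parent,
                               IntegerVector child, int n_samples, int L,
                               double s) {
  const int ne = left.size();
  std::vector<double> pos;
  std::vector<int> mnode;
  for (int e = 0; e < ne; ++e) {
    const double blen = node_time[parent[e]] - node_time[child[e]];
    const double mu = blen * s * (right[e] - left[e]);
    const int nm = (mu > 0) ? (int) R::rpois(mu) : 0;
    for (int m = 0; m < nm; ++m) {
      double x = left[e] + unif_rand() * (right[e] - left[e]);
      if (x >= right[e]) x = std::nextafter((double) right[e], 0.0);
      pos.push_back(x);
      mnode.push_back(child[e]);
    }
  }
  const int nm = (int) pos.size();
  std::vector<int> ord(nm);
  for (int i = 0; i < nm; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return pos[a] < pos[b]; });
  IntegerMatrix geno(nm, n_samples);
  NumericVector out_pos(nm);
  TreeSweep sw(left, right, parent, child, (int) node_time.size());
  for (int r = 0; r < nm; ++r) {
    const int m = ord[r];
    out_pos[r] = pos[m];
    sw.advance_to(pos[m]);
    for (int smp = 0; smp < n_samples; ++smp) {
      int p = smp;
      while (p != -1) {
        if (p == mnode[m]) { geno(r, smp) = 1; break; }
        p = sw.parent[p];
      }
    }
  }
  return List::create(_["positions"] = out_pos, _["geno"] = geno);
}

// HKY sequence simulation over the marginal trees of the ARG.
// V, lambda: eigenvectors/values of the symmetrized rate matrix
// S = diag(sqrt(pi)) Q diag(1/sqrt(pi)) with Q normalized to mean rate 1,
// so that P(tau) = diag(1/sqrt(pi)) V exp(Lambda tau) V' diag(sqrt(pi)).
// Branch lengths in substitution units are (coalescent length) * s.
// Returns the full sample alignment (bases coded 0..3) and the root
// (true ancestral) base per site.
// [[Rcpp::export(name = ".sim_sequence_hky_cpp")]]
List sim_sequence_hky_cpp(NumericVector node_time, IntegerVector left,
                          IntegerVector right, IntegerVector parent,
                          IntegerVector child, int n_samples, int L, double s,
                          NumericMatrix V, NumericVector lambda,
                          NumericVector pi) {
  const int nn = (int) node_time.size();
  const int ne = left.size();
  IntegerMatrix align(n_samples, L);
  IntegerVector anc(L);
  double cum_pi[4];
  {
    double c = 0;
    for (int i = 0; i < 4; ++i) { c += pi[i]; cum_pi[i] = c; }
    cum_pi[3] = 1.0;
  }
  // interval breakpoints
  std::vector<int> bp;
  bp.reserve(2 * ne + 2);
  for (int e = 0; e < ne; ++e) { bp.push_back(left[e]); bp.push_back(right[e]); }
  bp.push_back(0); bp.push_back(L);
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end()), bp.end());

  TreeSweep sw(left, right, parent, child, nn);
  std::vector<int> base(nn, 0);
  std::vector<int> involved;
  std::vector<char> seen(nn, 0);
  std::vector<double> cumP(4 * 4);  // per-node cumulative transition rows
  std::vector<std::vector<double>> nodeP(nn);

  for (size_t b = 0; b + 1 < bp.size(); ++b) {
    const int x0 = bp[b], x1 = bp[b + 1];
    if (x0 >= L || x1 <= 0 || x0 >= x1) continue;
    sw.advance_to((double) x0);
    // active nodes for this interval
    involved.clear();
    std::fill(seen.begin(), seen.end(), 0);
    for (int c = 0; c < nn; ++c) {
      if (sw.parent[c] != -1) {
        if (!seen[c]) { seen[c] = 1; involved.push_back(c); }
        const int p = sw.parent[c];
        if (!seen[p]) { seen[p] = 1; involved.push_back(p); }
      }
    }
    if (involved.empty()) continue;
    std::sort(involved.begin(), involved.end(), [&](int a, int c) {
      return node_time[a] > node_time[c];
    });
    // per-node transition matrix (cumulative rows) for its parent branch
    for (int c : involved) {
      if (sw.parent[c] == -1) continue;
      const double tau = (node_time[sw.parent[c]] - node_time[c]) * s;
      std::vector<double>& P = nodeP[c];
      P.assign(16, 0.0);
      for (int i = 0; i < 4; ++i) {
        double acc = 0.0;
        for (int j = 0; j < 4; ++j) {
          double pij = 0.0;
          for (int m = 0; m < 4; ++m)
            pij += V(i, m) * std::exp(lambda[m] * tau) * V(j, m);
          pij *= std::sqrt(pi[j] / pi[i]);
          if (pij < 0) pij = 0;
          acc += pij;
          P[4 * i + j] = acc;
        }
        for (int j = 0; j < 4; ++j) P[4 * i + j] /= acc;  // renormalize
      }
    }
    for (int site = x0; site < x1; ++site) {
      int root_base = -1;
      for (int c : involved) {
        const int p = sw.parent[c];
        if (p == -1) {
          const double u = unif_rand();
          int bcur = 0;
          while (bcur < 3 && u > cum_pi[bcur]) ++bcur;
          base[c] = bcur;
          if (root_base < 0) root_base = bcur;
        } else {
          const std::vector<double>& P = nodeP[c];
          const double u = unif_rand();
          const int i = base[p];
          int bcur = 0;
          while (bcur < 3 && u > P[4 * i + bcur]) ++bcur;
          base[c] = bcur;
        }
      }
      anc[site] = root_base;
      for (int smp = 0; smp < n_samples; ++smp) align(smp, site) = base[smp];
    }
  }
  return List::create(_["align"] = align, _["anc"] = anc);
}

// Extract biallelic variant columns from a coded base alignment.
// Returns genotypes (sites x haplotypes) coded 0/1 with allele 0 equal to
// the true ancestral base where it is present among the samples (otherwise
// the lowest base code, with anc_code = -1 marking that the true ancestral
// allele was lost), 0-based positions, and dropped-site counters.
// [[Rcpp::export(name = ".extract_variants_cpp")]]
List extract_variants_cpp(IntegerMatrix align, IntegerVector anc) {
  const int n = align.nrow(), L = align.ncol();
  std::vector<int> keep_pos, a0s, a1s, ancc;
  int n_multi = 0;
  for (int s = 0; s < L; ++s) {
    int cnt[4] = {0, 0, 0, 0};
    for (int i = 0; i < n; ++i) cnt[align(i, s)]++;
    int nall = 0, b1 = -1, b2 = -1;
    for (int b = 0; b < 4; ++b)
      if (cnt[b] > 0) { ++nall; if (b1 < 0) b1 = b; else if (b2 < 0) b2 = b; }
    if (nall == 1) continue;           // monomorphic among samples
    if (nall > 2) { ++n_multi; continue; }
    int a0 = b1, a1 = b2, ac;
    if (anc[s] == b2) { a0 = b2; a1 = b1; }
    ac = (anc[s] == a0) ? 0 : -1;      // -1: true ancestral allele lost
    keep_pos.push_back(s);
    a0s.push_back(a0); a1s.push_back(a1); ancc.push_back(ac);
  }
  const int S = (int) keep_pos.size();
  IntegerMatrix geno(S, n);
  for (int r = 0; r < S; ++r) {
    const int s = keep_pos[r];
    for (int i = 0; i < n; ++i) geno(r, i) = (align(i, s) == a1s[r]) ? 1 : 0;
  }
  return List::create(_["positions"] = wrap(keep_pos), _["geno"] = geno,
                      _["anc_code"] = wrap(ancc), _["n_multiallelic"] = n_multi,
                      _["allele0"] = wrap(a0s), _["allele1"] = wrap(a1s));
}
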