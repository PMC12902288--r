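// Structured-coalescent core: exponential-waiting-time coalescent across
// demes with piecewise-constant migration, instantaneous admixture pulses
// (backwards-time Bernoulli relocation) and deme merges (splits, viewed
// backwards).
//
// Two entry points share the genealogy builder:
//  - .sim_loci_cpp: drops infinite-sites mutations as Poisson on total
//    branch length, assigning them to unique integer positions, and
//    returns haplotype genotypes (the data simulator);
//  - .sim_branch_sfs_cpp: accumulates branch lengths by the joint
//    derived-leaf configuration of two sampled demes (the
//    Rao-Blackwellized expected joint SFS used by the demographic fitter:
//    conditioning on genealogies removes all mutation-sampling noise).
//
// Randomness: one std::mt19937_64 per locus, seeded from R with a counter
// scheme, so loci are exchangeable replicates and a model containing a
// zero-proportion pulse consumes exactly the same random stream as the
// model without that event (phi = 0 draws nothing).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <unordered_set>
#include <cmath>

using namespace Rcpp;

namespace {

struct Demography {
  int nd;
  std::vector<int> n_sample;
  std::vector<double> ne;
  std::vector<double> ev_time;
  std::vector<int> ev_type, ev_a, ev_b;
  std::vector<double> ev_prop;
  std::vector<double> mig_times;
  std::vector<std::vector<double> > migs; // column-major nd x nd
};

struct Tree {
  std::vector<int> parent;
  std::vector<double> node_time;
  int n_nodes, n_leaves, root;
  double total_len;
  std::vector<int> pulse_present, pulse_moved; // per schedule event
  // reusable work buffers (avoid per-locus allocation)
  std::vector<std::vector<int> > by_deme;
  std::vector<bool> alive;
  std::vector<double> coal_rate, mig_row;
};

// simulate one genealogy; throws Rcpp::exception on structural errors
void build_tree(const Demography &D, std::mt19937_64 &rng, Tree &T) {
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const int nd = D.nd;
  int n_leaves = 0;
  for (int d = 0; d < nd; ++d) n_leaves += D.n_sample[d];
  const int max_nodes = 2 * n_leaves - 1;
  T.parent.assign(max_nodes, -1);
  T.node_time.assign(max_nodes, 0.0);
  T.n_leaves = n_leaves;
  T.pulse_present.assign(D.ev_time.size(), 0);
  T.pulse_moved.assign(D.ev_time.size(), 0);

  // lineages kept in per-deme lists: O(1) rate bookkeeping and event
  // selection without per-event scans
  std::vector<std::vector<int> > &by_deme = T.by_deme;
  by_deme.resize(nd);
  for (int d = 0; d < nd; ++d) by_deme[d].clear();
  int id = 0;
  int n_active = 0;
  for (int d = 0; d < nd; ++d)
    for (int i = 0; i < D.n_sample[d]; ++i) {
      by_deme[d].push_back(id);
      ++id; ++n_active;
    }
  int n_nodes = n_leaves;

  double t = 0.0;
  size_t ev_i = 0, ep_i = 0;
  const double *M = D.migs[0].data();
  T.alive.assign(nd, true);
  T.coal_rate.assign(nd, 0.0);
  T.mig_row.assign(nd, 0.0);
  std::vector<bool> &alive = T.alive;
  std::vector<double> &coal_rate = T.coal_rate, &mig_row = T.mig_row;
  // accumulated-hazard waiting times: the standard exponential draw is
  // converted to a unit-rate hazard that is spent across schedule
  // boundaries (memorylessness makes this exact), so a schedule event
  // consumes no randomness and a phi = 0 pulse leaves the stream intact
  double hazard = -1.0;

  while (n_active > 1) {
    double total = 0.0;
    for (int d = 0; d < nd; ++d) {
      size_t k = by_deme[d].size();
      coal_rate[d] = k > 1 ? k * (k - 1.0) / (4.0 * D.ne[d]) : 0.0;
      double rs = 0.0;
      for (int j = 0; j < nd; ++j)
        if (j != d && alive[j]) rs += M[j * nd + d]; // M[d, j]
      mig_row[d] = rs;
      total += coal_rate[d] + k * rs;
    }

    double sched = R_PosInf;
    if (ev_i < D.ev_time.size()) sched = D.ev_time[ev_i];
    if (ep_i + 1 < D.mig_times.size() && D.mig_times[ep_i + 1] < sched)
      sched = D.mig_times[ep_i + 1];

    if (hazard < 0.0) {
      double u = unif(rng);
      if (u <= 0.0) u = 1e-300;
      hazard = -std::log(u);
    }
    double dt = total > 0.0 ? hazard / total : R_PosInf;
    if (t + dt >= sched) {
      if (!std::isfinite(sched))
        stop("unreachable common ancestor: lineages remain in isolated demes with no further events");
      hazard -= total * (sched - t);
      if (hazard < 0.0) hazard = 0.0;
      t = sched;
      while (ep_i + 1 < D.mig_times.size() && D.mig_times[ep_i + 1] <= t) {
        ++ep_i;
        M = D.migs[ep_i].data();
      }
      while (ev_i < D.ev_time.size() && D.ev_time[ev_i] <= t) {
        int a = D.ev_a[ev_i], b = D.ev_b[ev_i];
        if (D.ev_type[ev_i] == 0) {           // split: child a joins parent b
          std::vector<int> &src = by_deme[a], &dst = by_deme[b];
          dst.insert(dst.end(), src.begin(), src.end());
          src.clear();
          alive[a] = false;
        } else {                               // pulse: backwards, dest-b
          double phi = D.ev_prop[ev_i];        // lineages relocate to a
          std::vector<int> &dst = by_deme[b];
          int present = (int) dst.size(), moved = 0;
          if (phi > 0.0) {
            for (size_t i = 0; i < dst.size(); ) {
              if (unif(rng) < phi) {
                by_deme[a].push_back(dst[i]);
                dst[i] = dst.back();
                dst.pop_back();
                ++moved;
              } else ++i;
            }
          }
          T.pulse_present[ev_i] = present;
          T.pulse_moved[ev_i] = moved;
        }
        ++ev_i;
      }
      continue;
    }

    t += dt;
    hazard = -1.0;
    double u = unif(rng) * total;
    bool done = false;
    for (int d = 0; d < nd && !done; ++d) {
      std::vector<int> &lst = by_deme[d];
      if (u < coal_rate[d]) {
        int k = (int) lst.size();
        int a1 = (int) (unif(rng) * k); if (a1 >= k) a1 = k - 1;
        int a2 = (int) (unif(rng) * (k - 1)); if (a2 >= k - 1) a2 = k - 2;
        if (a2 >= a1) ++a2;
        int nid = n_nodes++;
        T.parent[lst[a1]] = nid;
        T.parent[lst[a2]] = nid;
        T.node_time[nid] = t;
        if (a1 < a2) std::swap(a1, a2);
        lst[a1] = lst.back(); lst.pop_back();
        lst[a2] = lst.back(); lst.pop_back();
        lst.push_back(nid);
        --n_active;
        done = true;
      } else u -= coal_rate[d];
      if (!done) {
        double dm = lst.size() * mig_row[d];
        if (u < dm) {
          int a1 = (int) (unif(rng) * lst.size());
          if (a1 >= (int) lst.size()) a1 = (int) lst.size() - 1;
          double v = unif(rng) * mig_row[d];
          int dest = -1;
          for (int j = 0; j < nd; ++j) {
            if (j == d || !alive[j]) continue;
            double r = M[j * nd + d];
            if (v < r) { dest = j; break; }
            v -= r;
          }
          if (dest < 0)
            for (int j = nd - 1; j >= 0; --j)
              if (j != d && alive[j]) { dest = j; break; }
          by_deme[dest].push_back(lst[a1]);
          lst[a1] = lst.back(); lst.pop_back();
          done = true;
        } else u -= dm;
      }
    }
    if (!done) stop("internal error: event selection fell through");
  }

  for (int d = 0; d < nd; ++d)
    if (!by_deme[d].empty()) T.root = by_deme[d][0];
  T.n_nodes = n_nodes;
  T.total_len = 0.0;
  for (int v = 0; v < n_nodes; ++v)
    if (v != T.root) T.total_len += T.node_time[T.parent[v]] - T.node_time[v];
}

Demography unpack(IntegerVector n_sample, NumericVector ne,
                  NumericVector ev_time, IntegerVector ev_type,
                  IntegerVector ev_a, IntegerVector ev_b,
                  NumericVector ev_prop, NumericVector mig_times,
                  List mig_mats) {
  Demography D;
  D.nd = n_sample.size();
  D.n_sample.assign(n_sample.begin(), n_sample.end());
  D.ne.assign(ne.begin(), ne.end());
  D.ev_time.assign(ev_time.begin(), ev_time.end());
  D.ev_type.assign(ev_type.begin(), ev_type.end());
  D.ev_a.assign(ev_a.begin(), ev_a.end());
  D.ev_b.assign(ev_b.begin(), ev_b.end());
  D.ev_prop.assign(ev_prop.begin(), ev_prop.end());
  D.mig_times.assign(mig_times.begin(), mig_times.end());
  for (int e = 0; e < mig_mats.size(); ++e) {
    NumericMatrix m = mig_mats[e];
    if (m.nrow() != D.nd || m.ncol() != D.nd)
      stop("migration matrix dimension mismatch");
    D.migs.push_back(std::vector<double>(m.begin(), m.end()));
  }
  return D;
}

} // namespace

// [[Rcpp::export(name = ".sim_loci_cpp")]]
List sim_loci_cpp(IntegerVector n_sample, NumericVector ne,
                  NumericVector ev_time, IntegerVector ev_type,
                  IntegerVector ev_a, IntegerVector ev_b,
                  NumericVector ev_prop, NumericVector mig_times,
                  List mig_mats, double mu, int locus_len, int n_loci,
                  NumericVector seeds) {
  Demography D = unpack(n_sample, ne, ev_time, ev_type, ev_a, ev_b, ev_prop,
                        mig_times, mig_mats);
  int n_leaves = 0;
  for (int d = 0; d < D.nd; ++d) n_leaves += D.n_sample[d];
  if (n_leaves < 2) stop("need at least 2 sampled haplotypes in total");
  if (seeds.size() != n_loci) stop("one seed per locus required");

  const int n_ev = (int) D.ev_time.size();
  std::vector<std::vector<int> > all_pos(n_loci);
  std::vector<std::vector<std::vector<int> > > all_carriers(n_loci);
  NumericVector tmrca(n_loci), tlen(n_loci);
  NumericMatrix pulse_present(n_loci, std::max(n_ev, 1));
  NumericMatrix pulse_moved(n_loci, std::max(n_ev, 1));
  long total_mut = 0;

  Tree T;
  for (int loc = 0; loc < n_loci; ++loc) {
    std::mt19937_64 rng((uint64_t) seeds[loc]);
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    build_tree(D, rng, T);
    tmrca[loc] = T.node_time[T.root];
    tlen[loc] = T.total_len;
    for (int e = 0; e < n_ev; ++e) {
      pulse_present(loc, e) = T.pulse_present[e];
      pulse_moved(loc, e) = T.pulse_moved[e];
    }

    double lambda = mu * (double) locus_len * T.total_len;
    std::poisson_distribution<int> pois(lambda);
    int n_mut = lambda > 0 ? pois(rng) : 0;
    if (n_mut > locus_len)
      stop("more mutations than sites in a locus; increase locus_length or reduce divergence");

    std::vector<std::vector<int> > children(T.n_nodes);
    for (int v = 0; v < T.n_nodes; ++v)
      if (v != T.root) children[T.parent[v]].push_back(v);

    std::unordered_set<int> used;
    all_pos[loc].reserve(n_mut);
    all_carriers[loc].reserve(n_mut);
    for (int m = 0; m < n_mut; ++m) {
      double v = unif(rng) * T.total_len;
      int node = -1;
      for (int w = 0; w < T.n_nodes; ++w) {
        if (w == T.root) continue;
        double bl = T.node_time[T.parent[w]] - T.node_time[w];
        if (v < bl) { node = w; break; }
        v -= bl;
      }
      if (node < 0) node = T.root == 0 ? 1 : 0;
      int p;
      do {
        p = 1 + (int) (unif(rng) * locus_len);
        if (p > locus_len) p = locus_len;
      } while (used.count(p));
      used.insert(p);
      std::vector<int> leaves, stack;
      stack.push_back(node);
      while (!stack.empty()) {
        int w = stack.back(); stack.pop_back();
        if (w < T.n_leaves) leaves.push_back(w);
        else for (size_t c = 0; c < children[w].size(); ++c)
          stack.push_back(children[w][c]);
      }
      all_pos[loc].push_back(p);
      all_carriers[loc].push_back(leaves);
    }
    total_mut += n_mut;
  }

  IntegerMatrix geno(n_leaves, (int) total_mut);
  IntegerVector site_locus((int) total_mut), site_pos((int) total_mut);
  int col = 0;
  for (int loc = 0; loc < n_loci; ++loc) {
    std::vector<int> ord(all_pos[loc].size());
    for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int) i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return all_pos[loc][a] < all_pos[loc][b];
    });
    for (size_t i = 0; i < ord.size(); ++i) {
      int m = ord[i];
      site_locus[col] = loc + 1;
      site_pos[col] = all_pos[loc][m];
      for (size_t j = 0; j < all_carriers[loc][m].size(); ++j)
        geno(all_carriers[loc][m][j], col) = 1;
      ++col;
    }
  }

  return List::create(_["geno"] = geno,
                      _["site_locus"] = site_locus,
                      _["site_pos"] = site_pos,
                      _["tmrca"] = tmrca,
                      _["total_len"] = tlen,
                      _["pulse_present"] = pulse_present,
                      _["pulse_moved"] = pulse_moved);
}

// [[Rcpp::export(name = ".sim_branch_sfs_cpp")]]
List sim_branch_sfs_cpp(IntegerVector n_sample, NumericVector ne,
                        NumericVector ev_time, IntegerVector ev_type,
                        IntegerVector ev_a, IntegerVector ev_b,
                        NumericVector ev_prop, NumericVector mig_times,
                        List mig_mats, int deme1, int deme2, int n_loci,
                        NumericVector seeds) {
  Demography D = unpack(n_sample, ne, ev_time, ev_type, ev_a, ev_b, ev_prop,
                        mig_times, mig_mats);
  if (seeds.size() != n_loci) stop("one seed per locus required");
  const int n1 = D.n_sample[deme1], n2 = D.n_sample[deme2];
  int n_leaves = 0;
  for (int d = 0; d < D.nd; ++d) n_leaves += D.n_sample[d];
  if (n1 + n2 != n_leaves)
    stop("branch-SFS mode requires sampling exactly the two target demes");

  // leaf deme membership follows the deme-blocked leaf ordering
  std::vector<int> leaf_in_d1(n_leaves, 0);
  {
    int id = 0;
    for (int d = 0; d < D.nd; ++d)
      for (int i = 0; i < D.n_sample[d]; ++i) leaf_in_d1[id++] = (d == deme1);
  }

  NumericMatrix acc(n1 + 1, n2 + 1); // branch length by (d1, d2) config
  double total_len_sum = 0.0;

  Tree T;
  std::vector<int> c1, c2;
  for (int loc = 0; loc < n_loci; ++loc) {
    std::mt19937_64 rng((uint64_t) seeds[loc]);
    build_tree(D, rng, T);
    total_len_sum += T.total_len;
    // leaf counts per node by upward accumulation (children precede
    // parents in creation order)
    c1.assign(T.n_nodes, 0);
    c2.assign(T.n_nodes, 0);
    for (int v = 0; v < T.n_leaves; ++v) {
      if (leaf_in_d1[v]) c1[v] = 1; else c2[v] = 1;
    }
    for (int v = 0; v < T.n_nodes; ++v) {
      if (v == T.root) continue;
      c1[T.parent[v]] += c1[v];
      c2[T.parent[v]] += c2[v];
    }
    for (int v = 0; v < T.n_nodes; ++v) {
      if (v == T.root) continue;
      acc(c1[v], c2[v]) += T.node_time[T.parent[v]] - T.node_time[v];
    }
  }
  return List::create(_["branch_sfs"] = acc,
                      _["mean_total_len"] = total_len_sum / n_loci);
}
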