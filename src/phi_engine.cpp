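// IIT 3.0 integrated-information engine for conditionally independent
// state-by-node TPMs over binary nodes.
//
// Conventions (shared with the R level and with tools/iit3_reference.py):
//  * states are little-endian bitmasks: bit i = node i, 1 = spin up;
//  * repertoires over a purview are indexed by the purview's nodes in
//    ascending order (bit k of a purview index = k-th smallest purview node);
//  * cause repertoires use the maximum-entropy prior over past states;
//    effect repertoires factorize over purview nodes;
//  * mechanism partitions are the IIT 3.0 bipartitions: unordered splits of
//    the mechanism times ordered splits of the purview, either side of a
//    part may be empty but not both;
//  * repertoire distance: exact earth-mover distance with Hamming ground
//    metric (effect repertoires are products, for which the EMD equals the
//    sum of per-node marginal differences; both routes agree);
//  * phi values are compared at precision 1e-6 (matching the reference
//    toolbox convention); purview ties within that band prefer the larger purview,
//    then the earlier purview in (size, bitmask) order;
//  * system partitions are the 2^n - 2 unidirectional cuts severing all
//    connections from one part to its complement (severed inputs are
//    replaced by maximum-entropy noise);
//  * big Phi is the generalized EMD between the unpartitioned and
//    partitioned cause-effect structures: concepts carry mass phi, the
//    ground metric is the sum of cause and effect EMDs between repertoires
//    expanded over the full system, and surplus mass is exchanged with the
//    null concept (unconstrained repertoires).
//
// The purview/partition searches carry exact pruning bounds (a candidate is
// skipped only when it provably cannot beat or tie the incumbent), so
// results are identical to the exhaustive search.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double TIE_TOL = 1e-6;
static const double PHI_EPS = 1e-6;
static const double BIG = 1e18;

static inline int popcount(unsigned x) { return __builtin_popcount(x); }

// gather the bits of u selected by posmask into a compact index
static inline int compress_bits(int u, int posmask) {
  int idx = 0, k = 0;
  for (int b = 0; (posmask >> b) != 0; ++b) {
    if ((posmask >> b) & 1) {
      if ((u >> b) & 1) idx |= (1 << k);
      ++k;
    }
  }
  return idx;
}

// ---------------------------------------------------------------------------
// Exact transportation solver: successive shortest paths with Johnson
// potentials on the dense bipartite graph, zero heap allocation. Node count
// is bounded by MAXP sources + MAXP sinks.
// ---------------------------------------------------------------------------
namespace emdsolve {

static const int MAXP = 72;

static double flow_[MAXP][MAXP];
static double a_[MAXP], b_[MAXP];
static double pot_[2 * MAXP], dist_[2 * MAXP];
static int par_[2 * MAXP]; // parent node on shortest path
static unsigned char done_[2 * MAXP];
static int src_[MAXP], snk_[MAXP];

// EMD between nonnegative vectors a (supplies, length na) and b (demands,
// length nb) under cost matrix C (na x nb, row-major, nonnegative); demand
// totals are rescaled to match the supply total exactly.
double transport(const double* a0, const double* b0, const double* C,
                 int na, int nb) {
  double sa = 0, sb = 0;
  for (int i = 0; i < na; ++i) sa += a0[i];
  for (int j = 0; j < nb; ++j) sb += b0[j];
  if (sa <= 1e-15 || sb <= 1e-15) return 0.0;
  double scale = sa / sb;

  // masses below DUST are treated as zero throughout: exact cancellations
  // during augmentation leave ~1e-16 residue that must not be mistaken for
  // transportable mass (the induced cost error is < 1e-12 x diameter)
  const double DUST = 1e-14;
  int S = 0, T = 0;
  for (int i = 0; i < na; ++i)
    if (a0[i] > DUST) { src_[S] = i; a_[S++] = a0[i]; }
  for (int j = 0; j < nb; ++j)
    if (b0[j] > DUST) { snk_[T] = j; b_[T++] = b0[j] * scale; }
  if (S > MAXP || T > MAXP) Rcpp::stop("transportation instance too large");

  for (int i = 0; i < S; ++i)
    for (int j = 0; j < T; ++j) flow_[i][j] = 0.0;
  int V = S + T; // sources 0..S-1, sinks S..S+T-1
  for (int v = 0; v < V; ++v) pot_[v] = 0.0;

  double total = 0.0;
  double remaining = sa;
  while (remaining > 1e-12) {
    // multi-source Dijkstra on reduced costs
    for (int v = 0; v < V; ++v) { dist_[v] = BIG; done_[v] = 0; par_[v] = -1; }
    for (int i = 0; i < S; ++i) if (a_[i] > DUST) dist_[i] = 0.0;
    while (true) {
      int u = -1; double best = BIG;
      for (int v = 0; v < V; ++v)
        if (!done_[v] && dist_[v] < best) { best = dist_[v]; u = v; }
      if (u < 0) break;
      done_[u] = 1;
      if (u < S) { // source: forward edges to every sink
        const double* Crow = C + src_[u] * nb;
        for (int j = 0; j < T; ++j) {
          int v = S + j;
          if (done_[v]) continue;
          double nd = dist_[u] + Crow[snk_[j]] + pot_[u] - pot_[v];
          if (nd < dist_[v] - 1e-15) { dist_[v] = nd; par_[v] = u; }
        }
      } else { // sink: residual edges back to sources with positive flow
        int j = u - S;
        for (int i = 0; i < S; ++i) {
          if (done_[i] || flow_[i][j] <= DUST) continue;
          double nd = dist_[u] - C[src_[i] * nb + snk_[j]] + pot_[u] - pot_[i];
          if (nd < dist_[i] - 1e-15) { dist_[i] = nd; par_[i] = u; }
        }
      }
    }
    // closest sink with unmet demand
    int t = -1; double bestd = BIG;
    for (int j = 0; j < T; ++j)
      if (b_[j] > DUST && dist_[S + j] < bestd) { bestd = dist_[S + j]; t = S + j; }
    if (t < 0) break;
    for (int v = 0; v < V; ++v)
      pot_[v] += std::min(dist_[v], bestd); // cap keeps reduced costs valid
    // walk back to a root source, recording bottleneck
    double push = b_[t - S];
    int v = t;
    while (par_[v] >= 0) {
      int u = par_[v];
      if (u < S && v >= S) {
        // forward edge: capacity unbounded
      } else {
        push = std::min(push, flow_[v][u - S]); // residual sink->source edge
      }
      v = u;
    }
    push = std::min(push, a_[v]);
    // apply, clamping cancellation residue to exact zero
    int w = t;
    while (par_[w] >= 0) {
      int u = par_[w];
      if (u < S && w >= S) flow_[u][w - S] += push;
      else {
        flow_[w][u - S] -= push;
        if (flow_[w][u - S] < DUST) flow_[w][u - S] = 0.0;
      }
      w = u;
    }
    a_[w] -= push;
    if (a_[w] < DUST) a_[w] = 0.0;
    b_[t - S] -= push;
    if (b_[t - S] < DUST) b_[t - S] = 0.0;
    remaining -= push;
    total += push * pot_[t];
    if (push <= 1e-15) break;
  }
  return total;
}

} // namespace emdsolve

// EMD between two distributions over 2^k binary states, Hamming ground metric.
static double emd_hamming(const std::vector<double>& p,
                          const std::vector<double>& q, int k) {
  if (k > 6) Rcpp::stop("EMD limited to 2^6 states");
  static std::vector<double> cost_cache[7];
  int m = 1 << k;
  std::vector<double>& C = cost_cache[k];
  if ((int)C.size() != m * m) {
    C.assign(m * m, 0.0);
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < m; ++j)
        C[i * m + j] = (double)popcount((unsigned)(i ^ j));
  }
  return emdsolve::transport(p.data(), q.data(), C.data(), m, m);
}

// ---------------------------------------------------------------------------
// Engine: repertoires and small phi for one (TPM, state)
// ---------------------------------------------------------------------------
struct Concept {
  int mech;
  double phi, phi_cause, phi_effect;
  int cause_pv, effect_pv;
  std::vector<double> cause_rep;      // over cause_pv states
  std::vector<double> effect_marg;    // P(node on), full length n with
                                      // unconstrained values off-purview
  std::vector<double> cause_full;     // expanded over all 2^n states
};

struct Engine {
  int n, ns, state;
  std::vector<double> tpm;          // ns x n, row-major: tpm[s * n + i]
  std::vector<double> lk;           // lk[i * ns + v] = P(node i matches its
                                    // current state | past state v)
  std::vector<double> uncon;        // unconstrained effect marginal per node
  std::vector<std::vector<int>> ext;              // ext[pv][v]: purview index
  std::vector<std::vector<double>> cause_cache;   // (mech * ns + pv)
  std::vector<char> cause_have;
  std::vector<double> effm_cache;                 // (mech * n + j)
  std::vector<char> effm_have;

  Engine(const std::vector<double>& tpm_, int n_, int state_)
      : n(n_), ns(1 << n_), state(state_), tpm(tpm_) {
    lk.assign(n * ns, 0.0);
    for (int i = 0; i < n; ++i) {
      bool on = (state >> i) & 1;
      for (int v = 0; v < ns; ++v)
        lk[i * ns + v] = on ? tpm[v * n + i] : 1.0 - tpm[v * n + i];
    }
    uncon.assign(n, 0.0);
    for (int j = 0; j < n; ++j) {
      double s = 0;
      for (int v = 0; v < ns; ++v) s += tpm[v * n + j];
      uncon[j] = s / ns;
    }
    ext.assign(ns, std::vector<int>());
    cause_cache.assign(ns * ns, std::vector<double>());
    cause_have.assign(ns * ns, 0);
    effm_cache.assign(ns * n, 0.0);
    effm_have.assign(ns * n, 0);
  }

  const std::vector<int>& extractor(int pv) {
    if (ext[pv].empty() && pv != 0) {
      ext[pv].assign(ns, 0);
      for (int v = 0; v < ns; ++v) ext[pv][v] = compress_bits(v, pv);
    }
    return ext[pv];
  }

  // cause repertoire of mechanism `mech` over purview `pv` (both bitmasks)
  const std::vector<double>& cause_rep(int mech, int pv) {
    int key = mech * ns + pv;
    if (cause_have[key]) return cause_cache[key];
    cause_have[key] = 1;
    std::vector<double>& out = cause_cache[key];
    int np = 1 << popcount((unsigned)pv);
    out.assign(np, 1.0 / np);
    if (pv == 0) { out.assign(1, 1.0); return out; }
    if (mech == 0) return out; // unconstrained: uniform
    const std::vector<int>& ex = extractor(pv);
    std::vector<double> rho(np);
    for (int i = 0; i < n; ++i) {
      if (!((mech >> i) & 1)) continue;
      std::fill(rho.begin(), rho.end(), 0.0);
      const double* l = &lk[i * ns];
      for (int v = 0; v < ns; ++v) rho[ex[v]] += l[v];
      double s = 0;
      for (int u = 0; u < np; ++u) s += rho[u];
      if (s <= 0) { std::fill(out.begin(), out.end(), 0.0); return out; }
      for (int u = 0; u < np; ++u) out[u] *= rho[u] / s;
    }
    double s = 0;
    for (int u = 0; u < np; ++u) s += out[u];
    if (s <= 0) { std::fill(out.begin(), out.end(), 0.0); return out; }
    for (int u = 0; u < np; ++u) out[u] /= s;
    return out;
  }

  // effect marginal: P(node j on at t+1 | mechanism fixed at current state)
  double eff_marg(int mech, int j) {
    int key = mech * n + j;
    if (effm_have[key]) return effm_cache[key];
    effm_have[key] = 1;
    double s = 0; int cnt = 0;
    int fixed = state & mech;
    for (int v = 0; v < ns; ++v) {
      if ((v & mech) == fixed) { s += tpm[v * n + j]; ++cnt; }
    }
    double val = s / cnt;
    effm_cache[key] = val;
    return val;
  }

  // joint effect repertoire over purview pv (product of Bernoullis)
  std::vector<double> effect_rep(int mech, int pv) {
    int np = 1 << popcount((unsigned)pv);
    std::vector<double> out(np, 1.0);
    int k = 0;
    for (int b = 0; b < n; ++b) {
      if (!((pv >> b) & 1)) continue;
      double pj = eff_marg(mech, b);
      for (int u = 0; u < np; ++u)
        out[u] *= ((u >> k) & 1) ? pj : 1.0 - pj;
      ++k;
    }
    return out;
  }

  // small phi of `mech` in one direction (0 = cause, 1 = effect):
  // max over purviews of the min over partitions. The distance to the fully
  // unconstrained repertoire (a valid partition) upper-bounds each purview's
  // phi; purviews are processed in decreasing order of that bound and the
  // scan stops once no remaining bound can beat or tie the incumbent. The
  // winner is chosen by an order-independent rule: maximal phi (tol 1e-10),
  // ties to the larger purview, then to the smaller bitmask. Pruned
  // candidates provably fall outside the tie band, so the result equals the
  // exhaustive search.
  void small_phi(int mech, int direction, double& best_phi, int& best_pv) {
    int npv_count = ns - 1;
    std::vector<std::pair<double, int>> order; // (-ub, pv)
    order.reserve(npv_count);
    for (int pv = 1; pv < ns; ++pv)
      order.push_back(std::make_pair(-purview_bound(mech, pv, direction), pv));
    std::sort(order.begin(), order.end());
    double max_phi = -1.0;
    std::vector<std::pair<int, double>> evaluated;
    evaluated.reserve(npv_count);
    for (size_t k = 0; k < order.size(); ++k) {
      double ub = -order[k].first;
      int pv = order[k].second;
      if (max_phi >= 0 && ub < max_phi - TIE_TOL) break; // nor can any later pv
      double phi_pv = phi_for_purview(mech, pv, direction, max_phi, ub);
      evaluated.push_back(std::make_pair(pv, phi_pv));
      if (phi_pv > max_phi) max_phi = phi_pv;
    }
    best_phi = 0.0; best_pv = 0;
    for (size_t k = 0; k < evaluated.size(); ++k) {
      int pv = evaluated[k].first;
      double phi_pv = evaluated[k].second;
      if (phi_pv < max_phi - TIE_TOL) continue;
      if (best_pv == 0 ||
          popcount((unsigned)pv) > popcount((unsigned)best_pv) ||
          (popcount((unsigned)pv) == popcount((unsigned)best_pv) && pv < best_pv)) {
        best_pv = pv; best_phi = phi_pv;
      }
    }
    if (max_phi <= 0) { best_phi = 0.0; }
  }

  // distance between the whole repertoire over pv and the fully
  // unconstrained repertoire: the (empty mechanism over full purview,
  // mechanism over empty purview) partition, always valid
  double purview_bound(int mech, int pv, int direction) {
    if (direction == 0) {
      const std::vector<double>& whole = cause_rep(mech, pv);
      double s = 0; for (double x : whole) s += x;
      if (s <= 0) return 0.0;
      return emd_hamming(whole, cause_rep(0, pv), popcount((unsigned)pv));
    }
    double d = 0.0;
    for (int b = 0; b < n; ++b)
      if ((pv >> b) & 1) d += std::fabs(eff_marg(mech, b) - eff_marg(0, b));
    return d;
  }

  // min over mechanism/purview bipartitions of the repertoire distance for
  // one purview; abandons the search (returning a value below the incumbent)
  // as soon as the running min can no longer beat or tie `incumbent`.
  // `ub` is the already-computed distance to the unconstrained repertoire.
  double phi_for_purview(int mech, int pv, int direction, double incumbent,
                         double ub) {
    int npv = popcount((unsigned)pv);
    int np = 1 << npv;
    int pv_nodes[12]; int nn = 0;
    for (int b = 0; b < n; ++b) if ((pv >> b) & 1) pv_nodes[nn++] = b;

    std::vector<double> whole;
    double whole_marg[12]; // effect only
    double phi_min = ub;
    if (direction == 0) {
      whole = cause_rep(mech, pv);
      double s = 0; for (double x : whole) s += x;
      if (s <= 0) return 0.0;
    } else {
      for (int k = 0; k < npv; ++k)
        whole_marg[k] = eff_marg(mech, pv_nodes[k]);
    }
    if (phi_min <= TIE_TOL) return 0.0;
    if (phi_min < incumbent - TIE_TOL) return phi_min; // cannot win the max

    int low = mech & (-mech); // canonical element kept in mechanism part 2
    int rest = mech & ~low;   // subsets of this form part 1 of the mechanism
    std::vector<double> part(np);
    for (int m1 = rest;; m1 = (m1 - 1) & rest) {
      int m2 = mech & ~m1;
      for (int p1 = pv;; p1 = (p1 - 1) & pv) {
        int p2 = pv & ~p1;
        bool skip = (m1 == 0 && p1 == pv); // the bound computed above
        if (!skip && (m1 | p1) != 0 && (m2 | p2) != 0) {
          double d;
          if (direction == 0) {
            const std::vector<double>& c1 = cause_rep(m1, p1);
            const std::vector<double>& c2 = cause_rep(m2, p2);
            int pos1 = 0, pos2 = 0;
            for (int kk = 0; kk < npv; ++kk) {
              if ((p1 >> pv_nodes[kk]) & 1) pos1 |= (1 << kk);
              if ((p2 >> pv_nodes[kk]) & 1) pos2 |= (1 << kk);
            }
            double s = 0;
            for (int u = 0; u < np; ++u) {
              double val = (p1 ? c1[compress_bits(u, pos1)] : 1.0) *
                           (p2 ? c2[compress_bits(u, pos2)] : 1.0);
              part[u] = val; s += val;
            }
            if (s <= 0) { d = BIG; }
            else {
              // Kantorovich lower bounds: EMD >= L1/2 (unit minimum ground
              // distance) and EMD >= sum_k |marginal_k difference| (the
              // signed sum of coordinates is 1-Lipschitz under Hamming).
              // A partition whose lower bound cannot improve the running
              // min needs no exact solve.
              double l1 = 0.0, maxdiff = 0.0;
              double margdiff[12];
              for (int k = 0; k < npv; ++k) margdiff[k] = 0.0;
              for (int u = 0; u < np; ++u) {
                double diff = part[u] - whole[u];
                l1 += std::fabs(diff);
                if (std::fabs(diff) > maxdiff) maxdiff = std::fabs(diff);
                for (int k = 0; k < npv; ++k)
                  if ((u >> k) & 1) margdiff[k] += diff;
              }
              double msum = 0.0;
              for (int k = 0; k < npv; ++k) msum += std::fabs(margdiff[k]);
              double lb = std::max(0.5 * l1, msum);
              if (maxdiff < 1e-12) d = 0.0;
              else if (lb >= phi_min) d = BIG; // cannot improve the min
              else d = emd_hamming(whole, part, npv);
            }
          } else {
            d = 0.0;
            for (int k = 0; k < npv; ++k) {
              int node = pv_nodes[k];
              double pm = ((p1 >> node) & 1) ? eff_marg(m1, node)
                                             : eff_marg(m2, node);
              d += std::fabs(whole_marg[k] - pm);
            }
          }
          if (d < phi_min) {
            phi_min = d;
            if (phi_min <= TIE_TOL) return 0.0;
            if (phi_min < incumbent - TIE_TOL) return phi_min;
          }
        }
        if (p1 == 0) break;
      }
      if (m1 == 0) break;
    }
    return phi_min >= BIG / 2 ? 0.0 : phi_min;
  }

  // cause repertoire expanded over the full 2^n state space
  std::vector<double> expand_cause(const std::vector<double>& rep, int pv) {
    std::vector<double> out(ns);
    if (pv == 0) {
      for (int v = 0; v < ns; ++v) out[v] = 1.0 / ns;
      return out;
    }
    const std::vector<int>& ex = extractor(pv);
    double fill = (double)(1 << popcount((unsigned)pv)) / ns;
    for (int v = 0; v < ns; ++v) out[v] = rep[ex[v]] * fill;
    return out;
  }

  std::vector<Concept> ces() {
    std::vector<Concept> out;
    for (int mech = 1; mech < ns; ++mech) {
      // effect side first: it needs no transportation solves, and a
      // reducible effect kills the concept regardless of the cause side
      double phie; int pve;
      small_phi(mech, 1, phie, pve);
      if (phie <= PHI_EPS) continue;
      double phic; int pvc;
      small_phi(mech, 0, phic, pvc);
      if (phic <= PHI_EPS) continue;
      Concept c;
      c.mech = mech;
      c.phi_cause = phic; c.phi_effect = phie;
      c.phi = std::min(phic, phie);
      c.cause_pv = pvc; c.effect_pv = pve;
      c.cause_rep = cause_rep(mech, pvc);
      c.cause_full = expand_cause(c.cause_rep, pvc);
      c.effect_marg.assign(n, 0.0);
      for (int j = 0; j < n; ++j)
        c.effect_marg[j] = ((pve >> j) & 1) ? eff_marg(mech, j) : uncon[j];
      out.push_back(c);
    }
    return out;
  }
};

// distance between two concepts expanded over the full system
static double concept_distance(const Concept& a, const Concept& b, int n) {
  double dc;
  if (a.cause_pv == b.cause_pv) {
    double maxdiff = 0.0;
    for (size_t u = 0; u < a.cause_full.size(); ++u)
      maxdiff = std::max(maxdiff, std::fabs(a.cause_full[u] - b.cause_full[u]));
    dc = (maxdiff < 1e-12) ? 0.0 : emd_hamming(a.cause_full, b.cause_full, n);
  } else {
    dc = emd_hamming(a.cause_full, b.cause_full, n);
  }
  double de = 0.0;
  for (int j = 0; j < n; ++j) de += std::fabs(a.effect_marg[j] - b.effect_marg[j]);
  return dc + de;
}

static double concept_null_distance(const Concept& a,
                                    const std::vector<double>& null_cause,
                                    const std::vector<double>& null_effm,
                                    int n) {
  double dc = emd_hamming(a.cause_full, null_cause, n);
  double de = 0.0;
  for (int j = 0; j < n; ++j) de += std::fabs(a.effect_marg[j] - null_effm[j]);
  return dc + de;
}

// generalized EMD between two cause-effect structures: concepts carry mass
// phi; surplus mass on either side is exchanged with the null concept
static double ces_distance_impl(const std::vector<Concept>& C1,
                                const std::vector<Concept>& C2,
                                const std::vector<double>& null_cause,
                                const std::vector<double>& null_effm, int n) {
  int n1 = (int)C1.size(), n2 = (int)C2.size();
  if (n1 == 0 && n2 == 0) return 0.0;
  double t1 = 0, t2 = 0;
  for (const Concept& c : C1) t1 += c.phi;
  for (const Concept& c : C2) t2 += c.phi;
  int na = n1 + 1, nb = n2 + 1; // last index on each side = null concept
  std::vector<double> a(na, 0.0), b(nb, 0.0);
  for (int i = 0; i < n1; ++i) a[i] = C1[i].phi;
  for (int j = 0; j < n2; ++j) b[j] = C2[j].phi;
  a[na - 1] = std::max(0.0, t2 - t1);
  b[nb - 1] = std::max(0.0, t1 - t2);
  std::vector<double> C(na * nb, 0.0);
  for (int i = 0; i < n1; ++i)
    for (int j = 0; j < n2; ++j)
      C[i * nb + j] = concept_distance(C1[i], C2[j], n);
  for (int i = 0; i < n1; ++i)
    C[i * nb + (nb - 1)] = concept_null_distance(C1[i], null_cause, null_effm, n);
  for (int j = 0; j < n2; ++j)
    C[(na - 1) * nb + j] = concept_null_distance(C2[j], null_cause, null_effm, n);
  C[(na - 1) * nb + (nb - 1)] = 0.0;
  return emdsolve::transport(a.data(), b.data(), C.data(), na, nb);
}

// apply a unidirectional cut: sever connections from nodes in `from_mask`
// to nodes in `to_mask`; severed inputs are marginalized (max-entropy noise)
static std::vector<double> cut_tpm(const std::vector<double>& tpm, int n,
                                   int from_mask, int to_mask) {
  int ns = 1 << n;
  std::vector<double> out(tpm);
  std::vector<int> subs;
  for (int sub = from_mask;; sub = (sub - 1) & from_mask) {
    subs.push_back(sub);
    if (sub == 0) break;
  }
  for (int j = 0; j < n; ++j) {
    if (!((to_mask >> j) & 1)) continue;
    for (int v = 0; v < ns; ++v) {
      int base = v & ~from_mask;
      double s = 0;
      for (int sub : subs) s += tpm[(base | sub) * n + j];
      out[v * n + j] = s / subs.size();
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// R interface
// ---------------------------------------------------------------------------

static std::vector<double> tpm_to_vec(const NumericMatrix& tpm, int& n) {
  n = tpm.ncol();
  int ns = tpm.nrow();
  if (ns != (1 << n)) stop("TPM must be 2^n x n");
  std::vector<double> v(ns * n);
  for (int s = 0; s < ns; ++s)
    for (int i = 0; i < n; ++i) {
      double p = tpm(s, i);
      if (p < -1e-12 || p > 1 + 1e-12) stop("TPM entries must lie in [0, 1]");
      v[s * n + i] = std::min(1.0, std::max(0.0, p));
    }
  return v;
}

static int mask_from_indices(const IntegerVector& idx, int n) {
  int m = 0;
  for (int k = 0; k < idx.size(); ++k) {
    int i = idx[k];
    if (i < 1 || i > n) stop("node index out of range");
    m |= (1 << (i - 1));
  }
  return m;
}

static int state_from_spins(const NumericVector& spins, int n) {
  if (spins.size() != n) stop("state length must equal the number of nodes");
  int st = 0;
  for (int i = 0; i < n; ++i) {
    if (spins[i] == 1) st |= (1 << i);
    else if (spins[i] != -1) stop("spins must be -1/+1");
  }
  return st;
}

// [[Rcpp::export]]
NumericVector cpp_cause_repertoire(NumericMatrix tpm, NumericVector spins,
                                   IntegerVector mechanism,
                                   IntegerVector purview) {
  int n; std::vector<double> t = tpm_to_vec(tpm, n);
  Engine e(t, n, state_from_spins(spins, n));
  int pv = mask_from_indices(purview, n);
  if (pv == 0) stop("purview must be nonempty");
  std::vector<double> r = e.cause_rep(mask_from_indices(mechanism, n), pv);
  return NumericVector(r.begin(), r.end());
}

// [[Rcpp::export]]
NumericVector cpp_effect_repertoire(NumericMatrix tpm, NumericVector spins,
                                    IntegerVector mechanism,
                                    IntegerVector purview) {
  int n; std::vector<double> t = tpm_to_vec(tpm, n);
  Engine e(t, n, state_from_spins(spins, n));
  int pv = mask_from_indices(purview, n);
  if (pv == 0) stop("purview must be nonempty");
  std::vector<double> r = e.effect_rep(mask_from_indices(mechanism, n), pv);
  return NumericVector(r.begin(), r.end());
}

// [[Rcpp::export]]
double cpp_emd_hamming(NumericVector p, NumericVector q) {
  int m = p.size();
  if (q.size() != m) stop("repertoires must share a purview");
  int k = 0; while ((1 << k) < m) ++k;
  if ((1 << k) != m) stop("repertoire length must be a power of 2");
  std::vector<double> a(p.begin(), p.end()), b(q.begin(), q.end());
  return emd_hamming(a, b, k);
}

// [[Rcpp::export]]
double cpp_emd_transport(NumericVector a, NumericVector b, NumericMatrix cost) {
  int na = a.size(), nb = b.size();
  if (cost.nrow() != na || cost.ncol() != nb) stop("cost matrix shape mismatch");
  std::vector<double> av(a.begin(), a.end()), bv(b.begin(), b.end());
  std::vector<double> C(na * nb);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) C[i * nb + j] = cost(i, j);
  return emdsolve::transport(av.data(), bv.data(), C.data(), na, nb);
}

// [[Rcpp::export]]
List cpp_small_phi(NumericMatrix tpm, NumericVector spins,
                   IntegerVector mechanism, std::string direction) {
  int n; std::vector<double> t = tpm_to_vec(tpm, n);
  Engine e(t, n, state_from_spins(spins, n));
  int mech = mask_from_indices(mechanism, n);
  if (mech == 0) stop("mechanism must be nonempty");
  int dir = (direction == "cause") ? 0 : 1;
  double phi; int pv;
  e.small_phi(mech, dir, phi, pv);
  IntegerVector pv_nodes;
  for (int b = 0; b < n; ++b) if ((pv >> b) & 1) pv_nodes.push_back(b + 1);
  return List::create(_["phi"] = phi, _["purview"] = pv_nodes);
}

static List concepts_to_list(const std::vector<Concept>& C, int n) {
  int m = (int)C.size();
  IntegerVector mechs(m);
  NumericVector phi(m), phic(m), phie(m);
  List cause_pv(m), effect_pv(m);
  for (int k = 0; k < m; ++k) {
    mechs[k] = C[k].mech;
    phi[k] = C[k].phi; phic[k] = C[k].phi_cause; phie[k] = C[k].phi_effect;
    IntegerVector cp, ep;
    for (int b = 0; b < n; ++b) {
      if ((C[k].cause_pv >> b) & 1) cp.push_back(b + 1);
      if ((C[k].effect_pv >> b) & 1) ep.push_back(b + 1);
    }
    cause_pv[k] = cp; effect_pv[k] = ep;
  }
  return List::create(_["mechanism_mask"] = mechs, _["phi"] = phi,
                      _["phi_cause"] = phic, _["phi_effect"] = phie,
                      _["cause_purview"] = cause_pv,
                      _["effect_purview"] = effect_pv);
}

// [[Rcpp::export]]
List cpp_ces(NumericMatrix tpm, NumericVector spins) {
  int n; std::vector<double> t = tpm_to_vec(tpm, n);
  Engine e(t, n, state_from_spins(spins, n));
  return concepts_to_list(e.ces(), n);
}

// [[Rcpp::export]]
List cpp_big_phi(NumericMatrix tpm, NumericVector spins) {
  int n; std::vector<double> t = tpm_to_vec(tpm, n);
  if (n > 5)
    stop("big_phi is limited to n <= 5 nodes: the IIT 3.0 search cost grows "
         "super-exponentially in system size");
  int state = state_from_spins(spins, n);
  if (n == 1) {
    return List::create(_["phi"] = 0.0, _["cut_from"] = IntegerVector(0),
                        _["cut_to"] = IntegerVector(0), _["n_concepts"] = 0,
                        _["sum_small_phi"] = 0.0);
  }
  Engine e(t, n, state);
  std::vector<Concept> C = e.ces();
  double sum_phi = 0;
  for (const Concept& c : C) sum_phi += c.phi;
  int ns = 1 << n;
  double best = 0.0;
  int best_cut = -1;
  if (!C.empty()) {
    std::vector<double> null_cause(ns, 1.0 / ns);
    best = BIG;
    for (int from = 1; from < ns - 1; ++from) {
      int to = (ns - 1) & ~from;
      std::vector<double> t2 = cut_tpm(t, n, from, to);
      double md = 0;
      for (size_t k = 0; k < t2.size(); ++k)
        md = std::max(md, std::fabs(t2[k] - t[k]));
      double d;
      if (md < 1e-15) {
        d = 0.0; // cut leaves the dynamics untouched: nothing is integrated
      } else {
        Engine e2(t2, n, state);
        std::vector<Concept> C2 = e2.ces();
        d = ces_distance_impl(C, C2, null_cause, e.uncon, n);
      }
      if (d < best - 1e-12) { best = d; best_cut = from; }
      if (best <= 1e-12) break;
    }
    if (best >= BIG / 2) best = 0.0;
  }
  IntegerVector cf, ct;
  if (best_cut >= 0) {
    for (int b = 0; b < n; ++b) {
      if ((best_cut >> b) & 1) cf.push_back(b + 1);
      else ct.push_back(b + 1);
    }
  }
  return List::create(_["phi"] = best, _["cut_from"] = cf, _["cut_to"] = ct,
                      _["n_concepts"] = (int)C.size(),
                      _["sum_small_phi"] = sum_phi);
}

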