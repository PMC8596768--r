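#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Structured-coalescent simulator for piecewise demographic epochs.
//
// The model arrives flattened into epochs (see resolve_epochs() on the R
// side). Within an epoch, deme d has size N_d(t) = N0_d * exp(-g_d * (t -
// t0)) backward in time, pairwise coalescence rate 1/(2 N_d(t)) and
// per-lineage migration rate to deme j of M_dj / N_d(t) (backward
// convention: M_dj migrant lineages per generation whose parents sit in j).
// Event times are drawn exactly by thinning: the total rate is a sum of
// exponentials in t, bounded on a window by its endpoint values.

struct Epoch {
  double start;
  std::vector<double> N0;     // size at epoch start (diploid)
  std::vector<double> growth; // backward decay rate within the epoch
  std::vector<double> M;      // D x D migrants/generation, row-major
  std::vector<int> join_from; // applied when entering the epoch
  std::vector<int> join_to;
};

static std::vector<Epoch> parse_epochs(const List &epochs, int D) {
  std::vector<Epoch> out;
  for (int e = 0; e < epochs.size(); ++e) {
    List ep = epochs[e];
    Epoch E;
    E.start = as<double>(ep["start"]);
    E.N0 = as<std::vector<double>>(ep["N0"]);
    E.growth = as<std::vector<double>>(ep["growth"]);
    NumericMatrix M = ep["M"];
    E.M.assign(D * D, 0.0);
    for (int i = 0; i < D; ++i)
      for (int j = 0; j < D; ++j) E.M[i * D + j] = M(i, j);
    E.join_from = as<std::vector<int>>(ep["join_from"]);
    E.join_to = as<std::vector<int>>(ep["join_to"]);
    out.push_back(E);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_sim_genealogy")]]
List cpp_sim_genealogy(List epochs, IntegerVector sample_demes, int n_demes,
                       double ceiling) {
  const int D = n_demes;
  std::vector<Epoch> eps = parse_epochs(epochs, D);
  const int E = (int)eps.size();
  const int n = sample_demes.size();
  const int n_nodes = 2 * n - 1;

  std::vector<double> node_time(n_nodes, 0.0);
  std::vector<int> parent(n_nodes, -1);

  std::vector<int> act;      // active node ids
  std::vector<int> act_deme; // deme of each active lineage (parallel)
  for (int i = 0; i < n; ++i) {
    act.push_back(i);
    act_deme.push_back(sample_demes[i]); // 0-based
  }

  double t = 0.0;
  int e = 0;
  int next_node = n;

  // apply joins of epoch 0 (usually none)
  for (size_t q = 0; q < eps[0].join_from.size(); ++q)
    for (size_t i = 0; i < act.size(); ++i)
      if (act_deme[i] == eps[0].join_from[q]) act_deme[i] = eps[0].join_to[q];

  std::vector<int> k(D);
  std::vector<double> A(D), lam(D);

  while ((int)act.size() > 1) {
    if (t > ceiling)
      stop("coalescent did not complete before the time ceiling (%g generations); the model may have no common ancestor", ceiling);

    const Epoch &ep = eps[e];
    double epoch_end = (e + 1 < E) ? eps[e + 1].start : R_PosInf;

    std::fill(k.begin(), k.end(), 0);
    for (size_t i = 0; i < act.size(); ++i) k[act_deme[i]]++;

    // A_d: rate coefficient at epoch-start reference; rate_d(t) = A_d * exp(g_d*(t - ep.start))
    double gmax = 0.0;
    for (int d = 0; d < D; ++d) {
      double Mrow = 0.0;
      for (int j = 0; j < D; ++j)
        if (j != d) Mrow += ep.M[d * D + j];
      double coal = 0.5 * k[d] * (k[d] - 1) / (2.0 * ep.N0[d]);
      double mig = k[d] * Mrow / ep.N0[d];
      A[d] = coal + mig;
      if (A[d] > 0 && std::fabs(ep.growth[d]) > gmax) gmax = std::fabs(ep.growth[d]);
    }
    double Atot = 0.0;
    for (int d = 0; d < D; ++d) Atot += A[d];

    if (Atot <= 0.0) {
      if (!R_FINITE(epoch_end)) {
        stop("no coalescence or migration possible among remaining lineages: model has no common ancestor");
      }
      t = epoch_end;
      e++;
      for (size_t q = 0; q < eps[e].join_from.size(); ++q)
        for (size_t i = 0; i < act.size(); ++i)
          if (act_deme[i] == eps[e].join_from[q]) act_deme[i] = eps[e].join_to[q];
      continue;
    }

    // window for thinning: cap growth factor change at e^0.5
    double t_hi = epoch_end;
    if (gmax > 0) t_hi = std::min(t_hi, t + 0.5 / gmax);
    if (!R_FINITE(t_hi)) t_hi = t + 1e12; // flat rates: exact, window arbitrary
    t_hi = std::min(t_hi, ceiling + 1.0);

    double Rmax = 0.0;
    for (int d = 0; d < D; ++d) {
      double r1 = A[d] * std::exp(ep.growth[d] * (t - ep.start));
      double r2 = A[d] * std::exp(ep.growth[d] * (t_hi - ep.start));
      Rmax += std::max(r1, r2);
    }

    double dt = R::exp_rand() / Rmax;
    if (t + dt >= t_hi) {
      t = t_hi;
      if (e + 1 < E && t >= epoch_end) {
        e++;
        for (size_t q = 0; q < eps[e].join_from.size(); ++q)
          for (size_t i = 0; i < act.size(); ++i)
            if (act_deme[i] == eps[e].join_from[q]) act_deme[i] = eps[e].join_to[q];
      }
      continue;
    }
    t += dt;

    double Rt = 0.0;
    for (int d = 0; d < D; ++d) {
      lam[d] = A[d] * std::exp(ep.growth[d] * (t - ep.start));
      Rt += lam[d];
    }
    if (unif_rand() * Rmax > Rt) continue; // thinning rejection

    // choose deme
    double u = unif_rand() * Rt, acc = 0.0;
    int d = 0;
    for (; d < D; ++d) {
      acc += lam[d];
      if (u <= acc) break;
    }
    if (d >= D) d = D - 1;

    double Nd = ep.N0[d] * std::exp(-ep.growth[d] * (t - ep.start));
    double coal = 0.5 * k[d] * (k[d] - 1) / (2.0 * Nd);
    double Mrow = 0.0;
    for (int j = 0; j < D; ++j)
      if (j != d) Mrow += ep.M[d * D + j];
    double mig = k[d] * Mrow / Nd;

    if (unif_rand() * (coal + mig) <= coal) {
      // coalesce two random lineages in deme d
      int i1 = -1, i2 = -1;
      {
        int r1 = (int)std::floor(unif_rand() * k[d]);
        int r2 = (int)std::floor(unif_rand() * (k[d] - 1));
        if (r2 >= r1) r2++;
        int seen = 0;
        for (size_t i = 0; i < act.size(); ++i) {
          if (act_deme[i] == d) {
            if (seen == r1) i1 = (int)i;
            if (seen == r2) i2 = (int)i;
            seen++;
          }
        }
      }
      int node = next_node++;
      node_time[node] = t;
      parent[act[i1]] = node;
      parent[act[i2]] = node;
      // replace i1 by new node, drop i2
      act[i1] = node;
      if (i2 != (int)act.size() - 1) {
        act[i2] = act.back();
        act_deme[i2] = act_deme.back();
      }
      act.pop_back();
      act_deme.pop_back();
    } else {
      // migrate one lineage from d to j ~ M[d][j]
      int r = (int)std::floor(unif_rand() * k[d]);
      int idx = -1, seen = 0;
      for (size_t i = 0; i < act.size(); ++i)
        if (act_deme[i] == d) {
          if (seen == r) { idx = (int)i; break; }
          seen++;
        }
      double v = unif_rand() * Mrow, a2 = 0.0;
      int j = 0;
      for (; j < D; ++j) {
        if (j == d) continue;
        a2 += ep.M[d * D + j];
        if (v <= a2) break;
      }
      if (j >= D) j = D - 1 - (d == D - 1 ? 1 : 0);
      act_deme[idx] = j;
    }
  }

  return List::create(_["parent"] = wrap(parent),
                      _["node_time"] = wrap(node_time),
                      _["n_samples"] = n);
}

// Drop infinite-sites mutations on a genealogy and tally derived-allele
// counts per population; optionally build the 0/1 haplotype matrix.
// [[Rcpp::export(name = ".cpp_drop_mutations")]]
List cpp_drop_mutations(IntegerVector parent, NumericVector node_time,
                        int n_samples, IntegerVector sample_demes, int n_demes,
                        double mu_bp, double L, bool haplotypes) {
  const int n_nodes = parent.size();
  const int n = n_samples;
  const int D = n_demes;

  // branch length above each non-root node
  std::vector<double> blen(n_nodes, 0.0);
  double T = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    if (parent[v] >= 0) {
      blen[v] = node_time[parent[v]] - node_time[v];
      T += blen[v];
    }
  }

  int S = (mu_bp * L * T > 0) ? (int)R::rpois(mu_bp * L * T) : 0;

  // leaves-per-deme below each node (nodes indexed in time order: child < parent)
  std::vector<int> leafcnt(n_nodes * D, 0);
  for (int v = 0; v < n; ++v) leafcnt[v * D + sample_demes[v]] = 1;
  for (int v = 0; v < n_nodes; ++v)
    if (parent[v] >= 0)
      for (int d = 0; d < D; ++d) leafcnt[parent[v] * D + d] += leafcnt[v * D + d];

  // cumulative branch lengths for placement
  std::vector<double> cum(n_nodes, 0.0);
  double run = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    run += blen[v];
    cum[v] = run;
  }

  std::vector<int> mut_node(S);
  NumericVector pos(S);
  for (int s = 0; s < S; ++s) {
    double u = unif_rand() * T;
    int lo = 0, hi = n_nodes - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    mut_node[s] = lo;
    pos[s] = unif_rand();
  }

  // sort by position
  IntegerVector ord(S);
  std::vector<int> idx(S);
  for (int s = 0; s < S; ++s) idx[s] = s;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) { return pos[a] < pos[b]; });

  NumericVector pos_sorted(S);
  IntegerMatrix counts(S, D);
  for (int s = 0; s < S; ++s) {
    pos_sorted[s] = pos[idx[s]];
    int v = mut_node[idx[s]];
    for (int d = 0; d < D; ++d) counts(s, d) = leafcnt[v * D + d];
  }

  List out = List::create(_["positions"] = pos_sorted, _["counts"] = counts,
                          _["total_length"] = T);

  if (haplotypes) {
    // children lists for subtree traversal
    std::vector<std::vector<int>> children(n_nodes);
    for (int v = 0; v < n_nodes; ++v)
      if (parent[v] >= 0) children[parent[v]].push_back(v);
    IntegerMatrix H(n, S);
    std::vector<int> stack;
    for (int s = 0; s < S; ++s) {
      int v0 = mut_node[idx[s]];
      stack.clear();
      stack.push_back(v0);
      while (!stack.empty()) {
        int v = stack.back();
        stack.pop_back();
        if (v < n) H(v, s) = 1;
        for (int c : children[v]) stack.push_back(c);
      }
    }
    out["haplotypes"] = H;
  }
  return out;
}
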