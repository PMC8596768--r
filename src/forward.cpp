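#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Individual-based forward Wright-Fisher simulator for one non-recombining
// locus in a constant multi-deme model. Haplotype classes form a persistent
// tree: each mutation event spawns a child class carrying one extra site, so
// class creation is O(1) and a class's site set is recovered by walking its
// ancestry. Selection acts through the selected site fully linked to the
// locus: with random union of gametes, genotype fitnesses (wAA, wAa, waa)
// reduce to marginal gamete weights wA = p*wAA + (1-p)*wAa and
// wa = p*wAa + (1-p)*waa. Per generation: selection -> migration (gamete
// pool mixing with forward fractions) -> multinomial drift (Walker alias
// sampling of 2N gametes) -> mutation.

struct Arena {
  std::vector<int> parent; // class tree
  std::vector<int> site;   // mutation id added by this class (-1 none)
  std::vector<uint8_t> sel;
  int new_class(int par, int st, uint8_t sl) {
    parent.push_back(par);
    site.push_back(st);
    sel.push_back(sl);
    return (int)parent.size() - 1;
  }
  void truncate(size_t k) {
    parent.resize(k);
    site.resize(k);
    sel.resize(k);
  }
};

// Fast local generator for the drift draws (xoshiro256+), seeded from R's
// RNG stream so runs remain reproducible under set.seed(); the structural
// draws (Poisson, hypergeometric, introduction) stay on R's generator.
struct FastRng {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  void seed_from_R() {
    uint64_t x = (uint64_t)(unif_rand() * 9007199254740992.0);
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

struct AliasTable {
  std::vector<double> prob;
  std::vector<int> alias;
  std::vector<int> small_, large_;
  int C = 0;
  void build(const double *p, int n, double psum) {
    C = n;
    prob.resize(n);
    alias.resize(n);
    small_.clear();
    large_.clear();
    for (int i = 0; i < n; ++i) {
      double pi = p[i] / psum * n;
      prob[i] = pi;
      alias[i] = i;
      if (pi < 1.0) small_.push_back(i); else large_.push_back(i);
    }
    while (!small_.empty() && !large_.empty()) {
      int s = small_.back(); small_.pop_back();
      int l = large_.back(); large_.pop_back();
      alias[s] = l;
      prob[l] -= (1.0 - prob[s]);
      if (prob[l] < 1.0) small_.push_back(l); else large_.push_back(l);
    }
    while (!small_.empty()) { prob[small_.back()] = 1.0; small_.pop_back(); }
    while (!large_.empty()) { prob[large_.back()] = 1.0; large_.pop_back(); }
  }
  inline int draw(FastRng &rng) const {
    double u = rng.unif() * C;
    int i = (int)u;
    if (i >= C) i = C - 1;
    return (u - i < prob[i]) ? i : alias[i];
  }
};

// [[Rcpp::export(name = ".cpp_forward_locus")]]
List cpp_forward_locus(IntegerVector N,        // diploid size per deme
                       NumericMatrix mig,      // forward fractions, off-diagonal
                       double muL,             // mutation rate per haplotype/gen
                       NumericMatrix fitness,  // D x 3: wAA, wAa, waa per deme
                       int t_burn, int t_sel,
                       NumericVector f_init,   // initial derived freq per deme
                       std::string origin,     // "standing", "de_novo", "none"
                       IntegerVector n_sample, // haploids sampled per deme
                       std::string retention,  // "not_lost" or "segregating"
                       int resample_cap) {
  const int D = N.size();
  std::vector<double> twoN(D);
  long total2N = 0;
  for (int d = 0; d < D; ++d) {
    twoN[d] = 2.0 * N[d];
    total2N += 2 * N[d];
  }

  Arena ar;
  std::vector<int> live; // class ids with >0 total count
  std::vector<std::vector<double>> cnt(D);

  int root = ar.new_class(-1, -1, 0);
  live.push_back(root);
  for (int d = 0; d < D; ++d) cnt[d].assign(1, twoN[d]);

  int next_site = 0;

  std::vector<std::vector<double>> phi(D), psi(D), newc(D);
  std::vector<double> cum;
  AliasTable alias;
  FastRng rng;
  rng.seed_from_R();

  std::vector<uint8_t> live_sel; // sel flag aligned with live
  live_sel.push_back(0);

  // nA_target: when non-negative, the per-deme derived-allele count this
  // generation is forced to the pre-simulated trajectory value and the
  // class multinomial is drawn conditionally on it (the factorization
  // draw-marginal-then-conditional leaves the joint law unchanged).
  std::vector<int> idx_der, idx_anc;
  std::vector<double> psi_sub;
  auto one_generation = [&](bool with_selection, const int *nA_target) {
    const size_t C = live.size();
    for (int d = 0; d < D; ++d) {
      phi[d].resize(C);
      const double *cd = cnt[d].data();
      double *pd_ = phi[d].data();
      if (!with_selection) {
        double inv = 1.0 / twoN[d];
        for (size_t i = 0; i < C; ++i) pd_[i] = cd[i] * inv;
      } else {
        double p = 0.0;
        for (size_t i = 0; i < C; ++i)
          if (live_sel[i]) p += cd[i];
        p /= twoN[d];
        double wA = p * fitness(d, 0) + (1.0 - p) * fitness(d, 1);
        double wa = p * fitness(d, 1) + (1.0 - p) * fitness(d, 2);
        double W = 0.0;
        for (size_t i = 0; i < C; ++i) {
          double w = cd[i] * (live_sel[i] ? wA : wa);
          pd_[i] = w;
          W += w;
        }
        double inv = 1.0 / W;
        for (size_t i = 0; i < C; ++i) pd_[i] *= inv;
      }
    }
    // migration mixing then drift
    for (int d = 0; d < D; ++d) {
      psi[d].resize(C);
      double self = 1.0;
      for (int j = 0; j < D; ++j)
        if (j != d) self -= mig(d, j);
      for (size_t i = 0; i < C; ++i) psi[d][i] = self * phi[d][i];
      for (int j = 0; j < D; ++j) {
        if (j == d) continue;
        double m = mig(d, j);
        if (m > 0)
          for (size_t i = 0; i < C; ++i) psi[d][i] += m * phi[j][i];
      }
    }
    for (int d = 0; d < D; ++d) {
      newc[d].assign(C, 0.0);
      if (C == 1 && nA_target == nullptr) {
        newc[d][0] = twoN[d];
        continue;
      }
      if (nA_target == nullptr) {
        alias.build(psi[d].data(), (int)C, 1.0);
        int n = (int)twoN[d];
        for (int q = 0; q < n; ++q) newc[d][alias.draw(rng)] += 1.0;
      } else {
        // conditional multinomial given the derived-allele total
        idx_der.clear(); idx_anc.clear();
        double sA = 0.0, sa = 0.0;
        for (size_t i = 0; i < C; ++i) {
          if (live_sel[i]) { idx_der.push_back((int)i); sA += psi[d][i]; }
          else { idx_anc.push_back((int)i); sa += psi[d][i]; }
        }
        int nA = nA_target[d];
        int na = (int)twoN[d] - nA;
        if (nA > 0) {
          if (idx_der.size() == 1) {
            newc[d][idx_der[0]] += nA;
          } else {
            psi_sub.resize(idx_der.size());
            for (size_t q = 0; q < idx_der.size(); ++q)
              psi_sub[q] = psi[d][idx_der[q]];
            alias.build(psi_sub.data(), (int)idx_der.size(), sA);
            for (int q = 0; q < nA; ++q) newc[d][idx_der[alias.draw(rng)]] += 1.0;
          }
        }
        if (na > 0) {
          if (idx_anc.size() == 1) {
            newc[d][idx_anc[0]] += na;
          } else {
            psi_sub.resize(idx_anc.size());
            for (size_t q = 0; q < idx_anc.size(); ++q)
              psi_sub[q] = psi[d][idx_anc[q]];
            alias.build(psi_sub.data(), (int)idx_anc.size(), sa);
            for (int q = 0; q < na; ++q) newc[d][idx_anc[alias.draw(rng)]] += 1.0;
          }
        }
      }
    }
    for (int d = 0; d < D; ++d) cnt[d].swap(newc[d]);
    // mutation: each new mutation hits a uniformly drawn gamete
    for (int d = 0; d < D; ++d) {
      int nmut = (muL > 0) ? (int)R::rpois(twoN[d] * muL) : 0;
      if (nmut == 0) continue;
      cum.resize(C);
      double run = 0.0;
      for (size_t i = 0; i < C; ++i) {
        run += cnt[d][i];
        cum[i] = run;
      }
      for (int m = 0; m < nmut; ++m) {
        int hit = -1;
        for (int tries = 0; tries < 64 && hit < 0; ++tries) {
          double u = rng.unif() * run;
          int lo = 0, hi = (int)C - 1;
          while (lo < hi) {
            int mid = (lo + hi) / 2;
            if (cum[mid] < u) lo = mid + 1; else hi = mid;
          }
          if (cnt[d][lo] > 0) hit = lo;
        }
        if (hit < 0) continue;
        cnt[d][hit] -= 1;
        int nc = ar.new_class(live[hit], next_site++, ar.sel[live[hit]]);
        live.push_back(nc);
        live_sel.push_back(ar.sel[nc]);
        for (int dd = 0; dd < D; ++dd) cnt[dd].push_back(dd == d ? 1.0 : 0.0);
      }
    }
    // compact: drop classes extinct in every deme
    size_t w = 0;
    for (size_t i = 0; i < live.size(); ++i) {
      double tot = 0.0;
      for (int d = 0; d < D; ++d) tot += cnt[d][i];
      if (tot > 0) {
        if (w != i) {
          live[w] = live[i];
          live_sel[w] = live_sel[i];
          for (int d = 0; d < D; ++d) cnt[d][w] = cnt[d][i];
        }
        ++w;
      }
    }
    live.resize(w);
    live_sel.resize(w);
    for (int d = 0; d < D; ++d) cnt[d].resize(w);
  };

  for (int g = 0; g < t_burn; ++g) {
    if (g % 4096 == 0) Rcpp::checkUserInterrupt();
    one_generation(false, nullptr);
  }

  bool with_sel = origin != "none";
  int restarts = 0;
  bool survived = true;

  if (with_sel) {
    // Survival conditioning at trajectory level: the derived-allele counts
    // form an autonomous Markov chain (selection -> deterministic migration
    // mixing -> binomial drift), so the whole path is pre-simulated and
    // rejection-resampled cheaply (the -SFC analogue); the haplotype-class
    // process is then simulated conditionally on the accepted path, which
    // leaves the joint forward Wright-Fisher law unchanged.
    std::vector<int> nA0(D);
    if (origin == "standing") {
      for (int d = 0; d < D; ++d) nA0[d] = (int)std::lround(f_init[d] * twoN[d]);
    } else {
      nA0[0] = 1;
      for (int d = 1; d < D; ++d) nA0[d] = 0;
    }
    std::vector<int> path((size_t)t_sel * D, 0);
    std::vector<double> p(D), pstar(D), pmix(D);
    for (;;) {
      for (int d = 0; d < D; ++d) p[d] = nA0[d] / twoN[d];
      for (int g = 0; g < t_sel; ++g) {
        for (int d = 0; d < D; ++d) {
          double pd = p[d];
          double wbar = pd * pd * fitness(d, 0) + 2.0 * pd * (1.0 - pd) * fitness(d, 1)
                        + (1.0 - pd) * (1.0 - pd) * fitness(d, 2);
          pstar[d] = (pd * pd * fitness(d, 0) + pd * (1.0 - pd) * fitness(d, 1)) / wbar;
        }
        for (int d = 0; d < D; ++d) {
          double self = 1.0;
          double acc = 0.0;
          for (int j = 0; j < D; ++j)
            if (j != d) { self -= mig(d, j); acc += mig(d, j) * pstar[j]; }
          pmix[d] = self * pstar[d] + acc;
        }
        for (int d = 0; d < D; ++d) {
          int nA = (pmix[d] <= 0) ? 0
                   : (pmix[d] >= 1) ? (int)twoN[d]
                   : (int)R::rbinom(twoN[d], pmix[d]);
          path[(size_t)g * D + d] = nA;
          p[d] = nA / twoN[d];
        }
      }
      double derived = 0.0;
      if (t_sel > 0) {
        for (int d = 0; d < D; ++d) derived += path[(size_t)(t_sel - 1) * D + d];
      } else {
        for (int d = 0; d < D; ++d) derived += nA0[d];
      }
      bool ok;
      if (retention == "segregating")
        ok = derived > 0 && derived < (double)total2N;
      else
        ok = derived > 0;
      if (ok) break;
      restarts++;
      if (restarts >= resample_cap) { survived = false; break; }
      if (restarts % 4096 == 0) Rcpp::checkUserInterrupt();
    }

    if (survived) {
      // introduce the derived allele on random haplotypes
      if (origin == "standing") {
        for (int d = 0; d < D; ++d) {
          int target = nA0[d];
          double pool = twoN[d];
          size_t C0 = live.size();
          for (size_t i = 0; i < C0 && target > 0; ++i) {
            double ci = cnt[d][i];
            if (ci <= 0) continue;
            int x;
            if (pool - ci <= 0) x = target;
            else x = (int)R::rhyper(ci, pool - ci, target);
            if (x > 0) {
              int nc = ar.new_class(live[i], -1, 1);
              live.push_back(nc);
              live_sel.push_back(1);
              for (int dd = 0; dd < D; ++dd)
                cnt[dd].push_back(dd == d ? (double)x : 0.0);
              cnt[d][i] -= x;
              target -= x;
            }
            pool -= ci;
          }
        }
      } else { // de_novo: single copy in deme 0
        double u = unif_rand() * twoN[0];
        double acc = 0.0;
        for (size_t i = 0; i < live.size(); ++i) {
          acc += cnt[0][i];
          if (u <= acc && cnt[0][i] > 0) {
            int nc = ar.new_class(live[i], -1, 1);
            live.push_back(nc);
            live_sel.push_back(1);
            for (int dd = 0; dd < D; ++dd)
              cnt[dd].push_back(dd == 0 ? 1.0 : 0.0);
            cnt[0][i] -= 1;
            break;
          }
        }
      }
      for (int g = 0; g < t_sel; ++g) {
        if (g % 1024 == 0) Rcpp::checkUserInterrupt();
        one_generation(true, path.data() + (size_t)g * D);
      }
    }
    } else if (t_sel > 0) {
    for (int g = 0; g < t_sel; ++g) {
      if (g % 4096 == 0) Rcpp::checkUserInterrupt();
      one_generation(false, nullptr);
    }
  }

  // final population frequencies of the derived allele
  NumericVector p_final(D);
  for (int d = 0; d < D; ++d) {
    double der = 0.0;
    for (size_t i = 0; i < live.size(); ++i)
      if (ar.sel[live[i]]) der += cnt[d][i];
    p_final[d] = der / twoN[d];
  }

  // sample haplotypes without replacement per deme
  int ntot = 0;
  for (int d = 0; d < D; ++d) ntot += n_sample[d];
  std::vector<int> samp_class(ntot);
  IntegerVector samp_deme(ntot);
  int si = 0;
  for (int d = 0; d < D; ++d) {
    int want = n_sample[d];
    double pool = twoN[d];
    for (size_t i = 0; i < live.size() && want > 0; ++i) {
      double ci = cnt[d][i];
      if (ci <= 0) continue;
      int x;
      if (pool - ci <= 0) x = want;
      else x = (int)R::rhyper(ci, pool - ci, want);
      for (int q = 0; q < x; ++q) {
        samp_class[si] = live[i];
        samp_deme[si] = d;
        si++;
      }
      want -= x;
      pool -= ci;
    }
  }

  // site sets of sampled classes
  std::unordered_map<int, std::vector<int>> class_sites;
  std::unordered_map<int, int> site_count;
  for (int i = 0; i < ntot; ++i) {
    int c = samp_class[i];
    if (!class_sites.count(c)) {
      std::vector<int> sites;
      for (int v = c; v >= 0; v = ar.parent[v])
        if (ar.site[v] >= 0) sites.push_back(ar.site[v]);
      class_sites[c] = sites;
    }
    for (int s : class_sites[c]) site_count[s] += 1;
  }

  // segregating sites among the sample
  std::vector<int> seg;
  for (auto &kv : site_count)
    if (kv.second > 0 && kv.second < ntot) seg.push_back(kv.first);
  std::sort(seg.begin(), seg.end());
  std::unordered_map<int, int> col;
  for (size_t j = 0; j < seg.size(); ++j) col[seg[j]] = (int)j;

  IntegerMatrix H(ntot, (int)seg.size());
  IntegerVector sel_state(ntot);
  for (int i = 0; i < ntot; ++i) {
    for (int s : class_sites[samp_class[i]]) {
      auto it = col.find(s);
      if (it != col.end()) H(i, it->second) = 1;
    }
    sel_state[i] = ar.sel[samp_class[i]];
  }

  return List::create(_["haplotypes"] = H, _["deme"] = samp_deme,
                      _["sel"] = sel_state, _["p_final"] = p_final,
                      _["survived"] = survived, _["restarts"] = restarts);
}
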