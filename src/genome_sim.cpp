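// Fragment-based discrete-generation backward Wright-Fisher coalescent.
//
// Each sampled haplotype starts as one lineage carrying an ancestry mask over
// fixed-length fragments. Going backward one generation at a time, every
// lineage draws a parent chromosome uniformly among the Ne(t) chromosomes of
// its current population (population sizes are chromosome counts, the GENOME
// convention: a size of N equals N/2 diploid individuals); an independent recombination event at each
// fragment boundary inside the lineage's span (probability `rec`) hands the
// downstream material to a freshly drawn parent chromosome. Lineages meeting
// in the same parent chromosome coalesce. Mutations are dropped on branches
// at coalescence time: Poisson(mu * fragment_length * n_fragments * branch
// generations), placed uniformly, infinite-sites within a fragment (repeated
// positions are re-drawn). A fragment is retired once a single lineage
// carries it (its sample MRCA has been reached); mutations above the MRCA are
// not segregating and are never emitted. Chromosomes are independent.
//
// Haplotypes are returned site-major, bit-packed (1 = derived).

#include <Rcpp.h>
#include <vector>
#include <deque>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Seg {
  int a, b;   // inclusive fragment interval
  int g;      // group (tree-branch) id
};

struct Lineage {
  int pop;
  std::vector<Seg> segs;
};

struct SiteRec {
  double pos;                 // 1-based bp within chromosome
  std::vector<uint8_t> row;   // packed carrier bits
  int count;                  // derived-allele count
};

class GroupStore {
public:
  std::vector<std::vector<int>> leaves;
  std::vector<double> birth;
  std::vector<int> refs;
  std::vector<int> freelist;

  int create(std::vector<int>&& lv, double t) {
    int id;
    if (!freelist.empty()) {
      id = freelist.back();
      freelist.pop_back();
      leaves[id] = std::move(lv);
      birth[id] = t;
      refs[id] = 0;
    } else {
      id = (int)leaves.size();
      leaves.push_back(std::move(lv));
      birth.push_back(t);
      refs.push_back(0);
    }
    return id;
  }
  void addref(int g) { ++refs[g]; }
  void decref(int g) {
    if (--refs[g] == 0) {
      leaves[g].clear();
      leaves[g].shrink_to_fit();
      freelist.push_back(g);
    }
  }
};

// piecewise-constant Ne lookup: epochs are half-open [t0, t1)
struct Epoch { double t0, t1, ne; };

class Demography {
public:
  std::vector<std::vector<Epoch>> epochs;   // per population
  std::vector<double> split_time;           // Inf if never splits
  std::vector<int> split_parent;

  double ne_at(int pop, double t) const {
    for (const Epoch& e : epochs[pop])
      if (t >= e.t0 && t < e.t1) return e.ne;
    stop("no Ne epoch covers generation %f for population %d", t, pop + 1);
    return 0.0;
  }
  // population holding a lineage when parents at depth t are drawn
  int pop_at(int pop, double t) const {
    while (split_time[pop] <= t) pop = split_parent[pop];
    return pop;
  }
};

inline void set_bit(std::vector<uint8_t>& row, int i) {
  row[i >> 3] |= (uint8_t)(1u << (i & 7));
}

// merge k sorted leaf vectors (pairwise-disjoint) into one sorted vector
std::vector<int> merge_leaves(const std::vector<const std::vector<int>*>& vs) {
  size_t tot = 0;
  for (auto v : vs) tot += v->size();
  std::vector<int> out;
  out.reserve(tot);
  if (vs.size() == 2) {
    std::merge(vs[0]->begin(), vs[0]->end(), vs[1]->begin(), vs[1]->end(),
               std::back_inserter(out));
    return out;
  }
  for (auto v : vs) out.insert(out.end(), v->begin(), v->end());
  std::sort(out.begin(), out.end());
  return out;
}

class ChromSim {
public:
  ChromSim(const Demography& dem, const std::vector<int>& hap_pop,
           int n_frag, double frag_len, double mu, double rec,
           double max_gen)
    : dem_(dem), n_hap_((int)hap_pop.size()), n_frag_(n_frag),
      frag_len_(frag_len), mu_(mu), rec_(rec), max_gen_(max_gen) {
    nbytes_ = (n_hap_ + 7) / 8;
    lins_.reserve(n_hap_);
    for (int i = 0; i < n_hap_; ++i) {
      int g = groups_.create(std::vector<int>{i}, 0.0);
      groups_.addref(g);
      Lineage L;
      L.pop = hap_pop[i];
      L.segs.push_back({0, n_frag_ - 1, g});
      lins_.push_back(std::move(L));
    }
    cc_.assign(n_frag_, n_hap_);
    n_incomplete_ = n_frag_;
    if (n_hap_ == 1) n_incomplete_ = 0;  // single haplotype: nothing segregates
  }

  void run() {
    double t = 0.0;
    while (n_incomplete_ > 0) {
      t += 1.0;
      if (t > max_gen_)
        stop("coalescent simulation exceeded max_gen = %g generations", max_gen_);
      step(t);
    }
  }

  std::vector<SiteRec>& sites() { return sites_; }
  int nbytes() const { return nbytes_; }

private:
  const Demography& dem_;
  int n_hap_, n_frag_;
  double frag_len_, mu_, rec_, max_gen_;
  int nbytes_;
  GroupStore groups_;
  std::vector<Lineage> lins_;
  std::vector<int> cc_;           // carrier count per fragment
  int n_incomplete_;
  std::vector<SiteRec> sites_;
  std::unordered_set<int64_t> used_pos_;

  void emit_mutations(int a, int b, double branch, const std::vector<int>& lv) {
    double lam = mu_ * frag_len_ * (double)(b - a + 1) * branch;
    if (lam <= 0.0) return;
    int nm = (int)R::rpois(lam);
    for (int m = 0; m < nm; ++m) {
      int frag, bp;
      int64_t key;
      int tries = 0;
      do {
        frag = a + (int)(unif_rand() * (double)(b - a + 1));
        if (frag > b) frag = b;
        bp = 1 + (int)(unif_rand() * frag_len_);
        if (bp > (int)frag_len_) bp = (int)frag_len_;
        key = (int64_t)frag * (int64_t)frag_len_ + (bp - 1);
        if (++tries > 1000) break;  // fragment saturated; drop (never in practice)
      } while (used_pos_.count(key));
      if (tries > 1000) continue;
      used_pos_.insert(key);
      SiteRec s;
      s.pos = (double)frag * frag_len_ + (double)bp;
      s.count = (int)lv.size();
      s.row.assign(nbytes_, 0);
      for (int leaf : lv) set_bit(s.row, leaf);
      sites_.push_back(std::move(s));
    }
  }

  void step(double t) {
    // effective population of every lineage at this parent generation
    int np = (int)dem_.epochs.size();
    std::vector<std::vector<int>> by_pop(np);
    for (size_t i = 0; i < lins_.size(); ++i) {
      int p = dem_.pop_at(lins_[i].pop, t);
      lins_[i].pop = p;
      by_pop[p].push_back((int)i);
    }

    // (parent chromosome) -> pieces of lineage material landing there
    std::unordered_map<int64_t, std::vector<std::vector<Seg>>> buckets;
    buckets.reserve(lins_.size() * 2);

    for (int p = 0; p < np; ++p) {
      if (by_pop[p].empty()) continue;
      // population sizes are numbers of chromosomes (GENOME convention):
      // the parent pool holds Ne(t) chromosome slots
      double M = dem_.ne_at(p, t);
      int Mi = (int)std::llround(M);
      // NB: the ancestral-graph lineage count may legitimately exceed Ne
      // (recombination grows it; bottlenecks shrink 2*Ne); lineages then
      // mass-coalesce, as in any backward Wright-Fisher step. Sampling more
      // haplotypes than the terminal population holds is rejected upstream.
      for (int li : by_pop[p]) {
        Lineage& L = lins_[li];
        int span_a = L.segs.front().a, span_b = L.segs.back().b;
        int nb = span_b - span_a;
        int kb = (nb > 0 && rec_ > 0.0) ? (int)R::rbinom((double)nb, rec_) : 0;
        std::vector<int> bps;  // boundary x splits fragments <= x from > x
        if (kb > 0) {
          std::unordered_set<int> chosen;
          while ((int)chosen.size() < kb) {
            int x = span_a + (int)(unif_rand() * (double)nb);
            if (x >= span_a + nb) x = span_a + nb - 1;
            chosen.insert(x);
          }
          bps.assign(chosen.begin(), chosen.end());
          std::sort(bps.begin(), bps.end());
        }
        auto draw_slot = [&]() -> int {
          int s = (int)(unif_rand() * M);
          if (s >= Mi) s = Mi - 1;
          return s;
        };
        size_t bi = 0;
        int slot = draw_slot();
        std::vector<Seg> piece;
        auto flush = [&]() {
          if (!piece.empty()) {
            int64_t key = ((int64_t)p << 32) | (int64_t)slot;
            buckets[key].push_back(std::move(piece));
            piece.clear();
          }
        };
        for (Seg s : L.segs) {
          while (bi < bps.size() && bps[bi] < s.b) {
            if (bps[bi] >= s.a) {
              // split seg at boundary bps[bi]
              Seg left{s.a, bps[bi], s.g};
              groups_.addref(s.g);  // one extra reference for the split
              piece.push_back(left);
              flush();
              slot = draw_slot();
              s.a = bps[bi] + 1;
            } else {
              // boundary falls in a gap between segments: new parent anyway
              flush();
              slot = draw_slot();
            }
            ++bi;
          }
          piece.push_back(s);
        }
        flush();
      }
    }

    // rebuild lineage list, coalescing buckets with >= 2 pieces
    std::vector<Lineage> next;
    next.reserve(buckets.size());
    for (auto& kv : buckets) {
      int pop = (int)(kv.first >> 32);
      auto& pieces = kv.second;
      if (pieces.size() == 1) {
        Lineage L;
        L.pop = pop;
        L.segs = std::move(pieces[0]);
        next.push_back(std::move(L));
        continue;
      }
      Lineage L;
      L.pop = pop;
      coalesce(pieces, t, L.segs);
      if (!L.segs.empty()) next.push_back(std::move(L));
    }
    lins_ = std::move(next);
  }

  // sweep-merge k piece seg-lists; emit mutations and build union groups on
  // overlaps; retire fragments whose carrier count reaches 1
  void coalesce(std::vector<std::vector<Seg>>& pieces, double t,
                std::vector<Seg>& out) {
    int k = (int)pieces.size();
    std::vector<size_t> idx(k, 0);
    std::vector<int> ns(k);  // next unconsumed fragment per piece
    for (int i = 0; i < k; ++i)
      ns[i] = pieces[i].empty() ? INT32_MAX : pieces[i][0].a;

    std::vector<int> cover;
    cover.reserve(k);
    for (;;) {
      int f = INT32_MAX;
      for (int i = 0; i < k; ++i)
        if (idx[i] < pieces[i].size() && ns[i] < f) f = ns[i];
      if (f == INT32_MAX) break;
      cover.clear();
      int e = INT32_MAX;
      for (int i = 0; i < k; ++i) {
        if (idx[i] >= pieces[i].size()) continue;
        if (ns[i] == f) {
          cover.push_back(i);
          if (pieces[i][idx[i]].b < e) e = pieces[i][idx[i]].b;
        } else if (ns[i] - 1 < e) {
          e = ns[i] - 1;
        }
      }
      if ((int)cover.size() == 1) {
        int i = cover[0];
        int g = pieces[i][idx[i]].g;
        if (push_out(out, f, e, g)) groups_.addref(g);
        advance(pieces[i], idx[i], ns[i], e);
        continue;
      }
      // true coalescence over [f, e]
      std::vector<const std::vector<int>*> lvs;
      lvs.reserve(cover.size());
      for (int i : cover) {
        int g = pieces[i][idx[i]].g;
        emit_mutations(f, e, t - groups_.birth[g], groups_.leaves[g]);
        lvs.push_back(&groups_.leaves[g]);
      }
      std::vector<int> un = merge_leaves(lvs);
      int d = (int)cover.size() - 1;
      // retire completed fragments; collect surviving sub-intervals
      int run_start = -1;
      int ng = -1;
      for (int x = f; x <= e; ++x) {
        cc_[x] -= d;
        bool complete = (cc_[x] == 1);
        if (complete) {
          cc_[x] = 0;  // retired
          --n_incomplete_;
          if (run_start >= 0) {
            if (ng < 0) ng = groups_.create(std::vector<int>(un), t);
            if (push_out(out, run_start, x - 1, ng)) groups_.addref(ng);
            run_start = -1;
          }
        } else if (run_start < 0) {
          run_start = x;
        }
      }
      if (run_start >= 0) {
        if (ng < 0) ng = groups_.create(std::move(un), t);
        if (push_out(out, run_start, e, ng)) groups_.addref(ng);
      }
      if (ng >= 0 && groups_.refs[ng] == 0) {
        groups_.addref(ng);
        groups_.decref(ng);
      }
      for (int i : cover) advance(pieces[i], idx[i], ns[i], e);
    }
    // release references held by the input pieces
    for (auto& pc : pieces)
      for (const Seg& s : pc) groups_.decref(s.g);
  }

  // returns true when a new seg entry (hence a new reference) was created
  static bool push_out(std::vector<Seg>& out, int a, int b, int g) {
    if (!out.empty() && out.back().g == g && out.back().b == a - 1) {
      out.back().b = b;  // coalesce adjacent identical-group intervals
      return false;
    }
    out.push_back({a, b, g});
    return true;
  }

  static void advance(std::vector<Seg>& piece, size_t& idx, int& ns, int e) {
    if (e >= piece[idx].b) {
      ++idx;
      ns = (idx < piece.size()) ? piece[idx].a : INT32_MAX;
    } else {
      ns = e + 1;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".simulate_genome_cpp")]]
List simulate_genome_cpp(IntegerVector hap_pop,       // 0-based population per haplotype
                         List epochs,                 // per pop: matrix (t0, t1, Ne)
                         NumericVector split_time,    // per pop, Inf if none
                         IntegerVector split_parent,  // 0-based, -1 if none
                         int n_chromosomes,
                         double chrom_length,
                         double fragment_length,
                         double mu,
                         double rec,
                         double max_gen = 5e6) {
  int np = epochs.size();
  Demography dem;
  dem.epochs.resize(np);
  for (int p = 0; p < np; ++p) {
    NumericMatrix m = epochs[p];
    for (int i = 0; i < m.nrow(); ++i)
      dem.epochs[p].push_back({m(i, 0), m(i, 1), m(i, 2)});
  }
  dem.split_time.assign(split_time.begin(), split_time.end());
  dem.split_parent.assign(split_parent.begin(), split_parent.end());

  int n_frag = (int)std::llround(chrom_length / fragment_length);
  std::vector<int> hp(hap_pop.begin(), hap_pop.end());
  int n_hap = (int)hp.size();
  int nbytes = (n_hap + 7) / 8;

  std::deque<SiteRec> all_sites;
  std::vector<int> site_chrom;

  for (int c = 0; c < n_chromosomes; ++c) {
    ChromSim sim(dem, hp, n_frag, fragment_length, mu, rec, max_gen);
    sim.run();
    std::vector<SiteRec>& st = sim.sites();
    std::sort(st.begin(), st.end(),
              [](const SiteRec& x, const SiteRec& y) { return x.pos < y.pos; });
    for (auto& s : st) {
      all_sites.push_back(std::move(s));
      site_chrom.push_back(c + 1);
    }
    Rcpp::checkUserInterrupt();
  }

  R_xlen_t S = (R_xlen_t)all_sites.size();
  RawVector bits((R_xlen_t)S * nbytes);
  NumericVector pos(S);
  IntegerVector chrom(S), count(S);
  for (R_xlen_t i = 0; i < S; ++i) {
    const SiteRec& s = all_sites[i];
    std::copy(s.row.begin(), s.row.end(), bits.begin() + i * nbytes);
    pos[i] = s.pos;
    chrom[i] = site_chrom[i];
    count[i] = s.count;
  }
  return List::create(_["bits"] = bits, _["n_hap"] = n_hap,
                      _["pos"] = pos, _["chrom"] = chrom, _["count"] = count);
}

// ---- bit-packed panel accessors -------------------------------------------

// diploid dosage matrix: individuals x sites. Individual k (1-based) owns
// haplotypes 2k-1 and 2k.
// [[Rcpp::export(name = ".panel_dosage_cpp")]]
IntegerMatrix panel_dosage_cpp(RawVector bits, int n_hap,
                               IntegerVector site_idx, IntegerVector ind_idx) {
  int nbytes = (n_hap + 7) / 8;
  int ns = site_idx.size(), ni = ind_idx.size();
  IntegerMatrix out(ni, ns);
  for (int j = 0; j < ns; ++j) {
    R_xlen_t off = (R_xlen_t)(site_idx[j] - 1) * nbytes;
    const uint8_t* row = (const uint8_t*)&bits[0] + off;
    for (int i = 0; i < ni; ++i) {
      int h1 = 2 * (ind_idx[i] - 1);
      int h2 = h1 + 1;
      int d = ((row[h1 >> 3] >> (h1 & 7)) & 1) + ((row[h2 >> 3] >> (h2 & 7)) & 1);
      out(i, j) = d;
    }
  }
  return out;
}

// haplotype 0/1 matrix: haplotypes x sites
// [[Rcpp::export(name = ".panel_haplotypes_cpp")]]
IntegerMatrix panel_haplotypes_cpp(RawVector bits, int n_hap,
                                   IntegerVector site_idx, IntegerVector hap_idx) {
  int nbytes = (n_hap + 7) / 8;
  int ns = site_idx.size(), nh = hap_idx.size();
  IntegerMatrix out(nh, ns);
  for (int j = 0; j < ns; ++j) {
    R_xlen_t off = (R_xlen_t)(site_idx[j] - 1) * nbytes;
    const uint8_t* row = (const uint8_t*)&bits[0] + off;
    for (int i = 0; i < nh; ++i) {
      int h = hap_idx[i] - 1;
      out(i, j) = (row[h >> 3] >> (h & 7)) & 1;
    }
  }
  return out;
}

// derived-allele count over a haplotype subset, for every site
// [[Rcpp::export(name = ".panel_subset_counts_cpp")]]
IntegerVector panel_subset_counts_cpp(RawVector bits, int n_hap, R_xlen_t n_site,
                                      IntegerVector hap_idx) {
  int nbytes = (n_hap + 7) / 8;
  int nh = hap_idx.size();
  IntegerVector out(n_site);
  for (R_xlen_t j = 0; j < n_site; ++j) {
    const uint8_t* row = (const uint8_t*)&bits[0] + j * nbytes;
    int c = 0;
    for (int i = 0; i < nh; ++i) {
      int h = hap_idx[i] - 1;
      c += (row[h >> 3] >> (h & 7)) & 1;
    }
    out[j] = c;
  }
  return out;
}
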