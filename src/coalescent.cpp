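// Structured-coalescent simulator for the two-population isolation-migration
// model with intra-locus (reciprocal) recombination and infinite-sites
// mutation.  Hudson-style ancestral recombination graph: lineages carry lists
// of ancestral segments, each segment tagged with the bitmask of sample tips
// it subtends.  Time is measured in units of 2*N_1 generations, so a branch of
// length t carries Poisson(theta * t / 2) mutations and the pairwise
// coalescence rate in population i is theta_1/theta_i per unit time.
//
// Rate book-keeping (per unit of 2*N_1 generations):
//   coalescence, pop i:        C(k_i, 2) * theta_1/theta_i
//   lineage in pop 1 -> pop 2: M_21 / 2                  (M_21 = 4 N_1 m_21)
//   lineage in pop 2 -> pop 1: (M_12 / 2) * theta_1/theta_2   (M_12 = 4 N_2 m_12)
//   recombination, lineage l:  (rho / 2) * (rmax_l - lmin_l), positions in [0,1]
// At time tau (2*N_1 units) the two populations merge into the ancestral one
// (relative size theta_A/theta_1) and migration stops.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <random>
#include <cmath>

using namespace Rcpp;

namespace {

struct Seg {
  double l, r;       // half-open [l, r) in [0, 1]
  uint64_t mask;     // sample tips subtended
};

struct Lineage {
  int pop;           // 0 = population 1, 1 = population 2 (0 = merged pop after tau)
  double tb;         // branch-segment birth time (for lazy length flushing)
  std::vector<Seg> segs;  // sorted, non-overlapping
  double lmin() const { return segs.front().l; }
  double rmax() const { return segs.back().r; }
};

struct Mut {
  double pos;
  uint64_t mask;
};

// splitmix64: decorrelate (seed, stream) pairs into mt19937_64 seeds
inline uint64_t mix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

class IMSim {
public:
  IMSim(int n1, int n2, double theta1, double theta2, double thetaA,
        double tau, double M12, double M21, double rho)
    : n1_(n1), n2_(n2), theta1_(theta1), tau_(tau), rho_(rho) {
    full_ = (n1 + n2 >= 64) ? ~0ULL : ((1ULL << (n1 + n2)) - 1ULL);
    // relative sizes; theta_1 > 0 enforced R-side
    x2_ = (theta2 > 0) ? theta2 / theta1 : 1.0;
    xA_ = (thetaA > 0) ? thetaA / theta1 : 1.0;
    crate_[0] = 1.0;
    crate_[1] = 1.0 / x2_;
    mig_[0] = M21 / 2.0;          // pop 1 lineage jumps (backwards) to pop 2
    mig_[1] = (M12 / 2.0) / x2_;  // pop 2 lineage jumps to pop 1
  }

  // simulate one ARG; accumulate span-weighted branch lengths and (optionally)
  // mutations.  L has (n1+1) x (n2+1) entries, column-major like R.
  // Branch lengths are flushed lazily: each lineage records the birth time of
  // its current segment set and contributes L (and mutations) only when an
  // event modifies it, so migration events cost O(1).
  void run(std::mt19937_64 &rng, std::vector<double> &L, bool want_muts,
           std::vector<Mut> *muts) {
    std::fill(L.begin(), L.end(), 0.0);
    Lp_ = &L;
    muts_ = want_muts ? muts : nullptr;
    rng_ = &rng;
    lin_.clear();
    for (int i = 0; i < n1_ + n2_; ++i) {
      Lineage l;
      l.pop = (i < n1_) ? 0 : 1;
      l.tb = 0.0;
      l.segs.push_back({0.0, 1.0, 1ULL << i});
      lin_.push_back(std::move(l));
    }
    bool merged = (tau_ <= 0.0);
    if (merged) merge_pops();
    double t = 0.0;
    std::uniform_real_distribution<double> unif(0.0, 1.0);

    while (!lin_.empty()) {
      int k[2] = {0, 0};
      double span = 0.0;
      for (const Lineage &l : lin_) {
        ++k[l.pop];
        span += l.rmax() - l.lmin();
      }
      double rc[2], rm[2];
      if (!merged) {
        rc[0] = 0.5 * k[0] * (k[0] - 1) * crate_[0];
        rc[1] = 0.5 * k[1] * (k[1] - 1) * crate_[1];
        rm[0] = k[0] * mig_[0];
        rm[1] = k[1] * mig_[1];
      } else {
        rc[0] = 0.5 * k[0] * (k[0] - 1) / xA_;
        rc[1] = rm[0] = rm[1] = 0.0;
      }
      double rr = 0.5 * rho_ * span;
      double total = rc[0] + rc[1] + rm[0] + rm[1] + rr;

      double dt;
      if (total <= 0.0) {
        // nothing can happen before the split time is reached
        dt = tau_ - t;
      } else {
        dt = std::exponential_distribution<double>(total)(rng);
      }
      if (!merged && t + dt >= tau_) {
        t = tau_;
        merge_pops();
        merged = true;
        continue;
      }
      t += dt;

      double u = unif(rng) * total;
      if (u < rc[0]) {
        coalesce(0, t, rng);
      } else if (u < rc[0] + rc[1]) {
        coalesce(1, t, rng);
      } else if (u < rc[0] + rc[1] + rm[0]) {
        migrate(0, rng);
      } else if (u < rc[0] + rc[1] + rm[0] + rm[1]) {
        migrate(1, rng);
      } else {
        recombine(rng, t, span);
      }
    }
  }

private:
  int n1_, n2_;
  double theta1_, tau_, rho_, x2_, xA_;
  double crate_[2], mig_[2];
  uint64_t full_;
  std::vector<Lineage> lin_;
  std::vector<double> *Lp_ = nullptr;
  std::vector<Mut> *muts_ = nullptr;
  std::mt19937_64 *rng_ = nullptr;

  void merge_pops() {
    for (Lineage &l : lin_) l.pop = 0;
  }

  inline void cellcount(uint64_t m, int &i, int &j) const {
    uint64_t m1 = m & ((n1_ >= 64) ? ~0ULL : ((1ULL << n1_) - 1ULL));
#if defined(__GNUC__) || defined(__clang__)
    i = __builtin_popcountll(m1);
    j = __builtin_popcountll(m ^ m1);
#else
    i = 0; j = 0;
    for (uint64_t x = m1; x; x &= x - 1) ++i;
    for (uint64_t x = m ^ m1; x; x &= x - 1) ++j;
#endif
  }

  // record the branch contributions of a lineage over [l.tb, t)
  void flush(Lineage &l, double t) {
    double dt = t - l.tb;
    if (dt > 0.0) {
      for (const Seg &s : l.segs) {
        double len = s.r - s.l;
        int i, j;
        cellcount(s.mask, i, j);
        (*Lp_)[i + (std::size_t)(n1_ + 1) * j] += dt * len;
        if (muts_) {
          double mean = 0.5 * theta1_ * dt * len;
          if (mean > 0.0) {
            int nm = std::poisson_distribution<int>(mean)(*rng_);
            for (int m = 0; m < nm; ++m) {
              double pos = s.l + len *
                std::uniform_real_distribution<double>(0.0, 1.0)(*rng_);
              muts_->push_back({pos, s.mask});
            }
          }
        }
      }
    }
    l.tb = t;
  }

  // index of the r-th (0-based) lineage currently in population pop
  int nth_in_pop(int pop, int r) const {
    for (int i = 0; i < (int)lin_.size(); ++i)
      if (lin_[i].pop == pop && r-- == 0) return i;
    return (int)lin_.size() - 1;  // unreachable
  }

  void coalesce(int pop, double t, std::mt19937_64 &rng) {
    int na = 0;
    for (const Lineage &l : lin_) if (l.pop == pop) ++na;
    int a = std::uniform_int_distribution<int>(0, na - 1)(rng);
    int b = std::uniform_int_distribution<int>(0, na - 2)(rng);
    if (b >= a) ++b;
    int ia = nth_in_pop(pop, a), ib = nth_in_pop(pop, b);
    flush(lin_[ia], t);
    flush(lin_[ib], t);
    std::vector<Seg> merged = merge_segs(lin_[ia].segs, lin_[ib].segs);
    if (ia > ib) std::swap(ia, ib);
    lin_.erase(lin_.begin() + ib);
    if (merged.empty()) {
      lin_.erase(lin_.begin() + ia);
    } else {
      lin_[ia].segs = std::move(merged);
      lin_[ia].tb = t;
    }
  }

  // union of two sorted segment lists; overlaps get the OR of the masks,
  // fully-coalesced pieces (mask == full) leave the ancestral material
  std::vector<Seg> merge_segs(const std::vector<Seg> &A,
                              const std::vector<Seg> &B) const {
    std::vector<Seg> out;
    std::size_t ia = 0, ib = 0;
    double pos = std::min(A.front().l, B.front().l);
    while (ia < A.size() || ib < B.size()) {
      bool inA = ia < A.size();
      bool inB = ib < B.size();
      double la = inA ? A[ia].l : 2.0, ra = inA ? A[ia].r : 2.0;
      double lb = inB ? B[ib].l : 2.0, rb = inB ? B[ib].r : 2.0;
      pos = std::max(pos, std::min(la, lb));
      bool coverA = inA && la <= pos;
      bool coverB = inB && lb <= pos;
      double nxt;
      uint64_t mask = 0;
      if (coverA && coverB) {
        mask = A[ia].mask | B[ib].mask;
        nxt = std::min(ra, rb);
      } else if (coverA) {
        mask = A[ia].mask;
        nxt = std::min(ra, inB ? lb : 2.0);
      } else {
        mask = B[ib].mask;
        nxt = std::min(rb, inA ? la : 2.0);
      }
      if (mask != full_ && nxt > pos) {
        if (!out.empty() && out.back().r == pos && out.back().mask == mask)
          out.back().r = nxt;
        else
          out.push_back({pos, nxt, mask});
      }
      if (coverA && ra <= nxt) ++ia;
      if (coverB && rb <= nxt) ++ib;
      pos = nxt;
    }
    return out;
  }

  void migrate(int pop, std::mt19937_64 &rng) {
    int na = 0;
    for (const Lineage &l : lin_) if (l.pop == pop) ++na;
    int a = std::uniform_int_distribution<int>(0, na - 1)(rng);
    lin_[nth_in_pop(pop, a)].pop = 1 - pop;
  }

  void recombine(std::mt19937_64 &rng, double t, double totspan) {
    double u = std::uniform_real_distribution<double>(0.0, totspan)(rng);
    int pick = -1;
    for (int i = 0; i < (int)lin_.size(); ++i) {
      double s = lin_[i].rmax() - lin_[i].lmin();
      if (u < s) { pick = i; break; }
      u -= s;
    }
    if (pick < 0) pick = (int)lin_.size() - 1;
    Lineage &l = lin_[pick];
    double bp = l.lmin() + u;  // uniform on (lmin, rmax), incl. trapped gaps
    std::vector<Seg> left, right;
    for (const Seg &s : l.segs) {
      if (s.r <= bp) left.push_back(s);
      else if (s.l >= bp) right.push_back(s);
      else {
        left.push_back({s.l, bp, s.mask});
        right.push_back({bp, s.r, s.mask});
      }
    }
    if (left.empty() || right.empty()) return;  // breakpoint outside material
    flush(l, t);
    Lineage nl;
    nl.pop = l.pop;
    nl.tb = t;
    nl.segs = std::move(right);
    l.segs = std::move(left);
    lin_.push_back(std::move(nl));
  }
};

std::mt19937_64 stream_rng(double seed, int stream) {
  uint64_t s = mix64(mix64((uint64_t)seed) ^ (uint64_t)(uint32_t)stream);
  return std::mt19937_64(s);
}

} // namespace

// [[Rcpp::export]]
List cpp_sim_loci(int n1, int n2, double theta1, double theta2, double thetaA,
                  double tau, double M12, double M21, double rho,
                  int num_loci, double seed, bool want_haplotypes,
                  bool want_spectrum) {
  if (n1 + n2 > 64)
    stop("total sample size n1 + n2 must be at most 64");
  IMSim sim(n1, n2, theta1, theta2, thetaA, tau, M12, M21, rho);
  std::vector<double> L((std::size_t)(n1 + 1) * (n2 + 1));
  List out(num_loci);
  for (int loc = 0; loc < num_loci; ++loc) {
    std::mt19937_64 rng = stream_rng(seed, loc);
    std::vector<Mut> muts;
    sim.run(rng, L, want_haplotypes, want_haplotypes ? &muts : nullptr);
    List rec;
    if (want_spectrum) {
      NumericMatrix Lm(n1 + 1, n2 + 1);
      std::copy(L.begin(), L.end(), Lm.begin());
      rec["spectrum"] = Lm;
    }
    if (want_haplotypes) {
      std::sort(muts.begin(), muts.end(),
                [](const Mut &a, const Mut &b) { return a.pos < b.pos; });
      int S = (int)muts.size();
      NumericVector pos(S);
      IntegerMatrix haps(n1 + n2, S);
      for (int s = 0; s < S; ++s) {
        pos[s] = muts[s].pos;
        for (int r = 0; r < n1 + n2; ++r)
          haps(r, s) = (muts[s].mask >> r) & 1ULL;
      }
      rec["positions"] = pos;
      rec["haplotypes"] = haps;
    }
    out[loc] = rec;
  }
  return out;
}

// Fast path for grid training: pooled JSFS over num_loci loci, mutations drawn
// per JSFS cell as Poisson((theta_1/2) * L_ij) given each locus's ARG.
// [[Rcpp::export]]
IntegerMatrix cpp_sim_jsfs(int n1, int n2, double theta1, double theta2,
                           double thetaA, double tau, double M12, double M21,
                           double rho, int num_loci, double seed) {
  if (n1 + n2 > 64)
    stop("total sample size n1 + n2 must be at most 64");
  IMSim sim(n1, n2, theta1, theta2, thetaA, tau, M12, M21, rho);
  std::vector<double> L((std::size_t)(n1 + 1) * (n2 + 1));
  IntegerMatrix S(n1 + 1, n2 + 1);
  for (int loc = 0; loc < num_loci; ++loc) {
    std::mt19937_64 rng = stream_rng(seed, loc);
    sim.run(rng, L, false, nullptr);
    for (std::size_t c = 0; c < L.size(); ++c) {
      if (L[c] > 0.0) {
        double mean = 0.5 * theta1 * L[c];
        S[c] += std::poisson_distribution<int>(mean)(rng);
      }
    }
  }
  return S;
}
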