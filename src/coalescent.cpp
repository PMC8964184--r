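// Structured-coalescent Monte Carlo engine.
//
// Epoch schedules are passed from R as a numeric matrix, one row per epoch in
// backward-time order (most recent first). Columns:
//   0 dur    epoch duration in units of 2*Nref generations (Inf for the last)
//   1 s1     deme-1 size at the epoch start (recent end), Nref units
//   2 b1     deme-1 backward growth rate: nu1(tau) = s1 * exp(b1 * tau)
//   3 s2     deme-2 size at epoch start (ignored when ndemes == 1)
//   4 b2     deme-2 backward growth rate
//   5 r12    backward per-lineage migration rate deme1 -> deme2 (= m12/2)
//   6 r21    backward per-lineage migration rate deme2 -> deme1 (= m21/2)
//   7 ndemes 2 before the merge, 1 from the merge on
//
// Time units follow the usual SFS convention: sizes are ratios to Nref,
// durations are in 2*Nref generations, so a pair of lineages in a deme of
// size nu coalesces at rate 1/nu and E[branch length with i descendants]
// in a panmictic constant-size-1 population is 2/i.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// SplitMix64: seeds one independent, reproducible stream per replicate.
inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// xoshiro256++ core; small, fast, and stable across platforms (the C++
// standard library distributions are implementation-defined, so raw
// uniforms are transformed by hand).
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in (0, 1)
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double expdraw(double rate) {
    return -std::log(unif()) / rate;
  }
  inline int below(int n) {  // uniform integer in [0, n)
    return static_cast<int>(next() % static_cast<uint64_t>(n));
  }
  int poisson(double lambda) {
    // Poisson(a + b) = Poisson(a) + Poisson(b): split large means so the
    // multiplication method never underflows.
    int total = 0;
    while (lambda > 30.0) {
      total += poisson(30.0);
      lambda -= 30.0;
    }
    double limit = std::exp(-lambda), prod = unif();
    int k = 0;
    while (prod > limit) { prod *= unif(); ++k; }
    return total + k;
  }
};

struct Branch {
  double len;
  int ci, cj;       // leaf class: pop-1 leaves, pop-2 leaves below the branch
  uint64_t mask;    // leaf set (leaf index bit), valid when n1 + n2 <= 64
};

// Waiting time to the next coalescence among k lineages in a deme of size
// nu(tau) = s0 * exp(b * (tloc + tau)), starting at local epoch time tloc.
// Returns Inf when the cumulative hazard over [0, Inf) is exhausted first.
inline double coal_wait(int k, double s0, double b, double tloc, Rng &rng) {
  if (k < 2) return R_PosInf;
  double cr = 0.5 * k * (k - 1);
  double E = -std::log(rng.unif());
  if (b == 0.0) return E * s0 / cr;
  // integral_0^w cr/(s0 e^{b(tloc+u)}) du = cr/(s0 b) e^{-b tloc} (1 - e^{-b w})
  double X = E * s0 * b * std::exp(b * tloc) / cr;
  double arg = 1.0 - X;
  if (arg <= 0.0) return R_PosInf;  // only possible when b > 0 (size grows backward)
  return -std::log(arg) / b;
}

// One genealogy under the schedule; appends the (2n - 2) non-root branches.
void simulate_once(const NumericMatrix &ep, int n1, int n2, Rng &rng,
                   std::vector<Branch> &branches) {
  const int n = n1 + n2;
  std::vector<int> deme(n), ci(n), cj(n);
  std::vector<double> birth(n, 0.0);
  std::vector<uint64_t> mask(n);
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) {
    deme[i] = (i < n1) ? 0 : 1;
    ci[i] = (i < n1) ? 1 : 0;
    cj[i] = (i < n1) ? 0 : 1;
    mask[i] = 1ULL << i;
    active[i] = i;
  }
  int nact = n, e = 0;
  const int nep = ep.nrow();
  double t = 0.0, tloc = 0.0;
  std::vector<int> in0, in1;
  in0.reserve(n); in1.reserve(n);

  while (nact > 1) {
    const double dur = ep(e, 0);
    const int nd = static_cast<int>(ep(e, 7));
    in0.clear(); in1.clear();
    for (int a = 0; a < nact; ++a) {
      int L = active[a];
      if (nd == 1 || deme[L] == 0) in0.push_back(L); else in1.push_back(L);
    }
    const int k0 = static_cast<int>(in0.size());
    const int k1 = static_cast<int>(in1.size());

    double w0 = coal_wait(k0, ep(e, 1), ep(e, 2), tloc, rng);
    double w1 = (nd == 2) ? coal_wait(k1, ep(e, 3), ep(e, 4), tloc, rng) : R_PosInf;
    double r12 = (nd == 2) ? ep(e, 5) : 0.0;
    double r21 = (nd == 2) ? ep(e, 6) : 0.0;
    double wm0 = (r12 > 0.0 && k0 > 0) ? rng.expdraw(k0 * r12) : R_PosInf;
    double wm1 = (r21 > 0.0 && k1 > 0) ? rng.expdraw(k1 * r21) : R_PosInf;

    double remain = dur - tloc;
    double w = std::min(std::min(w0, w1), std::min(wm0, wm1));
    if (w >= remain) {            // epoch boundary (never reached when dur = Inf)
      t += remain;
      ++e;
      if (e >= nep) e = nep - 1;  // defensive; last epoch is unbounded
      tloc = 0.0;
      if (static_cast<int>(ep(e, 7)) == 1)
        for (int a = 0; a < nact; ++a) deme[active[a]] = 0;  // merge
      continue;
    }
    t += w; tloc += w;
    if (w0 <= w1 && w0 <= wm0 && w0 <= wm1) {        // coalescence in deme 0
      int ia = rng.below(k0);
      int ib = rng.below(k0 - 1);
      if (ib >= ia) ++ib;
      int A = in0[ia], B = in0[ib];
      branches.push_back({t - birth[A], ci[A], cj[A], mask[A]});
      branches.push_back({t - birth[B], ci[B], cj[B], mask[B]});
      ci[A] += ci[B]; cj[A] += cj[B]; mask[A] |= mask[B]; birth[A] = t;
      for (int a = 0; a < nact; ++a)
        if (active[a] == B) { active[a] = active[nact - 1]; break; }
      --nact;
    } else if (w1 <= wm0 && w1 <= wm1) {              // coalescence in deme 1
      int ia = rng.below(k1);
      int ib = rng.below(k1 - 1);
      if (ib >= ia) ++ib;
      int A = in1[ia], B = in1[ib];
      branches.push_back({t - birth[A], ci[A], cj[A], mask[A]});
      branches.push_back({t - birth[B], ci[B], cj[B], mask[B]});
      ci[A] += ci[B]; cj[A] += cj[B]; mask[A] |= mask[B]; birth[A] = t;
      for (int a = 0; a < nact; ++a)
        if (active[a] == B) { active[a] = active[nact - 1]; break; }
      --nact;
    } else if (wm0 <= wm1) {                          // migration deme 0 -> 1
      deme[in0[rng.below(k0)]] = 1;
    } else {                                          // migration deme 1 -> 0
      deme[in1[rng.below(k1)]] = 0;
    }
  }
}

inline uint64_t rep_seed(double seed, int rep) {
  uint64_t base = static_cast<uint64_t>(seed);
  uint64_t x = base ^ (0x9E3779B97F4A7C15ULL * (static_cast<uint64_t>(rep) + 1));
  return splitmix64(x);
}

}  // namespace

// [[Rcpp::export(name = ".coal_lengths_cpp")]]
List coal_lengths_cpp(NumericMatrix epochs, int n1, int n2, int nreps, double seed) {
  if (n1 + n2 < 2) stop("need at least two sampled lineages");
  NumericMatrix sum(n1 + 1, n2 + 1), sumsq(n1 + 1, n2 + 1);
  std::vector<Branch> branches;
  std::vector<double> rep((n1 + 1) * (n2 + 1));
  for (int r = 0; r < nreps; ++r) {
    Rng rng(rep_seed(seed, r));
    branches.clear();
    simulate_once(epochs, n1, n2, rng, branches);
    std::fill(rep.begin(), rep.end(), 0.0);
    for (const Branch &b : branches) rep[b.ci * (n2 + 1) + b.cj] += b.len;
    for (int i = 0; i <= n1; ++i)
      for (int j = 0; j <= n2; ++j) {
        double v = rep[i * (n2 + 1) + j];
        sum(i, j) += v;
        sumsq(i, j) += v * v;
      }
  }
  return List::create(_["sum"] = sum, _["sumsq"] = sumsq, _["nreps"] = nreps);
}

// [[Rcpp::export(name = ".coal_mutations_cpp")]]
List coal_mutations_cpp(NumericMatrix epochs, int n1, int n2, int nloci,
                        double theta_per_locus, double seed) {
  const int n = n1 + n2;
  if (n > 64) stop("mutation simulation supports at most 64 haplotypes");
  std::vector<int> locus_of;
  std::vector<uint64_t> snp_mask;
  std::vector<Branch> branches;
  for (int loc = 0; loc < nloci; ++loc) {
    Rng rng(rep_seed(seed, loc));
    branches.clear();
    simulate_once(epochs, n1, n2, rng, branches);
    double ltot = 0.0;
    for (const Branch &b : branches) ltot += b.len;
    int nmut = (theta_per_locus > 0.0) ? rng.poisson(0.5 * theta_per_locus * ltot) : 0;
    for (int m = 0; m < nmut; ++m) {
      double u = rng.unif() * ltot, acc = 0.0;
      uint64_t hit = branches.back().mask;
      for (const Branch &b : branches) {
        acc += b.len;
        if (u <= acc) { hit = b.mask; break; }
      }
      locus_of.push_back(loc + 1);
      snp_mask.push_back(hit);
    }
  }
  const int nsnp = static_cast<int>(locus_of.size());
  IntegerMatrix hap(nsnp, n);
  IntegerVector loci(nsnp);
  for (int s = 0; s < nsnp; ++s) {
    loci[s] = locus_of[s];
    for (int i = 0; i < n; ++i)
      hap(s, i) = (snp_mask[s] >> i) & 1ULL ? 1 : 0;
  }
  return List::create(_["locus"] = loci, _["hap"] = hap);
}
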