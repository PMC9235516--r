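// Compiled kernels: seeded k-mer hashing, sliding-window minimizer selection,
// window charging, the configuration-count sum C, exact expectation by
// permutation enumeration, Monte-Carlo hash replicates, and duplicate-free
// sequence generators.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cstdint>
#include <cstring>
#include <numeric>
#include <random>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// 64-bit mixing. Hash values are a deterministic function of (seed, k-mer
// content) only, so equal k-mers in different sequences always receive equal
// values; the mixer plays the role of the idealized uniform [0,1) hash.
// ---------------------------------------------------------------------------

static inline uint64_t sm_mix(uint64_t x) {
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t fnv1a64(const char* s, size_t n) {
  uint64_t h = 0xCBF29CE484222325ULL;
  for (size_t i = 0; i < n; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 0x100000001B3ULL;
  }
  return h;
}

// top 53 bits -> [0, 1)
static inline double to_unit(uint64_t v) {
  return (double)(v >> 11) * (1.0 / 9007199254740992.0);
}

static inline uint64_t seed_key(uint64_t seed) {
  return sm_mix(seed + 0x9E3779B97F4A7C15ULL);
}

static inline double hash_value(uint64_t h0, uint64_t skey) {
  return to_unit(sm_mix(h0 ^ skey));
}

// [[Rcpp::export]]
NumericVector hash_kmers_cpp(CharacterVector kmers, double seed) {
  uint64_t skey = seed_key((uint64_t)seed);
  R_xlen_t n = kmers.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    out[i] = hash_value(fnv1a64(s, std::strlen(s)), skey);
  }
  return out;
}

// counter-mode seed stream from a master seed (53-bit values)
// [[Rcpp::export]]
NumericVector derive_seeds_cpp(double master, int n) {
  NumericVector out(n);
  uint64_t m = (uint64_t)master;
  for (int i = 0; i < n; ++i) {
    out[i] = (double)(sm_mix(m + (uint64_t)(i + 1) * 0x9E3779B97F4A7C15ULL) >> 11);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Minimizer selection: position p is selected iff it is the (leftmost) argmin
// of at least one window of w consecutive positions.
// ---------------------------------------------------------------------------

template <typename T>
static void select_minimizers(const T* a, int L, int w, uint8_t* sel, int* dq) {
  int head = 0, tail = 0;
  for (int idx = 0; idx < L; ++idx) {
    // keep earlier index on ties -> leftmost argmin
    while (tail > head && a[dq[tail - 1]] > a[idx]) --tail;
    dq[tail++] = idx;
    if (idx >= w - 1) {
      int s = idx - w + 1;
      while (dq[head] < s) ++head;
      sel[dq[head]] = 1;
    }
  }
}

// [[Rcpp::export]]
IntegerVector minimizer_positions_cpp(NumericVector a, int w) {
  int L = a.size();
  if (w < 1) stop("w must be >= 1");
  if (L < w) stop("sequence has fewer than w k-mers");
  std::vector<uint8_t> sel(L, 0);
  std::vector<int> dq(L);
  select_minimizers(REAL(a), L, w, sel.data(), dq.data());
  std::vector<int> pos;
  pos.reserve(2 * L / (w + 1) + 4);
  for (int p = 0; p < L; ++p)
    if (sel[p]) pos.push_back(p);
  return wrap(pos);
}

// ---------------------------------------------------------------------------
// Charging: p charges index i iff i in [max(-1, p-w), min(p-1, L-w-1)],
// a_p is the (leftmost) min of the window [i+1, i+w], and either
// i == max(-1, p-w) or a_i < a_p.  Exactly one i qualifies iff p is a
// minimizer.
// ---------------------------------------------------------------------------

static bool charges_at(const double* a, int L, int p, int w, int i) {
  int imin = std::max(-1, p - w);
  if (i < imin || i > std::min(p - 1, L - w - 1)) return false;
  double ap = a[p];
  for (int u = i + 1; u <= i + w; ++u) {
    if (u == p) continue;
    if (a[u] < ap || (a[u] == ap && u < p)) return false;
  }
  return i == imin || a[i] < ap;
}

// the unique charged index, or NA
// [[Rcpp::export]]
IntegerVector charge_index_cpp(NumericVector a, int p, int w) {
  int L = a.size();
  if (p < 0 || p >= L) stop("p out of range");
  IntegerVector out(1);
  out[0] = NA_INTEGER;
  int imin = std::max(-1, p - w), imax = std::min(p - 1, L - w - 1);
  for (int i = imin; i <= imax; ++i) {
    if (charges_at(REAL(a), L, p, w, i)) {
      out[0] = i;
      break;
    }
  }
  return out;
}

// every index charged by p (uniqueness checks enumerate this)
// [[Rcpp::export]]
IntegerVector charge_index_all_cpp(NumericVector a, int p, int w) {
  int L = a.size();
  if (p < 0 || p >= L) stop("p out of range");
  std::vector<int> hits;
  int imin = std::max(-1, p - w), imax = std::min(p - 1, L - w - 1);
  for (int i = imin; i <= imax; ++i)
    if (charges_at(REAL(a), L, p, w, i)) hits.push_back(i);
  return wrap(hits);
}

// ---------------------------------------------------------------------------
// Configuration-count sum C: for every matched pair (p, q) and every pair of
// legal charged indices (i, j), the joint charging event has probability
// x^alpha (1-x)^beta given the anchor value x, where alpha/beta count the
// below/above constraints with matched positions merged into one variable;
// conflicting signs zero the term.  Integrating over x gives a Beta integral.
// Contributions depend only on the local matching layout, so they are cached
// by a neighbourhood signature.
// ---------------------------------------------------------------------------

static double pair_contribution(const int* mA, int LA, int LB, int w, int p,
                                int q, const std::vector<double>& b0,
                                const std::vector<double>& b1,
                                const std::vector<double>& b2,
                                std::vector<int8_t>& bsign) {
  double total = 0.0;
  int imin = std::max(-1, p - w), imax = std::min(p - 1, LA - w - 1);
  int jmin = std::max(-1, q - w), jmax = std::min(q - 1, LB - w - 1);
  int off = q - w;  // bsign is indexed by (B position - off), range [0, 2w]
  for (int j = jmin; j <= jmax; ++j) {
    std::fill(bsign.begin(), bsign.end(), 0);
    int alphaB = 0, betaB = 0;
    if (j != jmin) {
      bsign[j - off] = 1;
      ++alphaB;
    }
    for (int v = j + 1; v <= j + w; ++v) {
      if (v == q) continue;
      bsign[v - off] = 2;
      ++betaB;
    }
    for (int i = imin; i <= imax; ++i) {
      int alpha = alphaB, beta = betaB;
      bool ok = true;
      if (i != imin) {
        int v = mA[i];
        if (v >= q - w && v <= q + w && v >= 0 && bsign[v - off] != 0) {
          if (bsign[v - off] != 1) ok = false;  // matched pair, opposite signs
          // else merged: already counted once on the B side
        } else {
          ++alpha;
        }
      }
      if (ok) {
        for (int u = i + 1; u <= i + w; ++u) {
          if (u == p) continue;
          int v = mA[u];
          if (v >= q - w && v <= q + w && v >= 0 && bsign[v - off] != 0) {
            if (bsign[v - off] != 2) {
              ok = false;
              break;
            }
          } else {
            ++beta;
          }
        }
      }
      if (ok) {
        total += (alpha == 0) ? b0[beta] : (alpha == 1 ? b1[beta] : b2[beta]);
      }
    }
  }
  return total;
}

// matchA[p] = matched position in B (0-based) or -1
// [[Rcpp::export]]
double expected_intersection_cpp(IntegerVector matchA, int LB, int w) {
  int LA = matchA.size();
  if (w < 2) stop("w must be >= 2");
  if (LA < w + 1 || LB < w + 1) stop("need L >= w + 1");
  const int* mA = INTEGER(matchA);
  // closed-form Beta integrals: alpha! beta! / (alpha+beta+1)! for alpha<=2
  std::vector<double> b0(2 * w + 1), b1(2 * w + 1), b2(2 * w + 1);
  for (int b = 0; b <= 2 * w; ++b) {
    double d1 = b + 1.0, d2 = b + 2.0, d3 = b + 3.0;
    b0[b] = 1.0 / d1;
    b1[b] = 1.0 / (d1 * d2);
    b2[b] = 2.0 / (d1 * d2 * d3);
  }
  std::vector<int8_t> bsign(2 * w + 1);
  std::unordered_map<std::string, double> cache;
  std::string key;
  key.reserve(4 * (w + 3));
  double C = 0.0;
  for (int p = 0; p < LA; ++p) {
    int q = mA[p];
    if (q < 0) continue;
    key.clear();
    auto push16 = [&key](int v) {
      key.push_back((char)(v & 0xFF));
      key.push_back((char)((v >> 8) & 0xFF));
    };
    push16(std::min(p, w));
    push16(std::min(LA - 1 - p, w));
    push16(std::min(q, w));
    push16(std::min(LB - 1 - q, w));
    for (int d = -w; d <= w - 1; ++d) {
      int u = p + d, code = 0x7FFF;
      if (d != 0 && u >= 0 && u < LA) {
        int v = mA[u];
        if (v >= 0) {
          int rd = v - q;
          if (rd >= -w && rd <= w) code = rd;
        }
      }
      push16(code);
    }
    auto it = cache.find(key);
    if (it == cache.end()) {
      double contrib = pair_contribution(mA, LA, LB, w, p, q, b0, b1, b2, bsign);
      cache.emplace(key, contrib);
      C += contrib;
    } else {
      C += it->second;
    }
  }
  return C;
}

// ---------------------------------------------------------------------------
// Exact expectations: only the relative order of hash values matters, so the
// expectation over the idealized hash equals the average over all n! rank
// assignments to the n distinct k-mers.  Sums are exact integers (J uses the
// fixed denominator 2520 = lcm(1..10), which every possible U divides).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List exact_enum_cpp(IntegerVector idA, IntegerVector idB, int n, int w,
                    IntegerVector ppos, IntegerVector qpos) {
  int LA = idA.size(), LB = idB.size();
  if (n > 10) stop("exact enumeration is limited to 10 distinct k-mers");
  if (LA < w || LB < w) stop("sequence has fewer than w k-mers");
  std::vector<int> perm(n);
  std::iota(perm.begin(), perm.end(), 0);
  std::vector<int> aA(LA), aB(LB), dq(std::max(LA, LB));
  std::vector<uint8_t> selA(LA), selB(LB), inA(n), inB(n);
  const double D = 2520.0;
  double nperm = 0, sumI = 0, sumU = 0, sumJ = 0;
  int np = ppos.size();
  std::vector<double> joint(np, 0.0);
  do {
    for (int p = 0; p < LA; ++p) aA[p] = perm[idA[p]];
    for (int p = 0; p < LB; ++p) aB[p] = perm[idB[p]];
    std::fill(selA.begin(), selA.end(), 0);
    std::fill(selB.begin(), selB.end(), 0);
    select_minimizers(aA.data(), LA, w, selA.data(), dq.data());
    select_minimizers(aB.data(), LB, w, selB.data(), dq.data());
    std::fill(inA.begin(), inA.end(), 0);
    std::fill(inB.begin(), inB.end(), 0);
    for (int p = 0; p < LA; ++p)
      if (selA[p]) inA[idA[p]] = 1;
    for (int q = 0; q < LB; ++q)
      if (selB[q]) inB[idB[q]] = 1;
    int I = 0, U = 0;
    for (int t = 0; t < n; ++t) {
      if (inA[t] && inB[t]) ++I;
      if (inA[t] || inB[t]) ++U;
    }
    sumI += I;
    sumU += U;
    sumJ += (D / U) * I;  // exact: U <= n <= 10 divides 2520
    for (int r = 0; r < np; ++r)
      if (selA[ppos[r]] && selB[qpos[r]]) joint[r] += 1;
    nperm += 1;
  } while (std::next_permutation(perm.begin(), perm.end()));
  return List::create(_["n_perm"] = nperm, _["sum_I"] = sumI,
                      _["sum_U"] = sumU, _["sum_J_num"] = sumJ,
                      _["J_den_unit"] = D, _["joint"] = wrap(joint));
}

// ---------------------------------------------------------------------------
// Monte-Carlo hash replicates: one row (I, U, J) of the minimizer-sketch
// Jaccard per hash seed.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix mc_replicates_cpp(CharacterVector kmersA, CharacterVector kmersB,
                                int w, NumericVector seeds) {
  int LA = kmersA.size(), LB = kmersB.size(), ns = seeds.size();
  if (w < 1) stop("w must be >= 1");
  if (LA < w || LB < w) stop("sequence has fewer than w k-mers");
  std::vector<uint64_t> h0A(LA), h0B(LB);
  std::unordered_map<std::string, int> idmap;
  idmap.reserve((size_t)(LA + LB) * 2);
  std::vector<int> idA(LA), idB(LB);
  for (int p = 0; p < LA; ++p) {
    const char* s = CHAR(STRING_ELT(kmersA, p));
    size_t len = std::strlen(s);
    h0A[p] = fnv1a64(s, len);
    auto r = idmap.emplace(std::string(s, len), (int)idmap.size());
    idA[p] = r.first->second;
  }
  for (int p = 0; p < LB; ++p) {
    const char* s = CHAR(STRING_ELT(kmersB, p));
    size_t len = std::strlen(s);
    h0B[p] = fnv1a64(s, len);
    auto r = idmap.emplace(std::string(s, len), (int)idmap.size());
    idB[p] = r.first->second;
  }
  int nid = (int)idmap.size();
  std::vector<double> aA(LA), aB(LB);
  std::vector<uint8_t> selA(LA), selB(LB);
  std::vector<int> dq(std::max(LA, LB));
  std::vector<int> stampA(nid, -1), stampB(nid, -1);
  NumericMatrix out(ns, 3);
  for (int si = 0; si < ns; ++si) {
    uint64_t skey = seed_key((uint64_t)seeds[si]);
    for (int p = 0; p < LA; ++p) aA[p] = hash_value(h0A[p], skey);
    for (int p = 0; p < LB; ++p) aB[p] = hash_value(h0B[p], skey);
    std::fill(selA.begin(), selA.end(), 0);
    std::fill(selB.begin(), selB.end(), 0);
    select_minimizers(aA.data(), LA, w, selA.data(), dq.data());
    select_minimizers(aB.data(), LB, w, selB.data(), dq.data());
    int cA = 0, cB = 0, I = 0;
    for (int p = 0; p < LA; ++p) {
      int t = idA[p];
      if (selA[p] && stampA[t] != si) {
        stampA[t] = si;
        ++cA;
      }
    }
    for (int p = 0; p < LB; ++p) {
      int t = idB[p];
      if (selB[p] && stampB[t] != si) {
        stampB[t] = si;
        ++cB;
        if (stampA[t] == si) ++I;
      }
    }
    int U = cA + cB - I;
    out(si, 0) = I;
    out(si, 1) = U;
    out(si, 2) = (U > 0) ? (double)I / U : 0.0;
  }
  colnames(out) = CharacterVector::create("I_hat", "U_hat", "J_hat");
  return out;
}

// ---------------------------------------------------------------------------
// Duplicate-free sequence generators.
// ---------------------------------------------------------------------------

static const char* BASES = "ACGT";

static inline int base_index(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

// randomized extension with backtracking on the order-(k-1) de Bruijn graph
// [[Rcpp::export]]
std::string random_dupfree_cpp(int L, int k, double seed, double max_backtrack) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  if (L < 1) stop("L must be >= 1");
  uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  std::mt19937_64 rng((uint64_t)seed);
  struct Frame {
    uint64_t kmer;
    uint8_t ord[4];
    uint8_t next;
  };
  for (int attempt = 0; attempt < 32; ++attempt) {
    std::unordered_set<uint64_t> used;
    used.reserve((size_t)L * 2);
    std::vector<Frame> st;
    st.reserve((size_t)L + 1);
    auto new_frame = [&rng](uint64_t km) {
      Frame f;
      f.kmer = km;
      f.next = 0;
      for (int c = 0; c < 4; ++c) f.ord[c] = (uint8_t)c;
      for (int c = 3; c > 0; --c) std::swap(f.ord[c], f.ord[rng() % (c + 1)]);
      return f;
    };
    uint64_t k0 = rng() & mask;
    st.push_back(new_frame(k0));
    used.insert(k0);
    double bt = 0.0;
    bool fail = false;
    while ((int)st.size() < L) {
      bool extended = false;
      Frame& top = st.back();
      while (top.next < 4) {
        int c = top.ord[top.next++];
        uint64_t nk = ((top.kmer << 2) | (uint64_t)c) & mask;
        if (!used.count(nk)) {
          used.insert(nk);
          st.push_back(new_frame(nk));
          extended = true;
          break;
        }
      }
      if (!extended) {
        used.erase(st.back().kmer);
        st.pop_back();
        bt += 1.0;
        if (st.empty() || bt > max_backtrack) {
          fail = true;
          break;
        }
      }
    }
    if (!fail && (int)st.size() == L) {
      std::string s((size_t)L + k - 1, 'A');
      for (int j = 0; j < k; ++j)
        s[j] = BASES[(st[0].kmer >> (2 * (k - 1 - j))) & 3ULL];
      for (int t = 1; t < L; ++t) s[k - 1 + t] = BASES[st[t].kmer & 3ULL];
      return s;
    }
  }
  stop("random_duplicate_free: backtracking budget exhausted");
}

// random Eulerian circuit (Hierholzer) on the full de Bruijn graph; any
// contiguous window of the circuit is duplicate-free, so this handles
// densities near L -> 4^k that defeat plain backtracking.  Needs k <= 12.
// [[Rcpp::export]]
std::string euler_dupfree_cpp(int L, int k, double seed) {
  if (k < 2 || k > 12) stop("Eulerian construction requires 2 <= k <= 12");
  int64_t nn = 1LL << (2 * (k - 1));
  int64_t ne = nn * 4;
  if ((int64_t)L > ne) stop("L exceeds the number of distinct k-mers");
  std::mt19937_64 rng((uint64_t)seed);
  std::vector<std::array<uint8_t, 4> > perms;
  {
    std::array<uint8_t, 4> p0 = {{0, 1, 2, 3}};
    do {
      perms.push_back(p0);
    } while (std::next_permutation(p0.begin(), p0.end()));
  }
  std::vector<uint8_t> ord(nn), ptr(nn, 0);
  for (int64_t v = 0; v < nn; ++v) ord[v] = (uint8_t)(rng() % 24);
  uint64_t nmask = (uint64_t)nn - 1ULL;
  std::vector<int64_t> stk;
  stk.reserve((size_t)ne + 1);
  std::vector<int64_t> circ;
  circ.reserve((size_t)ne + 1);
  stk.push_back((int64_t)(rng() & nmask));
  while (!stk.empty()) {
    int64_t v = stk.back();
    if (ptr[v] < 4) {
      int c = perms[ord[v]][ptr[v]++];
      stk.push_back((int64_t)((((uint64_t)v << 2) | (uint64_t)c) & nmask));
    } else {
      circ.push_back(v);
      stk.pop_back();
    }
  }
  if ((int64_t)circ.size() != ne + 1)
    stop("internal error: incomplete Eulerian circuit");
  int64_t m = (int64_t)circ.size();
  std::string s((size_t)L + k - 1, 'A');
  int64_t v0 = circ[m - 1];
  for (int j = 0; j < k - 1; ++j)
    s[j] = BASES[(v0 >> (2 * (k - 2 - j))) & 3];
  for (int t = 1; t <= L; ++t) s[k - 2 + t] = BASES[circ[m - 1 - t] & 3];
  return s;
}

// per-position substitution at rate r1, rejecting any substitution that would
// create a duplicate k-mer; infeasible positions are left unmutated (counted)
// [[Rcpp::export]]
List related_mutate_cpp(std::string a, int k, double r1, double seed) {
  int N = (int)a.size();
  int nk = N - k + 1;
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  if (nk < 1) stop("sequence shorter than k");
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::string b = a;
  auto enc = [&b, k](int st) {
    uint64_t v = 0;
    for (int j = 0; j < k; ++j) {
      int ci = base_index(b[st + j]);
      if (ci < 0) stop("non-ACGT character in sequence");
      v = (v << 2) | (uint64_t)ci;
    }
    return v;
  };
  std::unordered_set<uint64_t> kset;
  kset.reserve((size_t)nk * 2);
  for (int st = 0; st < nk; ++st) kset.insert(enc(st));
  if ((int)kset.size() != nk) stop("input sequence is not duplicate-free");
  int mutated = 0, skipped = 0;
  std::vector<uint64_t> oldk, newk;
  for (int t = 0; t < N; ++t) {
    if (unif(rng) >= r1) continue;
    int s0 = std::max(0, t - k + 1), s1 = std::min(t, N - k);
    oldk.clear();
    for (int st = s0; st <= s1; ++st) {
      uint64_t v = enc(st);
      oldk.push_back(v);
      kset.erase(v);
    }
    char orig = b[t];
    int cand[3];
    int ncand = 0;
    for (int c = 0; c < 4; ++c)
      if (BASES[c] != orig) cand[ncand++] = c;
    for (int c = ncand - 1; c > 0; --c)
      std::swap(cand[c], cand[rng() % (c + 1)]);
    bool done = false;
    for (int ci = 0; ci < ncand && !done; ++ci) {
      b[t] = BASES[cand[ci]];
      newk.clear();
      bool ok = true;
      for (int st = s0; st <= s1 && ok; ++st) {
        uint64_t v = enc(st);
        if (kset.count(v)) ok = false;
        for (size_t u = 0; u < newk.size() && ok; ++u)
          if (newk[u] == v) ok = false;
        if (ok) newk.push_back(v);
      }
      if (ok) {
        for (size_t u = 0; u < newk.size(); ++u) kset.insert(newk[u]);
        ++mutated;
        done = true;
      }
    }
    if (!done) {
      b[t] = orig;
      for (size_t u = 0; u < oldk.size(); ++u) kset.insert(oldk[u]);
      ++skipped;
    }
  }
  return List::create(_["sequence"] = b, _["n_mutated"] = mutated,
                      _["n_skipped"] = skipped);
}
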