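#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Exact matched/unmatched haplotype-hypothesis likelihoods for one
// subsample of reads.
//
// Inputs are per-read haplotype compatibility masks over the panel rows
// (TRUE where a haplotype carries every allele the read observed), with
// rows grouped by population. The disomy part marginalises over all 2^n
// assignments of the n test-sample reads to the two homologs; the
// monosomy reads are pinned to homolog 1. Joint frequencies are exact
// bit-counts per population, mixed by the ancestry weights of each
// homolog distribution; no smoothing is applied inside the sums, so
// allele combinations absent from the panel contribute nothing. The
// caller regularises only at the hypothesis level, by bounding the
// log-likelihood ratio at +/- log(1/floorVal).

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

struct Layout {
  int P;                  // populations
  std::vector<int> np;    // rows per population
  std::vector<int> off;   // word offset per population
  std::vector<int> nw;    // words per population
  int W;                  // total words
};

static Layout makeLayout(const IntegerVector& popSizes) {
  Layout L;
  L.P = popSizes.size();
  L.np.assign(popSizes.begin(), popSizes.end());
  L.off.resize(L.P); L.nw.resize(L.P);
  int w = 0;
  for (int p = 0; p < L.P; ++p) {
    L.off[p] = w;
    L.nw[p] = (L.np[p] + 63) / 64;
    w += L.nw[p];
  }
  L.W = w;
  return L;
}

// pack one logical column (rows grouped by population) into padded words
static void packColumn(const int* col, const Layout& L, uint64_t* out) {
  int row = 0;
  for (int p = 0; p < L.P; ++p) {
    for (int w = 0; w < L.nw[p]; ++w) out[L.off[p] + w] = 0ULL;
    for (int r = 0; r < L.np[p]; ++r, ++row) {
      if (col[row]) out[L.off[p] + (r >> 6)] |= (1ULL << (r & 63));
    }
  }
}

static void packOnes(const Layout& L, uint64_t* out) {
  for (int p = 0; p < L.P; ++p) {
    for (int w = 0; w < L.nw[p]; ++w) {
      int lo = w * 64;
      int hi = std::min(L.np[p], lo + 64);
      uint64_t word = 0ULL;
      for (int r = lo; r < hi; ++r) word |= (1ULL << (r & 63));
      out[L.off[p] + w] = word;
    }
  }
}

// mixed frequency of the haplotype set whose compatibility words are given
static inline double mixedFreq(const uint64_t* words, const Layout& L,
                               const double* alpha) {
  double f = 0.0;
  for (int p = 0; p < L.P; ++p) {
    if (alpha[p] == 0.0) continue;
    long cnt = 0;
    for (int w = 0; w < L.nw[p]; ++w) cnt += popcount64(words[L.off[p] + w]);
    f += alpha[p] * (double)cnt / (double)L.np[p];
  }
  return f;
}

// likelihoods for one subsample given packed per-read words
static void pairCore(const std::vector<uint64_t>& Acols,
                     const std::vector<uint64_t>& Bcols,
                     const std::vector<int>& selA,
                     const std::vector<int>& selB,
                     const Layout& L,
                     const double* alpha1, const double* alpha2,
                     std::vector<uint64_t>& sub, std::vector<double>& f1,
                     std::vector<double>& f2, std::vector<double>& g1,
                     double& matched, double& unmatched, double& fAout,
                     double& disomyOut) {
  const int m = (int)selA.size();
  const int n = (int)selB.size();
  (void)m;
  std::vector<uint64_t> Awords(L.W);
  packOnes(L, Awords.data());
  for (int j : selA) {
    const uint64_t* col = &Acols[(size_t)j * L.W];
    for (int w = 0; w < L.W; ++w) Awords[w] &= col[w];
  }
  const size_t nsub = (size_t)1 << n;
  if (sub.size() < nsub * L.W) sub.resize(nsub * L.W);
  if (f1.size() < nsub) { f1.resize(nsub); f2.resize(nsub); g1.resize(nsub); }
  bool sameAlpha = true;
  for (int p = 0; p < L.P; ++p) {
    if (alpha1[p] != alpha2[p]) { sameAlpha = false; break; }
  }
  packOnes(L, sub.data());
  std::vector<uint64_t> gw(L.W);
  for (size_t S = 0; S < nsub; ++S) {
    uint64_t* w = &sub[S * L.W];
    if (S) {
      size_t low = S & (~S + 1);
      int r = 0;
      while (((size_t)1 << r) != low) ++r;
      const uint64_t* prev = &sub[(S ^ low) * L.W];
      const uint64_t* rd = &Bcols[(size_t)selB[r] * L.W];
      for (int k = 0; k < L.W; ++k) w[k] = prev[k] & rd[k];
    }
    for (int k = 0; k < L.W; ++k) gw[k] = w[k] & Awords[k];
    f1[S] = mixedFreq(w, L, alpha1);
    f2[S] = sameAlpha ? f1[S] : mixedFreq(w, L, alpha2);
    g1[S] = mixedFreq(gw.data(), L, alpha1);
  }
  const size_t full = nsub - 1;
  double mm = 0.0, dd = 0.0;
  for (size_t S = 0; S < nsub; ++S) {
    const size_t C = full ^ S;
    mm += g1[S] * f2[C];
    dd += f1[S] * f2[C];
  }
  const double scale = std::ldexp(1.0, -n); // (1/2)^n
  const double fA = mixedFreq(Awords.data(), L, alpha1);
  matched = mm * scale;
  unmatched = fA * dd * scale;
  fAout = fA;
  disomyOut = dd * scale;
}

static std::vector<uint64_t> packMatrix(const LogicalMatrix& M,
                                        const Layout& L) {
  std::vector<uint64_t> out((size_t)std::max(M.ncol(), 1) * L.W);
  for (int j = 0; j < M.ncol(); ++j)
    packColumn(&M(0, j), L, &out[(size_t)j * L.W]);
  return out;
}

// log-likelihood ratio bounded at +/- log(1/floorVal): panels of N
// haplotypes cannot resolve probability ratios beyond ~2N
static inline double boundedLlr(double matched, double unmatched,
                                double floorVal) {
  const double cap = -std::log(floorVal);
  if (matched == 0.0) return cap;
  if (unmatched == 0.0) return -cap;
  double g = std::log(unmatched) - std::log(matched);
  if (g > cap) g = cap;
  if (g < -cap) g = -cap;
  return g;
}

// m-out-of-n bootstrap of the window LLR, entirely in compiled code.
// Subsamples use R's RNG (deterministic under set.seed); subsamples for
// which both hypotheses are zero are redrawn up to maxAttempts.
// [[Rcpp::export(name = ".cpp_bootstrap_window")]]
List cpp_bootstrap_window(LogicalMatrix A, LogicalMatrix B,
                          IntegerVector popSizes,
                          NumericVector alpha1, NumericVector alpha2,
                          double floorVal,
                          int m, int capA, int capB, int maxAttempts) {
  Layout L = makeLayout(popSizes);
  const int nA = A.ncol(), nB = B.ncol();
  if (std::min(capB, nB) > 16) stop("too many test-sample reads");
  std::vector<uint64_t> Acols = packMatrix(A, L);
  std::vector<uint64_t> Bcols = packMatrix(B, L);
  std::vector<uint64_t> sub;
  std::vector<double> f1, f2, g1;
  NumericVector gam(m);
  int got = 0, attempts = 0;
  std::vector<int> selA, selB;
  while (got < m && attempts < maxAttempts) {
    ++attempts;
    if (nA > capA) {
      IntegerVector s = Rcpp::sample(nA, capA, false);
      selA.assign(s.begin(), s.end());
      for (int& v : selA) --v;
    } else {
      selA.resize(nA);
      for (int i = 0; i < nA; ++i) selA[i] = i;
    }
    if (nB > capB) {
      IntegerVector s = Rcpp::sample(nB, capB, false);
      selB.assign(s.begin(), s.end());
      for (int& v : selB) --v;
    } else {
      selB.resize(nB);
      for (int i = 0; i < nB; ++i) selB[i] = i;
    }
    double matched, unmatched, fA, disomy;
    pairCore(Acols, Bcols, selA, selB, L, alpha1.begin(), alpha2.begin(),
             sub, f1, f2, g1, matched, unmatched, fA, disomy);
    if (matched == 0.0 && unmatched == 0.0) continue;
    gam[got++] = boundedLlr(matched, unmatched, floorVal);
  }
  if (got < m) return List::create(_["flagged"] = true);
  return List::create(_["flagged"] = false, _["gamma"] = gam,
                      _["attempts"] = attempts);
}

// [[Rcpp::export(name = ".cpp_pair_likelihoods")]]
List cpp_pair_likelihoods(LogicalMatrix A, LogicalMatrix B,
                          IntegerVector popSizes,
                          NumericVector alpha1, NumericVector alpha2) {
  const int n = B.ncol();
  if (n > 16) stop("too many test-sample reads for exact enumeration");
  Layout L = makeLayout(popSizes);
  int H = 0;
  for (int p = 0; p < L.P; ++p) H += L.np[p];
  if (A.nrow() != H || (n > 0 && B.nrow() != H))
    stop("mask rows must match sum of population sizes");
  std::vector<uint64_t> Acols = packMatrix(A, L);
  std::vector<uint64_t> Bcols = packMatrix(B, L);
  std::vector<int> selA(A.ncol()), selB(n);
  for (int i = 0; i < A.ncol(); ++i) selA[i] = i;
  for (int i = 0; i < n; ++i) selB[i] = i;
  std::vector<uint64_t> sub;
  std::vector<double> f1, f2, g1;
  double matched, unmatched, fA, disomy;
  pairCore(Acols, Bcols, selA, selB, L, alpha1.begin(), alpha2.begin(),
           sub, f1, f2, g1, matched, unmatched, fA, disomy);
  return List::create(_["matched"] = matched, _["unmatched"] = unmatched,
                      _["fA"] = fA, _["disomy"] = disomy);
}
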