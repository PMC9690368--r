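#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Workspace for refining haplotype group ids. Group ids live in 1..n and
// one site's symbol in 0..n+2 (alleles 0/1; missing gets 2 + haplotype
// index so it matches nothing), so the combined key fits in a small
// direct-lookup table; a version stamp avoids clearing it between calls.
struct Refiner {
  int n;
  std::vector<int> lut, stamp;
  int version;
  Refiner(int n_) : n(n_), lut((size_t)(n_ + 1) * (n_ + 3), 0),
                    stamp((size_t)(n_ + 1) * (n_ + 3), -1), version(0) {}
  // gid: current group ids (1..k); alleles: full column; rows: indices
  void refine(std::vector<int> &gid, const int *alleles,
              const std::vector<int> &rows) {
    ++version;
    int next = 0;
    for (size_t i = 0; i < rows.size(); ++i) {
      int a = alleles[rows[i]];
      int sym = (a < 0) ? (int)(2 + i) : a;
      int key = gid[i] * (n + 3) + sym;
      if (stamp[key] != version) { stamp[key] = version; lut[key] = ++next; }
      gid[i] = lut[key];
    }
  }
};

static double ehhOf(const std::vector<int> &gid, std::vector<int> &cnt) {
  int n = gid.size();
  std::fill(cnt.begin(), cnt.end(), 0);
  for (int i = 0; i < n; ++i) cnt[gid[i]]++;
  double pairs = 0.0;
  for (int g = 1; g <= n; ++g) pairs += 0.5 * cnt[g] * (cnt[g] - 1);
  return pairs / (0.5 * (double)n * (n - 1));
}

// Per-chromosome XP-EHH core: for every site, integrate EHH (trapezoids
// over bp) for test and control haplotypes over a shared extent fixed by
// the pooled EHH falling below `cutoff` (crossing linearly interpolated)
// or by a gap > `maxGap` between consecutive sites. Identity includes the
// core site; the curve value at offset 0 is 1 for all groups.
//
// H: haplotypes x variants, alleles 0/1, negative = missing.
// testRows/ctrlRows: 0-based row indices into H.
// Returns a variants x 2 matrix (iHH_test, iHH_control).
// [[Rcpp::export]]
NumericMatrix xpehh_chrom_cpp(IntegerMatrix H, NumericVector pos,
                              IntegerVector testRows, IntegerVector ctrlRows,
                              double maxGap, double cutoff) {
  int m = H.ncol();
  int nT = testRows.size(), nC = ctrlRows.size();
  if (nT < 2 || nC < 2)
    stop("each group needs at least 2 haplotypes");
  std::vector<int> tR(testRows.begin(), testRows.end());
  std::vector<int> cR(ctrlRows.begin(), ctrlRows.end());
  std::vector<int> pR(tR);
  pR.insert(pR.end(), cR.begin(), cR.end());
  int nP = pR.size();

  std::vector<int> A(H.begin(), H.end());  // column-major
  int nrow = H.nrow();

  Refiner rfP(nP), rfT(nT), rfC(nC);
  std::vector<int> gP, gT, gC;
  std::vector<int> cntP(nP + 1), cntT(nT + 1), cntC(nC + 1);

  NumericMatrix out(m, 2);
  for (int c = 0; c < m; ++c) {
    double areaT = 0.0, areaC = 0.0;
    for (int dir = -1; dir <= 1; dir += 2) {
      gP.assign(nP, 1);
      gT.assign(nT, 1);
      gC.assign(nC, 1);
      const int *core = &A[(size_t)c * nrow];
      rfP.refine(gP, core, pR);
      rfT.refine(gT, core, tR);
      rfC.refine(gC, core, cR);
      double dPrev = 0.0, ePprev = 1.0, eTprev = 1.0, eCprev = 1.0;
      int j = c;
      while (true) {
        int nxt = j + dir;
        if (nxt < 0 || nxt >= m) break;
        if (std::abs(pos[nxt] - pos[j]) > maxGap) break;
        const int *col = &A[(size_t)nxt * nrow];
        rfP.refine(gP, col, pR);
        rfT.refine(gT, col, tR);
        rfC.refine(gC, col, cR);
        double eP = ehhOf(gP, cntP), eT = ehhOf(gT, cntT), eC = ehhOf(gC, cntC);
        double d = std::abs(pos[nxt] - pos[c]);
        if (eP < cutoff) {
          double frac = (ePprev - cutoff) / (ePprev - eP);
          double xs = dPrev + frac * (d - dPrev);
          double eTs = eTprev + frac * (eT - eTprev);
          double eCs = eCprev + frac * (eC - eCprev);
          areaT += (xs - dPrev) * (eTprev + eTs) / 2.0;
          areaC += (xs - dPrev) * (eCprev + eCs) / 2.0;
          break;
        }
        areaT += (d - dPrev) * (eTprev + eT) / 2.0;
        areaC += (d - dPrev) * (eCprev + eC) / 2.0;
        dPrev = d; ePprev = eP; eTprev = eT; eCprev = eC;
        j = nxt;
      }
    }
    out(c, 0) = areaT;
    out(c, 1) = areaC;
  }
  return out;
}
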