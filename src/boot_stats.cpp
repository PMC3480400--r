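#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Per-replicate diversity statistics over subsamples of individuals.
//
// a1, a2: n x L integer matrices of globally-coded allele labels
//         (codes 1..nCodes, 0 = missing; a pair is missing as a whole so
//         a1 == 0 implies a2 == 0 at that slot).
// idx:    B x m matrix of 1-based row indices, one subsample per row.
// locOfCode: locus index (1-based) for every global code; only used for its
//         length here because codes are already locus-partitioned in a1/a2.
// occLC:  per code, whether the allele satisfies the locally-common occupancy
//         criterion computed over all units (allele restricted to few units).
// occPriv: per code, whether the allele occurs in exactly one unit globally.
// freqMin / strictFreq: within-subsample frequency criterion for locally
//         common alleles (>= freqMin when strictFreq is false, > when true).
//
// Returns a B x 6 matrix: per-replicate means over non-empty loci of
// allelic richness, Shannon index, Nei gene diversity, observed
// heterozygosity, locally common alleles and private alleles.
// [[Rcpp::export]]
NumericMatrix boot_stats_kernel(IntegerMatrix a1, IntegerMatrix a2,
                                IntegerMatrix idx,
                                IntegerVector locOfCode,
                                LogicalVector occLC,
                                LogicalVector occPriv,
                                double freqMin, bool strictFreq) {
  const int B = idx.nrow(), m = idx.ncol();
  const int L = a1.ncol();
  const int nCodes = locOfCode.size();
  NumericMatrix out(B, 6);
  std::vector<int> cnt(nCodes + 1, 0);
  std::vector<int> touched;
  touched.reserve(2 * m);

  for (int b = 0; b < B; ++b) {
    double sRich = 0, sSh = 0, sNei = 0, sLC = 0, sPriv = 0, sHet = 0;
    int nLocG = 0, nLocH = 0;
    for (int l = 0; l < L; ++l) {
      touched.clear();
      int nCopies = 0, nInd = 0, nHet = 0;
      for (int j = 0; j < m; ++j) {
        const int i = idx(b, j) - 1;
        const int c1 = a1(i, l);
        if (c1 == 0) continue;
        const int c2 = a2(i, l);
        ++nInd;
        if (c1 != c2) ++nHet;
        if (cnt[c1] == 0) touched.push_back(c1);
        ++cnt[c1];
        if (cnt[c2] == 0) touched.push_back(c2);
        ++cnt[c2];
        nCopies += 2;
      }
      if (nInd > 0) {
        sHet += static_cast<double>(nHet) / nInd;
        ++nLocH;
      }
      if (nCopies > 0) {
        const int k = static_cast<int>(touched.size());
        double sumP2 = 0, sh = 0;
        int lc = 0, pv = 0;
        for (int t = 0; t < k; ++t) {
          const int c = touched[t];
          const double p = static_cast<double>(cnt[c]) / nCopies;
          sumP2 += p * p;
          sh -= p * std::log(p);
          if (occLC[c - 1] && (strictFreq ? p > freqMin : p >= freqMin)) ++lc;
          if (occPriv[c - 1]) ++pv;
          cnt[c] = 0;
        }
        sRich += k;
        sSh += sh;
        sNei += 1.0 - sumP2;
        sLC += lc;
        sPriv += pv;
        ++nLocG;
      }
    }
    out(b, 0) = nLocG ? sRich / nLocG : NA_REAL;
    out(b, 1) = nLocG ? sSh / nLocG : NA_REAL;
    out(b, 2) = nLocG ? sNei / nLocG : NA_REAL;
    out(b, 3) = nLocH ? sHet / nLocH : NA_REAL;
    out(b, 4) = nLocG ? sLC / nLocG : NA_REAL;
    out(b, 5) = nLocG ? sPriv / nLocG : NA_REAL;
  }
  colnames(out) = CharacterVector::create(
      "allelic_richness", "shannon", "nei_diversity", "obs_heterozygosity",
      "locally_common", "private_alleles");
  return out;
}
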