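#include <Rcpp.h>
using namespace Rcpp;

// Weighted per-band second-moment accumulation over slice spectra.
// Ff, Fm: complex slice spectra of the two images, dim nx*ny*nz (unshifted).
// For each band: idx holds 0-based positions of the band's frequency
// support within one slice, w2 the squared window at those positions, and
// dcPos the position of the DC sample within idx (-1 if absent).
// Returns per band: weighted sums of |Ff|^2, |Fm|^2, Re(Ff conj(Fm)), and
// the window-weighted DC totals (real parts) for both images.
// [[Rcpp::export(name = ".bandMomentsCpp")]]
NumericMatrix bandMomentsCpp(ComplexVector Ff, ComplexVector Fm,
                             int sliceSize, int nz, List idxList,
                             List w2List, IntegerVector dcPos,
                             NumericVector wdc) {
  int nb = idxList.size();
  NumericMatrix out(nb, 5); // sumsqF, sumsqM, cross, dcF, dcM
  const Rcomplex *pf = Ff.begin(), *pm = Fm.begin();
  for (int b = 0; b < nb; ++b) {
    IntegerVector idx = idxList[b];
    NumericVector w2 = w2List[b];
    int m = idx.size();
    double sF = 0, sM = 0, cr = 0, dF = 0, dM = 0;
    for (int s = 0; s < nz; ++s) {
      size_t base = (size_t)s * sliceSize;
      for (int i = 0; i < m; ++i) {
        size_t o = base + idx[i];
        double w = w2[i];
        double fr = pf[o].r, fi = pf[o].i, mr = pm[o].r, mi = pm[o].i;
        sF += w * (fr * fr + fi * fi);
        sM += w * (mr * mr + mi * mi);
        cr += w * (fr * mr + fi * mi);
      }
      if (dcPos[b] >= 0) {
        size_t o = base + idx[dcPos[b]];
        dF += pf[o].r;
        dM += pm[o].r;
      }
    }
    out(b, 0) = sF; out(b, 1) = sM; out(b, 2) = cr;
    out(b, 3) = dF * wdc[b]; out(b, 4) = dM * wdc[b];
  }
  return out;
}
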