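// Pedigree gene-drop with Haldane recombination, and the adjacent-SNP r^2
// scan used for LD calibration.  R's RNG throughout.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

// transmit one recombinant haplotype from the parent's two haplotypes
void meiosis(const IntegerMatrix& hapA, const IntegerMatrix& hapB, int parent,
             const IntegerVector& chromFirst, const IntegerVector& chromLast,
             const NumericVector& chromLenBp, const NumericVector& pos,
             double cmPerMb, IntegerMatrix& out, int child) {
  const int nchr = chromFirst.size();
  std::vector<double> xo;
  for (int c = 0; c < nchr; ++c) {
    const double mapLenCM = chromLenBp[c] / 1e6 * cmPerMb;
    int ncross = (mapLenCM > 0.0) ? (int)R::rpois(mapLenCM / 100.0) : 0;
    xo.clear();
    for (int k = 0; k < ncross; ++k) xo.push_back(unif_rand() * chromLenBp[c]);
    std::sort(xo.begin(), xo.end());
    bool phaseA = unif_rand() < 0.5;
    size_t nextXo = 0;
    for (int j = chromFirst[c]; j <= chromLast[c]; ++j) {
      while (nextXo < xo.size() && xo[nextXo] < pos[j]) {
        phaseA = !phaseA;
        ++nextXo;
      }
      out(child, j) = phaseA ? hapA(parent, j) : hapB(parent, j);
    }
  }
}

}  // namespace

// sire/dam are 0-based row indices into the haplotype matrices (-1 for
// founders, whose rows must be pre-filled); rows must be ordered so that
// parents precede their offspring.
// [[Rcpp::export(name = ".gene_drop_cpp")]]
List gene_drop_cpp(IntegerMatrix paternal, IntegerMatrix maternal,
                   const IntegerVector& sire, const IntegerVector& dam,
                   const IntegerVector& chromFirst,
                   const IntegerVector& chromLast,
                   const NumericVector& chromLenBp, const NumericVector& pos,
                   double cmPerMb) {
  const int n = paternal.nrow();
  for (int i = 0; i < n; ++i) {
    if (sire[i] < 0) continue;
    meiosis(paternal, maternal, sire[i], chromFirst, chromLast, chromLenBp,
            pos, cmPerMb, paternal, i);
    meiosis(paternal, maternal, dam[i], chromFirst, chromLast, chromLenBp,
            pos, cmPerMb, maternal, i);
  }
  return List::create(_["paternal"] = paternal, _["maternal"] = maternal);
}

// r^2 (squared Pearson correlation of dosages) for each within-chromosome
// pair of SNPs that are adjacent after restricting to MAF > mafMin
// [[Rcpp::export(name = ".adjacent_ld_cpp")]]
NumericVector adjacent_ld_cpp(const NumericMatrix& G,
                              const IntegerVector& chrom, double mafMin) {
  const int n = G.nrow(), p = G.ncol();
  std::vector<double> mean(p), var(p);
  std::vector<bool> keep(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) { s += G(i, j); s2 += G(i, j) * G(i, j); }
    mean[j] = s / n;
    var[j] = s2 / n - mean[j] * mean[j];
    const double f = mean[j] / 2.0;
    const double maf = std::min(f, 1.0 - f);
    keep[j] = (maf > mafMin) && (var[j] > 0.0);
  }
  std::vector<double> out;
  int prev = -1;
  for (int j = 0; j < p; ++j) {
    if (!keep[j]) continue;
    if (prev >= 0 && chrom[prev] == chrom[j]) {
      double sxy = 0.0;
      for (int i = 0; i < n; ++i) sxy += G(i, prev) * G(i, j);
      const double cov = sxy / n - mean[prev] * mean[j];
      out.push_back(cov * cov / (var[prev] * var[j]));
    }
    prev = j;
  }
  return NumericVector(out.begin(), out.end());
}
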