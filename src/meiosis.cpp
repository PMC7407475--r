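#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Batch gamete simulation over a multi-chromosome genetic map.
//
// Crossover model: per chromosome the crossover count is Poisson with mean
// equal to the chromosome length in Morgans, crossover positions are uniform
// on the chromosome, and the starting parental haplotype is chosen with
// probability 1/2. Alleles are copied alternately between the two parental
// haplotypes at crossover boundaries (Haldane model: no interference, no
// obligate chiasma, no mutation). All randomness comes from R's RNG stream,
// so results are reproducible under set.seed().
//
// h1, h2:            n_ind x n_loci 0/1 haplotype matrices
// parent:            1-based row indices, one per requested gamete
// chr_first/chr_last: 1-based inclusive locus ranges, one per chromosome
//                    (loci must be stored in map order, chromosome blocks
//                    contiguous, positions non-decreasing within a block)
// pos_cM:            locus positions in centiMorgan
// [[Rcpp::export]]
IntegerMatrix gs_gametes_cpp(const IntegerMatrix& h1, const IntegerMatrix& h2,
                             const IntegerVector& parent,
                             const IntegerVector& chr_first,
                             const IntegerVector& chr_last,
                             const NumericVector& pos_cM) {
  const int n_gam = parent.size();
  const int n_loci = h1.ncol();
  const int n_chr = chr_first.size();
  IntegerMatrix out(n_gam, n_loci);
  std::vector<double> xo;

  for (int g = 0; g < n_gam; ++g) {
    const int p = parent[g] - 1;
    for (int c = 0; c < n_chr; ++c) {
      const int s = chr_first[c] - 1;
      const int e = chr_last[c] - 1;
      const double start = pos_cM[s];
      const double len_M = (pos_cM[e] - start) / 100.0;
      const int n_xo = (len_M > 0.0) ? (int)R::rpois(len_M) : 0;
      int cur = (unif_rand() < 0.5) ? 0 : 1; // starting parental haplotype

      if (n_xo == 0) {
        const IntegerMatrix& src = cur == 0 ? h1 : h2;
        for (int l = s; l <= e; ++l) out(g, l) = src(p, l);
        continue;
      }
      xo.clear();
      for (int i = 0; i < n_xo; ++i)
        xo.push_back(start + unif_rand() * len_M * 100.0);
      std::sort(xo.begin(), xo.end());

      int xi = 0;
      for (int l = s; l <= e; ++l) {
        while (xi < n_xo && xo[xi] <= pos_cM[l]) {
          cur ^= 1;
          ++xi;
        }
        out(g, l) = cur == 0 ? h1(p, l) : h2(p, l);
      }
    }
  }
  return out;
}
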