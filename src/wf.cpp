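#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Forward Wright-Fisher evolution of a diploid population.
//
// H: raw matrix (2N x m), 0/1 alleles; rows 2i, 2i+1 are the two haplotypes
//    of individual i. Sites are ordered by (chromosome, position).
// pos: site positions in bp (double, length m).
// chrom: 0-based chromosome index per site, non-decreasing.
// chrom_len: chromosome lengths in bp (for crossover placement).
// n_gen: generations to evolve.
// s: additive selection coefficient (fitnesses 1, 1+s, 1+2s at sweep_site).
// sweep_site: 0-based column of the selected site, or -1 for neutrality.
// recomb_rate: expected crossovers per bp per gamete per generation.
//
// Uses R's RNG throughout so results are reproducible under set.seed().
// Returns list(H = evolved matrix, traj = per-generation frequency of the
// allele at sweep_site measured after reproduction; empty if sweep_site < 0).

// [[Rcpp::export]]
List wf_evolve(RawMatrix H, NumericVector pos, IntegerVector chrom,
               NumericVector chrom_len, int n_gen, double s, int sweep_site,
               double recomb_rate) {
  const int two_n = H.nrow();
  const int m = H.ncol();
  const int n_ind = two_n / 2;
  const int n_chrom = chrom_len.size();

  // site ranges per chromosome
  std::vector<int> c_lo(n_chrom, m), c_hi(n_chrom, 0);
  for (int j = 0; j < m; ++j) {
    int c = chrom[j];
    if (j < c_lo[c]) c_lo[c] = j;
    if (j + 1 > c_hi[c]) c_hi[c] = j + 1;
  }
  for (int c = 0; c < n_chrom; ++c) if (c_lo[c] > c_hi[c]) { c_lo[c] = 0; c_hi[c] = 0; }

  // column-major RawMatrix is awkward for row copies; work row-major in buffers
  std::vector<uint8_t> cur((size_t)two_n * m), nxt((size_t)two_n * m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < two_n; ++i)
      cur[(size_t)i * m + j] = H(i, j);

  std::vector<double> fit(n_ind), cumw(n_ind);
  std::vector<double> bp;
  NumericVector traj(sweep_site >= 0 ? n_gen : 0);

  RNGScope scope;

  for (int g = 0; g < n_gen; ++g) {
    // fitness per individual
    double tot = 0.0;
    for (int i = 0; i < n_ind; ++i) {
      double w = 1.0;
      if (sweep_site >= 0 && s != 0.0) {
        int dos = cur[(size_t)(2 * i) * m + sweep_site] +
                  cur[(size_t)(2 * i + 1) * m + sweep_site];
        w = 1.0 + s * dos;
      }
      fit[i] = w;
      tot += w;
      cumw[i] = tot;
    }

    for (int k = 0; k < two_n; ++k) {
      // choose parent individual proportional to fitness
      int par;
      if (sweep_site >= 0 && s != 0.0) {
        double u = unif_rand() * tot;
        par = (int)(std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
        if (par >= n_ind) par = n_ind - 1;
      } else {
        par = (int)(unif_rand() * n_ind);
        if (par >= n_ind) par = n_ind - 1;
      }
      uint8_t *dst = &nxt[(size_t)k * m];
      const uint8_t *h0 = &cur[(size_t)(2 * par) * m];
      const uint8_t *h1 = &cur[(size_t)(2 * par + 1) * m];
      // independent assortment across chromosomes; crossovers within
      for (int c = 0; c < n_chrom; ++c) {
        int lo = c_lo[c], hi = c_hi[c];
        if (hi <= lo) continue;
        int which = (unif_rand() < 0.5) ? 0 : 1;
        int nx = (int)R::rpois(recomb_rate * chrom_len[c]);
        if (nx == 0) {
          std::memcpy(dst + lo, which ? h1 + lo : h0 + lo, hi - lo);
        } else {
          bp.clear();
          for (int x = 0; x < nx; ++x) bp.push_back(unif_rand() * chrom_len[c]);
          std::sort(bp.begin(), bp.end());
          int j = lo;
          size_t b = 0;
          while (j < hi) {
            double lim = (b < bp.size()) ? bp[b] : R_PosInf;
            int j2 = j;
            while (j2 < hi && pos[j2] < lim) ++j2;
            const uint8_t *src = which ? h1 : h0;
            if (j2 > j) std::memcpy(dst + j, src + j, j2 - j);
            j = j2;
            which = 1 - which;
            ++b;
            if (b > bp.size()) break;
          }
        }
      }
    }
    cur.swap(nxt);
    if (sweep_site >= 0) {
      int cnt = 0;
      for (int i = 0; i < two_n; ++i) cnt += cur[(size_t)i * m + sweep_site];
      traj[g] = (double)cnt / two_n;
    }
  }

  RawMatrix out(two_n, m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < two_n; ++i)
      out(i, j) = cur[(size_t)i * m + j];
  return List::create(Named("H") = out, Named("traj") = traj);
}
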