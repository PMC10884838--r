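#include <Rcpp.h>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// Hamming distance with early exit once it exceeds m.
static inline int hamming_gt(const char *a, const char *b, int k, int m) {
  int d = 0;
  for (int i = 0; i < k; ++i) {
    if (a[i] != b[i] && ++d > m) return 1;
  }
  return 0;
}

// Exact per-position k-mer match counts under a Hamming budget.
//
// For every position p with a full k-mer, counts the number of genome
// positions (p itself included) whose k-mer is within Hamming distance m.
// Pigeonhole seeding: a pair within distance m must agree exactly on at
// least one of m+1 k-mer chunks, so only chunk-sharing pairs are verified.
// Cost is ~O(total positions) plus verification of pairs arising in
// repeats (tandem arrays, homolog pairs, telomeric tracts).
//
// [[Rcpp::export]]
List mappability_counts_cpp(CharacterVector seqs, int k, int m,
                            double max_pairs = 5e7) {
  const int nch = seqs.size();
  std::vector<std::string> S(nch);
  std::vector<long long> off(nch + 1, 0);
  for (int c = 0; c < nch; ++c) {
    S[c] = as<std::string>(seqs[c]);
    long long np = (long long)S[c].size() - k + 1;
    off[c + 1] = off[c] + (np > 0 ? np : 0);
  }
  const long long N = off[nch];
  std::vector<int> cnt((size_t)N, 1);

  const int nchunk = m + 1;
  std::vector<int> clen(nchunk), coff(nchunk);
  {
    int base = k / nchunk, extra = k % nchunk, p0 = 0;
    for (int j = 0; j < nchunk; ++j) {
      clen[j] = base + (j < extra ? 1 : 0);
      coff[j] = p0;
      p0 += clen[j];
    }
  }

  // decode a global position id into (chrom, pos)
  auto chrom_of = [&](long long id, long long &pos) {
    int c = 0;
    while (off[c + 1] <= id) ++c;
    pos = id - off[c];
    return c;
  };

  std::unordered_set<unsigned long long> seen;
  double npairs = 0;

  for (int j = 0; j < nchunk; ++j) {
    std::unordered_map<std::string, std::vector<long long> > H;
    H.reserve((size_t)N + 16);
    for (int c = 0; c < nch; ++c) {
      long long L = (long long)S[c].size() - k + 1;
      for (long long p = 0; p < L; ++p)
        H[S[c].substr((size_t)(p + coff[j]), (size_t)clen[j])]
            .push_back(off[c] + p);
    }
    for (std::unordered_map<std::string, std::vector<long long> >::iterator
             it = H.begin();
         it != H.end(); ++it) {
      std::vector<long long> &v = it->second;
      const size_t g = v.size();
      if (g < 2) continue;
      npairs += (double)g * (double)(g - 1) / 2.0;
      if (npairs > max_pairs)
        stop("genome too repetitive for mappability computation "
             "(candidate pair budget exceeded)");
      for (size_t a = 0; a + 1 < g; ++a) {
        for (size_t b = a + 1; b < g; ++b) {
          long long i1 = v[a], i2 = v[b];
          if (nchunk > 1) {
            unsigned long long key =
                (unsigned long long)i1 * (unsigned long long)N +
                (unsigned long long)i2;
            if (!seen.insert(key).second) continue;
          }
          long long p1, p2;
          int c1 = chrom_of(i1, p1), c2 = chrom_of(i2, p2);
          if (!hamming_gt(S[c1].data() + p1, S[c2].data() + p2, k, m)) {
            ++cnt[(size_t)i1];
            ++cnt[(size_t)i2];
          }
        }
      }
    }
  }

  List out(nch);
  for (int c = 0; c < nch; ++c) {
    long long np = off[c + 1] - off[c];
    IntegerVector x((R_xlen_t)(np > 0 ? np : 0));
    for (long long p = 0; p < np; ++p) x[(R_xlen_t)p] = cnt[(size_t)(off[c] + p)];
    out[c] = x;
  }
  out.names() = seqs.names();
  return out;
}
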