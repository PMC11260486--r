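// Bottom-s MinHash sketching of canonical k-mers.
//
// k-mers (k <= 31) are 2-bit encoded on the fly together with their
// reverse complement; the canonical form is the numerically smaller of
// the two, which coincides with lexicographic order under A<C<G<T.
// Hashes are a splitmix64 mix of the canonical code with the sketch
// seed, masked to 53 bits so every value is exactly representable as an
// R double. k-mers containing any non-ACGT base are skipped.

#include <Rcpp.h>
#include <set>
#include <string>
using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

} // namespace

// [[Rcpp::export]]
NumericVector minhash_sketch_cpp(CharacterVector seqs, int k, int s,
                                 double hash_seed) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  const uint64_t mask2k = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const uint64_t mask53 = (1ULL << 53) - 1;
  const uint64_t seed_mix = splitmix64((uint64_t)hash_seed);
  const int shift_rc = 2 * (k - 1);

  std::set<uint64_t> keep;
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    const std::string seq = as<std::string>(seqs[si]);
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (size_t p = 0; p < seq.size(); ++p) {
      const int c = base_code(seq[p]);
      if (c < 0) { valid = 0; fwd = rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask2k;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift_rc);
      if (++valid < k) continue;
      const uint64_t canon = fwd < rev ? fwd : rev;
      const uint64_t h = splitmix64(canon ^ seed_mix) & mask53;
      if ((int)keep.size() < s) {
        keep.insert(h);
      } else if (h < *keep.rbegin()) {
        if (keep.insert(h).second) keep.erase(std::prev(keep.end()));
      }
    }
  }
  NumericVector out(keep.size());
  R_xlen_t i = 0;
  for (uint64_t h : keep) out[i++] = (double)h;
  return out; // ascending: std::set iterates in order
}
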