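#include <Rcpp.h>
#include <cstdint>

// FNV-1a 64-bit over the bytes of each string, reduced modulo L.
// Used for path-fingerprint bit assignment: deterministic and
// platform-independent (fixed offset basis / prime per the FNV spec).
// [[Rcpp::export]]
Rcpp::IntegerVector fnv1a64_mod(Rcpp::CharacterVector x, int L) {
  const uint64_t basis = 14695981039346656037ULL;
  const uint64_t prime = 1099511628211ULL;
  Rcpp::IntegerVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const char *s = CHAR(STRING_ELT(x, i));
    uint64_t h = basis;
    for (const char *p = s; *p; ++p) {
      h ^= (uint64_t)(unsigned char)(*p);
      h *= prime;
    }
    out[i] = (int)(h % (uint64_t)L);
  }
  return out;
}
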