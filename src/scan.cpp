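#include <Rcpp.h>
#include <cstring>
#include <cstdint>
using namespace Rcpp;

// IUPAC degenerate matching over A/C/G/T/N subjects via bit-parallel
// Shift-And. Each base is a 4-bit mask (A=1, C=2, G=4, T=8); a motif letter
// matches a subject letter iff their masks intersect. Subject letters are
// restricted to A,C,G,T,N and N carries mask 0, so an unknown base matches
// no motif letter (including motif N) -- unknown sequence never creates
// hits. Every (possibly overlapping) offset is counted. Motifs are limited
// to 64 letters (one machine word), far beyond any curated cis-element.

static inline void build_mask(unsigned char mask[256]) {
  std::memset(mask, 0, 256);
  mask[(unsigned char)'A'] = 1;  mask[(unsigned char)'C'] = 2;
  mask[(unsigned char)'G'] = 4;  mask[(unsigned char)'T'] = 8;
  mask[(unsigned char)'R'] = 1 | 4;  mask[(unsigned char)'Y'] = 2 | 8;
  mask[(unsigned char)'S'] = 2 | 4;  mask[(unsigned char)'W'] = 1 | 8;
  mask[(unsigned char)'K'] = 4 | 8;  mask[(unsigned char)'M'] = 1 | 2;
  mask[(unsigned char)'B'] = 2 | 4 | 8;  mask[(unsigned char)'D'] = 1 | 4 | 8;
  mask[(unsigned char)'H'] = 1 | 2 | 8;  mask[(unsigned char)'V'] = 1 | 2 | 4;
  mask[(unsigned char)'N'] = 1 | 2 | 4 | 8;
}

// [[Rcpp::export(name = ".scan_count_cpp")]]
IntegerMatrix scan_count_cpp(CharacterVector sequences,
                             CharacterVector motifs) {
  unsigned char mask[256];
  build_mask(mask);
  const int ng = sequences.size(), nm = motifs.size();
  IntegerMatrix out(ng, nm);

  // per-motif Shift-And tables: occ[m][smask] has bit j set iff motif
  // letter j accepts a subject base with mask smask (smask in {0,1,2,4,8})
  std::vector<std::array<uint64_t, 16> > occ(nm);
  std::vector<uint64_t> accept(nm);   // bit (len-1) flags a complete match
  for (int m = 0; m < nm; ++m) {
    const char* p = CHAR(STRING_ELT(motifs, m));
    size_t plen = std::strlen(p);
    if (plen == 0 || plen > 64) {
      stop("motif length must be in 1..64: %s", p);
    }
    occ[m].fill(0);
    for (size_t j = 0; j < plen; ++j) {
      unsigned char b = mask[(unsigned char)p[j]];
      if (!b) stop("invalid IUPAC character in motif: %s", p);
      for (int s = 0; s < 16; ++s) {
        if (b & s) occ[m][s] |= (uint64_t)1 << j;
      }
    }
    accept[m] = (uint64_t)1 << (plen - 1);
  }

  std::vector<unsigned char> sm;
  for (int g = 0; g < ng; ++g) {
    const char* s = CHAR(STRING_ELT(sequences, g));
    size_t slen = std::strlen(s);
    sm.resize(slen);
    for (size_t i = 0; i < slen; ++i) {
      unsigned char c = (unsigned char)s[i];
      // anything outside A,C,G,T gets mask 0 (treated as unknown)
      sm[i] = (c == 'A') ? 1 : (c == 'C') ? 2
            : (c == 'G') ? 4 : (c == 'T') ? 8 : 0;
    }
    for (int m = 0; m < nm; ++m) {
      const uint64_t* tab = occ[m].data();
      const uint64_t acc = accept[m];
      uint64_t d = 0;
      int count = 0;
      for (size_t i = 0; i < slen; ++i) {
        d = ((d << 1) | 1) & tab[sm[i]];
        count += (d & acc) != 0;
      }
      out(g, m) = count;
    }
  }
  return out;
}
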