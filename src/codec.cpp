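#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// 2-bit code: A=00 C=01 G=10 T=11; 3-bit code adds N=100.
// Bases are packed left-to-right, first base in the most significant bits,
// final byte zero-padded on the right.

static inline int base2_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static inline int base3_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  case 'N': return 4;
  default:  return -1;
  }
}

static const char DECODE2[4] = {'A', 'C', 'G', 'T'};
static const char DECODE3[5] = {'A', 'C', 'G', 'T', 'N'};

// [[Rcpp::export(name = ".pack_cpp")]]
List pack_cpp(std::string seq, bool force_two_bit = false) {
  R_xlen_t n = seq.size();
  if (n == 0) stop("cannot pack an empty sequence");
  bool has_n = false;
  for (R_xlen_t i = 0; i < n; ++i) {
    char c = seq[i];
    if (c == 'N') {
      has_n = true;
    } else if (base2_code(c) < 0) {
      stop("invalid base '%s' at position %d (alphabet is A,C,G,T,N)",
           std::string(1, c).c_str(), (int)(i + 1));
    }
  }
  int encoding;
  int bits;
  if (force_two_bit || !has_n) {
    encoding = 0;
    bits = 2;
  } else {
    encoding = 1;
    bits = 3;
  }
  R_xlen_t nbytes = (n * bits + 7) / 8;
  RawVector payload(nbytes);
  R_xlen_t bitpos = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    char c = seq[i];
    int code = (encoding == 0)
      ? base2_code(c == 'N' ? 'A' : c)   // forced mode: N evaluated as A
      : base3_code(c);
    for (int b = bits - 1; b >= 0; --b, ++bitpos) {
      if ((code >> b) & 1)
        payload[bitpos / 8] |= (0x80 >> (bitpos % 8));
    }
  }
  return List::create(_["encoding"] = encoding,
                      _["byte_size"] = (int)nbytes,
                      _["base_length"] = (int)n,
                      _["payload"] = payload);
}

// [[Rcpp::export(name = ".pack_many_cpp")]]
List pack_many_cpp(CharacterVector seqs, bool force_two_bit = false) {
  R_xlen_t n = seqs.size();
  List out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = pack_cpp(as<std::string>(seqs[i]), force_two_bit);
  return out;
}

// [[Rcpp::export(name = ".unpack_cpp")]]
std::string unpack_cpp(int encoding, RawVector payload, int base_length) {
  int bits = (encoding == 0) ? 2 : 3;
  R_xlen_t need = ((R_xlen_t)base_length * bits + 7) / 8;
  if (payload.size() != need)
    stop("payload has %d bytes but %d bases at %d bits/base require %d",
         (int)payload.size(), base_length, bits, (int)need);
  std::string out((size_t)base_length, 'X');
  R_xlen_t bitpos = 0;
  for (int i = 0; i < base_length; ++i) {
    int code = 0;
    for (int b = 0; b < bits; ++b, ++bitpos) {
      code = (code << 1) |
        ((payload[bitpos / 8] & (0x80 >> (bitpos % 8))) ? 1 : 0);
    }
    if (encoding == 0) {
      out[i] = DECODE2[code];
    } else {
      if (code > 4) stop("corrupt payload: invalid 3-bit code %d", code);
      out[i] = DECODE3[code];
    }
  }
  // pad bits beyond base_length * bits must be zero
  for (R_xlen_t p = bitpos; p < (R_xlen_t)payload.size() * 8; ++p) {
    if (payload[p / 8] & (0x80 >> (p % 8)))
      stop("corrupt payload: nonzero pad bits");
  }
  return out;
}

// MurmurHash2, 32-bit, by Austin Appleby (public domain reference
// algorithm). Computed over the payload bytes only; seed fixed upstream.
// [[Rcpp::export(name = ".murmur2_cpp")]]
double murmur2_cpp(RawVector data, double seed = 0) {
  const uint32_t m = 0x5bd1e995;
  const int r = 24;
  uint32_t len = (uint32_t)data.size();
  uint32_t h = ((uint32_t)seed) ^ len;
  R_xlen_t i = 0;
  R_xlen_t n = data.size();
  while (n - i >= 4) {
    uint32_t k = (uint32_t)data[i] | ((uint32_t)data[i + 1] << 8) |
      ((uint32_t)data[i + 2] << 16) | ((uint32_t)data[i + 3] << 24);
    k *= m;
    k ^= k >> r;
    k *= m;
    h *= m;
    h ^= k;
    i += 4;
  }
  switch (n - i) {
  case 3: h ^= (uint32_t)data[i + 2] << 16; // fall through
  case 2: h ^= (uint32_t)data[i + 1] << 8;  // fall through
  case 1: h ^= (uint32_t)data[i];
    h *= m;
  }
  h ^= h >> 13;
  h *= m;
  h ^= h >> 15;
  return (double)h;
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'N': return 'N';
  default:
    stop("invalid base '%s' in reverse complement", std::string(1, c).c_str());
  }
  return 'X'; // unreachable
}

static std::string rc_one(const std::string& s) {
  size_t n = s.size();
  std::string out(n, 'X');
  for (size_t i = 0; i < n; ++i) out[n - 1 - i] = comp_base(s[i]);
  return out;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = rc_one(as<std::string>(seqs[i]));
  return out;
}

// Locale-independent bytewise a <= b, used for canonical-orientation choice.
// [[Rcpp::export(name = ".bytewise_leq_cpp")]]
LogicalVector bytewise_leq_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = strcmp(CHAR(STRING_ELT(a, i)), CHAR(STRING_ELT(b, i))) <= 0;
  }
  return out;
}

// Exhaustive ungapped scan of every offset on both strands.
//
// mode 0 (symmetric): score = Hamming mismatches; a hit is valid when
//   score <= max_mismatch. Strand-symmetric by construction.
// mode 1 (left_seed): the first seed_len bases of the READ must match the
//   reference exactly. In forward projection the read's left end is the
//   projected sequence's left end on the forward strand, and its RIGHT end
//   on the reverse strand — this handedness is what makes reverse
//   complementation able to change the winning locus. Score counts
//   mismatches outside the seed.
//
// Winner: smallest (score, position, strand) with forward < reverse; the
// position-first tie-break keeps the scan strand-symmetric (the mirror of a
// leftmost winner is still leftmost).
// Returns pos = 0-based offset or NA, strand 0/1, score or NA.
// [[Rcpp::export(name = ".toy_scan_cpp")]]
DataFrame toy_scan_cpp(CharacterVector reads, std::string ref, int mode,
                       int seed_len, int max_mismatch) {
  R_xlen_t nref = ref.size();
  R_xlen_t nr = reads.size();
  IntegerVector pos(nr, NA_INTEGER), strand(nr, NA_INTEGER),
    score(nr, NA_INTEGER);
  for (R_xlen_t i = 0; i < nr; ++i) {
    std::string r = as<std::string>(reads[i]);
    R_xlen_t L = r.size();
    if (mode == 1 && seed_len >= (int)L)
      stop("seed_len must be shorter than the read length");
    if (L > nref) continue; // read longer than reference: unmapped
    std::string proj[2] = {r, rc_one(r)};
    int best_score = max_mismatch + 1;
    R_xlen_t best_pos = -1;
    int best_strand = -1;
    for (R_xlen_t o = 0; o + L <= nref; ++o) {
      for (int s = 0; s < 2; ++s) {
        const std::string& p = proj[s];
        int mm = 0, sc = 0;
        bool seed_ok = true;
        for (R_xlen_t j = 0; j < L; ++j) {
          bool match = (p[j] == ref[o + j]);
          if (!match) {
            ++mm;
            bool in_seed;
            if (mode == 1) {
              // read-left seed: leading bases of the forward projection,
              // trailing bases of the reverse projection
              in_seed = (s == 0) ? (j < (R_xlen_t)seed_len)
                                 : (j >= L - (R_xlen_t)seed_len);
            } else {
              in_seed = false;
            }
            if (in_seed) { seed_ok = false; break; }
            ++sc;
            if (sc >= best_score && mode == 0) break;
          }
        }
        if (mode == 1 && !seed_ok) continue;
        if (mode == 0) sc = mm;
        if (sc > max_mismatch) continue;
        if (sc < best_score ||
            (sc == best_score &&
             (o < best_pos || (o == best_pos && s < best_strand)))) {
          best_score = sc;
          best_pos = o;
          best_strand = s;
        }
      }
    }
    if (best_pos >= 0) {
      pos[i] = (int)best_pos;
      strand[i] = best_strand;
      score[i] = best_score;
    }
  }
  return DataFrame::create(_["pos"] = pos, _["strand"] = strand,
                           _["score"] = score);
}
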