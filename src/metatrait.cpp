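#include <Rcpp.h>
#include <string>
#include <cstring>
#include <vector>
using namespace Rcpp;

// base -> 0:A 1:C 2:G 3:T, -1 otherwise (N etc.)
static inline int base_idx(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline int codon_idx(const char *s) {
  int a = base_idx(s[0]), b = base_idx(s[1]), c = base_idx(s[2]);
  if (a < 0 || b < 0 || c < 0) return -1;
  return 16 * a + 4 * b + c;
}

// TAA = 3,0,0 -> 48; TAG = 3,0,2 -> 50; TGA = 3,2,0 -> 56
static inline bool is_stop(int idx) {
  return idx == 48 || idx == 50 || idx == 56;
}

// Codon counts in frame 0; trailing partial codon dropped; codons containing
// a non-ACGT base skipped.  Returns length-64 vector indexed 16a+4b+c; stop
// codons are counted here and excluded downstream.
// [[Rcpp::export]]
IntegerVector cpp_count_codons(std::string seq) {
  IntegerVector out(64);
  size_t L = seq.size();
  for (size_t p = 0; p + 3 <= L; p += 3) {
    int idx = codon_idx(seq.c_str() + p);
    if (idx >= 0) out[idx]++;
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_count_codons_batch(CharacterVector seqs) {
  int n = seqs.size();
  IntegerMatrix out(64, n);
  for (int i = 0; i < n; i++) {
    std::string s = as<std::string>(seqs[i]);
    size_t L = s.size();
    for (size_t p = 0; p + 3 <= L; p += 3) {
      int idx = codon_idx(s.c_str() + p);
      if (idx >= 0) out(idx, i)++;
    }
  }
  return out;
}

struct OrfHit { int start, end, strand, frame; };

// maximal stop-free codon runs on one strand; coords local to `s`
static void scan_frames(const std::string &s, int min_len,
                        int strand, std::vector<OrfHit> &hits) {
  int L = (int)s.size();
  for (int f = 0; f < 3; f++) {
    int run_start = f, p = f;
    for (; p + 3 <= L; p += 3) {
      int idx = codon_idx(s.c_str() + p);
      if (is_stop(idx)) {
        if (p - run_start >= min_len)
          hits.push_back({run_start, p, strand, f});
        run_start = p + 3;
      }
    }
    if (p - run_start >= min_len)
      hits.push_back({run_start, p, strand, f});
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); i++) {
    switch (r[i]) {
    case 'A': case 'a': r[i] = 'T'; break;
    case 'C': case 'c': r[i] = 'G'; break;
    case 'G': case 'g': r[i] = 'C'; break;
    case 'T': case 't': r[i] = 'A'; break;
    default: r[i] = 'N';
    }
  }
  return r;
}

// Six-frame ORF scan.  Columns: start, end (0-based half-open, forward
// coordinates), strand (+1/-1), frame (0-2 on the scanned strand).
// [[Rcpp::export]]
IntegerMatrix cpp_find_orfs(std::string seq, int min_len) {
  std::vector<OrfHit> hits;
  scan_frames(seq, min_len, 1, hits);
  std::string rc = revcomp(seq);
  size_t nfwd = hits.size();
  scan_frames(rc, min_len, -1, hits);
  int L = (int)seq.size();
  for (size_t i = nfwd; i < hits.size(); i++) { // map rc coords to forward
    int s = hits[i].start, e = hits[i].end;
    hits[i].start = L - e;
    hits[i].end = L - s;
  }
  IntegerMatrix out((int)hits.size(), 4);
  for (size_t i = 0; i < hits.size(); i++) {
    out(i, 0) = hits[i].start;
    out(i, 1) = hits[i].end;
    out(i, 2) = hits[i].strand;
    out(i, 3) = hits[i].frame;
  }
  colnames(out) = CharacterVector::create("start", "end", "strand", "frame");
  return out;
}

// Pooled G+C and usable (non-N) nucleotide totals over all six-frame ORFs
// of all sequences; same ORF definition as cpp_find_orfs.  Works directly
// on the forward buffer (complementation preserves G+C, so reverse-strand
// runs are scored on their forward footprint).  Returns c(gc, total).
// [[Rcpp::export]]
NumericVector cpp_orf_gc_pool(CharacterVector seqs, int min_len) {
  double gc = 0, tot = 0;
  for (int i = 0; i < seqs.size(); i++) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int L = (int)strlen(s);
    // add GC/total for forward span [from, to)
    auto add_span = [&](int from, int to) {
      for (int p = from; p < to; p++) {
        int b = base_idx(s[p]);
        if (b < 0) continue;
        tot += 1;
        if (b == 1 || b == 2) gc += 1;
      }
    };
    for (int f = 0; f < 3; f++) {
      // forward strand
      int run_start = f, p = f;
      for (; p + 3 <= L; p += 3) {
        int idx = codon_idx(s + p);
        if (is_stop(idx)) {
          if (p - run_start >= min_len) add_span(run_start, p);
          run_start = p + 3;
        }
      }
      if (p - run_start >= min_len) add_span(run_start, p);
      // reverse strand, scanned in reverse-complement coordinates: rc
      // position q reads complement of s[L-1-q]
      run_start = f;
      p = f;
      for (; p + 3 <= L; p += 3) {
        int a = base_idx(s[L - 1 - p]), b = base_idx(s[L - 2 - p]),
            c = base_idx(s[L - 3 - p]);
        int idx = (a < 0 || b < 0 || c < 0) ? -1
                  : 16 * (3 - a) + 4 * (3 - b) + (3 - c);
        if (is_stop(idx)) {
          if (p - run_start >= min_len) add_span(L - p, L - run_start);
          run_start = p + 3;
        }
      }
      if (p - run_start >= min_len) add_span(L - p, L - run_start);
    }
  }
  return NumericVector::create(gc, tot);
}

// counts of A, C, G, T over all sequences (N and others excluded)
// [[Rcpp::export]]
NumericVector cpp_base_counts(CharacterVector seqs) {
  NumericVector out(4);
  for (int i = 0; i < seqs.size(); i++) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    for (; *s; s++) {
      int b = base_idx(*s);
      if (b >= 0) out[b] += 1;
    }
  }
  out.names() = CharacterVector::create("A", "C", "G", "T");
  return out;
}

// fast local PRNG (xorshift128+) keyed from R's RNG stream, so read
// generation stays reproducible under set.seed while avoiding a slow
// R-API call per base
static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// i.i.d. random reads with P(G) = P(C) = gc/2; seedable via set.seed in R
// [[Rcpp::export]]
CharacterVector cpp_random_reads(int n, int len, double gc) {
  RNGScope scope;
  uint64_t key = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
                 (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t s0 = splitmix64(key), s1 = splitmix64(key);
  CharacterVector out(n);
  std::string buf(len, 'A');
  double th_g = gc / 2, th_c = gc, th_a = gc + (1 - gc) / 2;
  for (int i = 0; i < n; i++) {
    for (int j = 0; j < len; j++) {
      uint64_t x = s0, y = s1;
      s0 = y;
      x ^= x << 23;
      s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
      double u = ((s1 + y) >> 11) * (1.0 / 9007199254740992.0);
      buf[j] = (u < th_g) ? 'G' : (u < th_c) ? 'C' : (u < th_a) ? 'A' : 'T';
    }
    out[i] = buf;
  }
  return out;
}

// mean Phred score per quality string (offset 33)
// [[Rcpp::export]]
NumericVector cpp_mean_qual(CharacterVector quals) {
  int n = quals.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    const char *s = CHAR(STRING_ELT(quals, i));
    double acc = 0;
    int m = 0;
    for (; *s; s++, m++) acc += (double)(*s - 33);
    out[i] = m ? acc / m : NA_REAL;
  }
  return out;
}
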