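// Bit-packed DNA core: 4-bit one-hot codes packed two-per-byte, loaded as
// unsigned 64-bit words at byte granularity.  A 64-bit load at byte position n
// covers bases 2n..2n+15; an AND of two such words followed by popcount counts
// matching bases, because distinct unambiguous codes share no bits.
#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------- encoding

// code -> IUPAC character (code 0 is the gap)
static const char CODE2CHAR[17] = "-ACMGRSVTWYHKDBN";

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'M': case 'm': return 3;
    case 'G': case 'g': return 4;
    case 'R': case 'r': return 5;
    case 'S': case 's': return 6;
    case 'V': case 'v': return 7;
    case 'T': case 't': return 8;
    case 'W': case 'w': return 9;
    case 'Y': case 'y': return 10;
    case 'H': case 'h': return 11;
    case 'K': case 'k': return 12;
    case 'D': case 'd': return 13;
    case 'B': case 'b': return 14;
    case 'N': case 'n': return 15;
    case '-': return 0;
    default: return -1;
  }
}

// complement of a one-hot nibble = bit reversal within the nibble
// (A<->T, C<->G; N, S and gap are self-complementary)
static inline int nib_comp(int c) {
  return ((c & 1) << 3) | ((c & 2) << 1) | ((c & 4) >> 1) | ((c & 8) >> 3);
}

struct Packed {
  std::vector<uint8_t> bytes; // ceil(n/2) data bytes + 8 zero padding bytes
  int n;                      // number of encoded bases
};

static Packed pack(const std::string& s) {
  Packed p;
  p.n = (int)s.size();
  p.bytes.assign((size_t)((p.n + 1) / 2 + 8), 0);
  for (int i = 0; i < p.n; ++i) {
    int c = base_code(s[i]);
    if (c < 0)
      stop("unknown base '%s' at position %d", std::string(1, s[i]).c_str(), i + 1);
    p.bytes[(size_t)(i >> 1)] |= (uint8_t)(c << ((i & 1) * 4));
  }
  return p;
}

static inline int code_at(const Packed& p, int i) {
  return (p.bytes[(size_t)(i >> 1)] >> ((i & 1) * 4)) & 0xF;
}

static std::string unpack(const Packed& p) {
  std::string s((size_t)p.n, ' ');
  for (int i = 0; i < p.n; ++i) s[(size_t)i] = CODE2CHAR[code_at(p, i)];
  return s;
}

// little-endian assembly so that base 2n sits in the least-significant nibble
static inline uint64_t load_word(const Packed& p, int bytepos) {
  uint64_t w = 0;
  for (int j = 0; j < 8; ++j)
    w |= (uint64_t)p.bytes[(size_t)(bytepos + j)] << (8 * j);
  return w;
}

// tolerant load: bytes beyond the padded buffer read as zero (gap)
static inline uint64_t load_word_safe(const Packed& p, int bytepos) {
  if (bytepos < 0) return 0;
  if (bytepos + 8 <= (int)p.bytes.size()) return load_word(p, bytepos);
  uint64_t w = 0;
  for (int j = 0; j < 8 && bytepos + j < (int)p.bytes.size(); ++j)
    w |= (uint64_t)p.bytes[(size_t)(bytepos + j)] << (8 * j);
  return w;
}

static Packed rc_packed(const Packed& p) {
  Packed out;
  out.n = p.n;
  out.bytes.assign((size_t)((p.n + 1) / 2 + 8), 0);
  for (int i = 0; i < p.n; ++i) {
    int c = nib_comp(code_at(p, p.n - 1 - i));
    out.bytes[(size_t)(i >> 1)] |= (uint8_t)(c << ((i & 1) * 4));
  }
  return out;
}

static inline int popcnt64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int n = 0;
  while (x) { x &= x - 1; ++n; }
  return n;
#endif
}

// mismatch count K = 16 - popcount(a & b), clamped at 0 (shared ambiguity
// bits can push popcount above 16)
static inline int mismatches(uint64_t a, uint64_t b) {
  int k = 16 - popcnt64(a & b);
  return k < 0 ? 0 : k;
}

// ---------------------------------------------------------------- matching

struct ScanRes {
  int pos;    // best offset (smallest offset achieving the minimum K); -1 if none
  int nm;     // 16 - K at the best offset
  bool found; // min K <= k
};

// head words of the query: a0 covers bases 0..15, a_minus covers bases 1..16
static inline void head_words(const Packed& q, uint64_t& a0, uint64_t& am) {
  a0 = load_word(q, 0);
  am = (a0 >> 4) | (load_word(q, 1) << 4);
}

// scan the query's 16-base head along every offset 0..subject.n-1.
// Even offsets compare a0 against the word at byte o/2; odd offsets compare
// a_minus against the word at byte (o+1)/2 (query bases 1..16 vs subject
// bases o+1..o+16).  Offset -1 is excluded.  Subject bases past the end read
// as gaps and count as mismatches.
static ScanRes scan16(const Packed& q, const Packed& b, int k) {
  ScanRes r; r.pos = -1; r.nm = 0; r.found = false;
  if (q.n == 0 || b.n == 0) return r;
  uint64_t a0, am;
  head_words(q, a0, am);
  int bestK = 17;
  for (int o = 0; o < b.n; ++o) {
    uint64_t qw = (o & 1) ? am : a0;
    uint64_t bw = load_word(b, (o + 1) / 2); // odd offsets
    if (!(o & 1)) bw = load_word(b, o / 2);  // even offsets
    int K = mismatches(qw, bw);
    if (K < bestK) { bestK = K; r.pos = o; }
    if (bestK == 0) break; // cannot improve; smallest offset already kept
  }
  r.nm = 16 - bestK;
  r.found = bestK <= k;
  return r;
}

// single-offset comparison of the query head at a given subject offset
static int match_at16(const Packed& q, const Packed& b, int o) {
  if (q.n == 0) return 0;
  uint64_t a0, am;
  head_words(q, a0, am);
  uint64_t bw = (o & 1) ? load_word_safe(b, (o + 1) / 2) : load_word_safe(b, o / 2);
  return 16 - mismatches((o & 1) ? am : a0, bw);
}

// ---------------------------------------------------------------- scoring

static inline double phred_prob(int q) {
  return 1.0 - std::pow(10.0, -q / 10.0);
}

// mean base-correct probability over the 16 bases starting at `start`
// (0-based), restricted to in-range bases.  floored=true applies the 0.75
// lower bound; an empty window returns the floor (or 0 unfloored).
static double mean16(const std::string& qual, int start, bool floored) {
  int len = (int)qual.size();
  double s = 0.0; int cnt = 0;
  for (int i = start; i < start + 16; ++i) {
    if (i < 0 || i >= len) continue;
    s += phred_prob((int)qual[(size_t)i] - 33);
    ++cnt;
  }
  if (cnt == 0) return floored ? 0.75 : 0.0;
  double m = s / cnt;
  if (floored && m < 0.75) m = 0.75;
  return m;
}

// ------------------------------------------------------- four-way matching

struct Match {
  bool found;   // min K within tolerance (or accepted by the loosened redo)
  int pos;      // insert-size candidate implied by the best offset
  int nm;       // matched bases at the best offset (raw, reported even if !found)
  double score; // quality-weighted score; 0 when !found
};

struct PairState {
  Match a1, a2, p1, p2; // adapter r1/r2, paired-end r1/r2
  int k_extra;
};

static PairState four_way(const Packed& r1, const std::string& q1,
                          const Packed& r2, const std::string& q2,
                          const Packed& ad1, const Packed& ad2,
                          int k, int cutoff) {
  PairState st;
  // (a) adapter head vs read: insert-size candidate = match offset
  ScanRes s1a = scan16(ad1, r1, k);
  ScanRes s2a = scan16(ad2, r2, k);
  st.a1 = { s1a.found, s1a.pos, s1a.nm, 0.0 };
  st.a2 = { s2a.found, s2a.pos, s2a.nm, 0.0 };
  // (b) loosen k for the paired-end matches when adapter evidence is weak
  st.k_extra = (std::max(s1a.nm, s2a.nm) < cutoff) ? 1 : 0;
  // (c) read_i head vs reverse complement of read_j: s = len_j - offset
  Packed rc1 = rc_packed(r1), rc2 = rc_packed(r2);
  ScanRes s1p = scan16(r1, rc2, k + st.k_extra);
  ScanRes s2p = scan16(r2, rc1, k + st.k_extra);
  st.p1 = { s1p.found, s1p.pos < 0 ? -1 : r2.n - s1p.pos, s1p.nm, 0.0 };
  st.p2 = { s2p.found, s2p.pos < 0 ? -1 : r1.n - s2p.pos, s2p.nm, 0.0 };
  // (d) loosened redo at the best match's insert size
  Match* ms[4] = { &st.a1, &st.a2, &st.p1, &st.p2 };
  int best = 0;
  for (int i = 1; i < 4; ++i) if (ms[i]->nm > ms[best]->nm) best = i;
  if (ms[best]->nm > cutoff && ms[best]->pos >= 0) {
    int s_best = ms[best]->pos;
    for (int i = 0; i < 4; ++i) {
      if (ms[i]->nm >= cutoff) continue;
      int off;
      const Packed* q; const Packed* b;
      switch (i) {
        case 0: off = s_best;        q = &ad1; b = &r1;  break;
        case 1: off = s_best;        q = &ad2; b = &r2;  break;
        case 2: off = r2.n - s_best; q = &r1;  b = &rc2; break;
        default: off = r1.n - s_best; q = &r2; b = &rc1; break;
      }
      if (off < 0) continue;
      int nm2 = match_at16(*q, *b, off);
      if (nm2 > cutoff) {
        ms[i]->found = true;
        ms[i]->pos = s_best;
        ms[i]->nm = nm2;
      }
    }
  }
  // (e) scores; adapter probability is 1 for user-supplied adapters
  if (st.a1.found) st.a1.score = st.a1.nm * mean16(q1, st.a1.pos, true);
  if (st.a2.found) st.a2.score = st.a2.nm * mean16(q2, st.a2.pos, true);
  if (st.p1.found)
    st.p1.score = st.p1.nm * mean16(q1, st.p1.pos, true) * mean16(q2, 0, true);
  if (st.p2.found)
    st.p2.score = st.p2.nm * mean16(q2, st.p2.pos, true) * mean16(q1, 0, true);
  return st;
}

// ---------------------------------------------------------- decision rules

struct Rec { bool present; int pos; double score; };

static Rec reconcile_rec(const Rec& a, const Rec& b) {
  if (!a.present && !b.present) return { false, -1, 0.0 };
  if (!a.present) return b;
  if (!b.present) return a;
  if (a.pos == b.pos) return { true, a.pos, a.score + b.score };
  return (b.score > a.score) ? b : a; // tie keeps the first argument
}

enum Reason { AGREED = 1, SCORE_MAX = 2, LOWQ_OVERRIDE = 3,
              TAIL_FP = 4, BELOW_THRESHOLD = 5 };

struct Verdict {
  bool trim;
  int s1, s2;   // kept lengths
  double score; // reconciled r12 score
  int reason;
};

// adjacent-1-bp re-positioning: the adapter's first four bases are compared
// at candidate starts s-1, s, s+1; highest matched count wins, ties prefer s
// then the smaller offset
static int adjust_pos(const Packed& read, const Packed& adapter, int s) {
  int cands[3] = { s, s - 1, s + 1 };
  int bestc = s, bestn = -1;
  for (int ci = 0; ci < 3; ++ci) {
    int c = cands[ci];
    if (c < 0) continue;
    int n = 0;
    for (int j = 0; j < 4 && j < adapter.n; ++j) {
      int i = c + j;
      int rb = (i >= 0 && i < read.n) ? code_at(read, i) : 0;
      if (rb & code_at(adapter, j)) ++n;
    }
    if (n > bestn) { bestn = n; bestc = c; } // strict >: ties keep s, then s-1
  }
  return bestc;
}

static Verdict decide_pair(const PairState& st,
                           const Packed& r1, const std::string& q1,
                           const Packed& r2, const std::string& q2,
                           const Packed& ad1, const Packed& ad2,
                           double trim_score, int tail_len, bool tail_prose) {
  Rec a1 = { st.a1.found, st.a1.pos, st.a1.score };
  Rec p1 = { st.p1.found, st.p1.pos, st.p1.score };
  Rec a2 = { st.a2.found, st.a2.pos, st.a2.score };
  Rec p2 = { st.p2.found, st.p2.pos, st.p2.score };
  Rec r1r = reconcile_rec(a1, p1);
  Rec r2r = reconcile_rec(a2, p2);
  Rec r12 = reconcile_rec(r1r, r2r);

  Verdict v; v.trim = false; v.s1 = r1.n; v.s2 = r2.n;
  v.score = r12.score; v.reason = BELOW_THRESHOLD;
  if (!r12.present) return v;

  bool do_trim = false;
  int reason = 0;

  // low-quality override: positions differ, one read has a convincing score
  // and the other cannot argue (too short, or unfloored 16-mer accuracy < 0.6)
  bool differ = !(r1r.present && r2r.present && r1r.pos == r2r.pos);
  if (differ) {
    if (r1r.present && r1r.score > trim_score &&
        (r2.n <= r1r.pos || mean16(q2, r1r.pos, false) < 0.6)) {
      do_trim = true; reason = LOWQ_OVERRIDE;
    } else if (r2r.present && r2r.score > trim_score &&
               (r1.n <= r2r.pos || mean16(q1, r2r.pos, false) < 0.6)) {
      do_trim = true; reason = LOWQ_OVERRIDE;
    }
  }

  if (!do_trim) {
    // tail false-positive filter
    auto in_tail = [&](int pos, int len) { return pos >= len - tail_len; };
    bool E1, E2;
    if (!tail_prose) {
      E1 = a1.present && p1.present && in_tail(a1.pos, r1.n) && in_tail(p1.pos, r1.n);
      E2 = a2.present && p2.present && in_tail(a2.pos, r2.n) && in_tail(p2.pos, r2.n);
    } else {
      // prose reading: adapter in the tail but the paired-end match is not
      E1 = a1.present && in_tail(a1.pos, r1.n) && !(p1.present && in_tail(p1.pos, r1.n));
      E2 = a2.present && in_tail(a2.pos, r2.n) && !(p2.present && in_tail(p2.pos, r2.n));
    }
    bool R1 = a1.present && p1.present && a1.pos == p1.pos;
    bool R2 = a2.present && p2.present && a2.pos == p2.pos;
    bool fp = (E1 || E2) && !(R1 || R2);
    if (r12.score > trim_score && !fp) {
      do_trim = true;
      reason = (r1r.present && r2r.present && r1r.pos == r2r.pos) ? AGREED : SCORE_MAX;
    } else {
      v.reason = (r12.score > trim_score && fp) ? TAIL_FP : BELOW_THRESHOLD;
      return v;
    }
  }

  int s = r12.pos;
  int s1 = (s > r1.n - 3) ? s : adjust_pos(r1, ad1, s);
  int s2 = (s > r2.n - 3) ? s : adjust_pos(r2, ad2, s);
  v.trim = true;
  v.s1 = std::min(s1, r1.n);
  v.s2 = std::min(s2, r2.n);
  v.reason = reason;
  return v;
}

// ------------------------------------------------------ consensus calling

struct OverlapPred { bool overlap; int s; };

static OverlapPred predict_ov(const Packed& r1, const Packed& r2,
                              bool trimmed, int k) {
  if (trimmed) {
    if (r1.n == r2.n && r1.n > 0) return { true, r1.n };
    return { false, -1 };
  }
  Packed rc1 = rc_packed(r1), rc2 = rc_packed(r2);
  ScanRes m1 = scan16(rc2, r1, k); // head of rc(r2) in r1: s = offset + len2
  ScanRes m2 = scan16(rc1, r2, k); // head of rc(r1) in r2: s = offset + len1
  if (m1.found && m2.found && m1.pos + r2.n == m2.pos + r1.n)
    return { true, m1.pos + r2.n };
  return { false, -1 };
}

// mismatch ratio over the whole overlapped region; N is demoted to the gap
// code first, so N opposite anything counts as a mismatch
static bool assess_ov(const Packed& r1, const Packed& r2, int s,
                      double max_ratio, double* ratio_out) {
  int lo = std::max(0, s - r2.n), hi = std::min(r1.n, s);
  int len = hi - lo;
  if (ratio_out) *ratio_out = NA_REAL;
  if (len <= 0) return false;
  int mm = 0;
  for (int i = lo; i < hi; ++i) {
    int c1 = code_at(r1, i); if (c1 == 15) c1 = 0;
    int c2 = code_at(r2, s - 1 - i); if (c2 == 15) c2 = 0;
    if ((c1 & nib_comp(c2)) == 0) ++mm;
  }
  double ratio = (double)mm / len;
  if (ratio_out) *ratio_out = ratio;
  return ratio <= max_ratio;
}

// replace disagreeing calls by the higher-quality call (complemented for the
// mate); the winning quality is copied to both positions; equal qualities keep
// read 1's call
static int correct_ov(std::string& s1, std::string& q1,
                      std::string& s2, std::string& q2, int s) {
  int L1 = (int)s1.size(), L2 = (int)s2.size();
  int lo = std::max(0, s - L2), hi = std::min(L1, s);
  int ncorr = 0;
  for (int i = lo; i < hi; ++i) {
    int j = s - 1 - i;
    int c1 = base_code(s1[(size_t)i]);
    int c2 = base_code(s2[(size_t)j]);
    if (c1 == nib_comp(c2)) { // agreeing calls (case-insensitive)
      continue;
    }
    ++ncorr;
    if ((int)q1[(size_t)i] >= (int)q2[(size_t)j]) {
      s2[(size_t)j] = CODE2CHAR[nib_comp(c1)];
      q2[(size_t)j] = q1[(size_t)i];
    } else {
      s1[(size_t)i] = CODE2CHAR[nib_comp(c2)];
      q1[(size_t)i] = q2[(size_t)j];
    }
  }
  return ncorr;
}

// ------------------------------------------------------- quality trimming

// first window (starts 0,1,2,..., truncated at the tail) whose mean Phred
// falls below the threshold marks the cut: that base and everything after it
// is removed.  Returns the kept length.
static int qtrim_keep(const std::string& qual, int window, double threshold) {
  int len = (int)qual.size();
  if (len == 0 || window < 1) return len;
  std::vector<int> cum((size_t)len + 1, 0);
  for (int i = 0; i < len; ++i) cum[(size_t)i + 1] = cum[(size_t)i] + ((int)qual[(size_t)i] - 33);
  for (int start = 0; start < len; ++start) {
    int end = std::min(start + window, len);
    double mean = (double)(cum[(size_t)end] - cum[(size_t)start]) / (end - start);
    if (mean < threshold) return start;
  }
  return len;
}

// ============================================================ R interface

static List packed_to_list(const Packed& p) {
  int nwords = (int)p.bytes.size() / 8 + (((int)p.bytes.size() % 8) ? 1 : 0);
  CharacterVector words(nwords);
  for (int w = 0; w < nwords; ++w) {
    uint64_t x = 0;
    for (int j = 0; j < 8; ++j) {
      size_t idx = (size_t)(w * 8 + j);
      if (idx < p.bytes.size()) x |= (uint64_t)p.bytes[idx] << (8 * j);
    }
    char buf[17];
    snprintf(buf, sizeof buf, "%016llx", (unsigned long long)x);
    words[w] = buf;
  }
  List out = List::create(_["words"] = words, _["n_bases"] = p.n);
  out.attr("class") = "packed_seq";
  return out;
}

static uint64_t word_from_hex(const std::string& h);

static Packed packed_from_list(const List& l) {
  CharacterVector words = l["words"];
  int n = as<int>(l["n_bases"]);
  Packed p; p.n = n;
  p.bytes.assign((size_t)((n + 1) / 2 + 8), 0);
  for (int w = 0; w < words.size(); ++w) {
    uint64_t x = word_from_hex(CHAR(STRING_ELT(words, w)));
    for (int j = 0; j < 8; ++j) {
      size_t idx = (size_t)(w * 8 + j);
      if (idx < p.bytes.size()) p.bytes[idx] = (uint8_t)((x >> (8 * j)) & 0xFF);
    }
  }
  return p;
}

static uint64_t word_from_hex(const std::string& h) {
  uint64_t x = 0;
  for (char c : h) {
    int d;
    if (c >= '0' && c <= '9') d = c - '0';
    else if (c >= 'a' && c <= 'f') d = c - 'a' + 10;
    else if (c >= 'A' && c <= 'F') d = c - 'A' + 10;
    else stop("invalid hexadecimal word '%s'", h.c_str());
    x = (x << 4) | (uint64_t)d;
  }
  return x;
}

static std::string word_to_hex(uint64_t x) {
  char buf[17];
  snprintf(buf, sizeof buf, "%016llx", (unsigned long long)x);
  return std::string(buf);
}

// [[Rcpp::export]]
List cpp_encode(std::string seq) { return packed_to_list(pack(seq)); }

// [[Rcpp::export]]
std::string cpp_decode(List pseq) { return unpack(packed_from_list(pseq)); }

// [[Rcpp::export]]
std::string cpp_word_at(List pseq, int n) {
  Packed p = packed_from_list(pseq);
  if (n < 0 || n + 8 > (int)p.bytes.size())
    stop("memory position %d is outside the padded buffer (0..%d)",
         n, (int)p.bytes.size() - 8);
  return word_to_hex(load_word(p, n));
}

// [[Rcpp::export]]
List cpp_head_pair(List pseq) {
  Packed p = packed_from_list(pseq);
  if (p.n < 1) stop("head_pair requires at least one base");
  uint64_t a0, am;
  head_words(p, a0, am);
  return List::create(_["a0"] = word_to_hex(a0), _["a_minus"] = word_to_hex(am));
}

// [[Rcpp::export]]
List cpp_reverse_complement(List pseq) {
  return packed_to_list(rc_packed(packed_from_list(pseq)));
}

// [[Rcpp::export]]
int cpp_mismatch_count(std::string a_word, std::string b_word) {
  return mismatches(word_from_hex(a_word), word_from_hex(b_word));
}

// [[Rcpp::export]]
List cpp_scan(List query, List subject, int k) {
  ScanRes r = scan16(packed_from_list(query), packed_from_list(subject), k);
  return List::create(_["found"] = r.found, _["offset"] = r.pos,
                      _["n_match"] = r.nm);
}

// [[Rcpp::export]]
int cpp_match_at(List query, List subject, int offset) {
  if (offset < 0) stop("offset must be non-negative");
  return match_at16(packed_from_list(query), packed_from_list(subject), offset);
}

// [[Rcpp::export]]
double cpp_mean16(std::string qual, int start, bool floored) {
  return mean16(qual, start, floored);
}

static List state_to_list(const PairState& st) {
  auto m = [](const Match& x) {
    return List::create(_["found"] = x.found,
                        _["pos"] = x.pos, _["n_match"] = x.nm,
                        _["score"] = x.score);
  };
  return List::create(_["adapter_r1"] = m(st.a1), _["adapter_r2"] = m(st.a2),
                      _["pe_r1"] = m(st.p1), _["pe_r2"] = m(st.p2),
                      _["k_extra"] = st.k_extra);
}

static PairState state_from_list(const List& l) {
  auto m = [](const List& x) {
    Match r;
    r.found = as<bool>(x["found"]);
    r.pos = as<int>(x["pos"]);
    r.nm = as<int>(x["n_match"]);
    r.score = as<double>(x["score"]);
    return r;
  };
  PairState st;
  st.a1 = m(l["adapter_r1"]); st.a2 = m(l["adapter_r2"]);
  st.p1 = m(l["pe_r1"]); st.p2 = m(l["pe_r2"]);
  st.k_extra = as<int>(l["k_extra"]);
  return st;
}

// [[Rcpp::export]]
List cpp_four_way(std::string s1, std::string q1, std::string s2, std::string q2,
                  std::string adapter1, std::string adapter2, int k, int cutoff) {
  Packed r1 = pack(s1), r2 = pack(s2), a1 = pack(adapter1), a2 = pack(adapter2);
  return state_to_list(four_way(r1, q1, r2, q2, a1, a2, k, cutoff));
}

// [[Rcpp::export]]
List cpp_decide(List state, std::string s1, std::string q1,
                std::string s2, std::string q2,
                std::string adapter1, std::string adapter2,
                double trim_score, int tail_len, bool tail_prose) {
  Packed r1 = pack(s1), r2 = pack(s2), a1 = pack(adapter1), a2 = pack(adapter2);
  Verdict v = decide_pair(state_from_list(state), r1, q1, r2, q2, a1, a2,
                          trim_score, tail_len, tail_prose);
  return List::create(_["trim"] = v.trim,
                      _["insert_size_r1"] = v.s1, _["insert_size_r2"] = v.s2,
                      _["combined_score"] = v.score, _["reason"] = v.reason);
}

// [[Rcpp::export]]
int cpp_adjust_position(std::string seq, std::string adapter, int s) {
  return adjust_pos(pack(seq), pack(adapter), s);
}

// [[Rcpp::export]]
List cpp_predict_overlap(std::string s1, std::string s2, bool trimmed, int k) {
  OverlapPred p = predict_ov(pack(s1), pack(s2), trimmed, k);
  return List::create(_["overlap"] = p.overlap, _["insert_size"] = p.s);
}

// [[Rcpp::export]]
List cpp_assess_overlap(std::string s1, std::string s2, int s, double max_ratio) {
  double ratio;
  bool ok = assess_ov(pack(s1), pack(s2), s, max_ratio, &ratio);
  return List::create(_["pass"] = ok, _["mismatch_ratio"] = ratio);
}

// [[Rcpp::export]]
List cpp_correct_overlap(std::string s1, std::string q1,
                         std::string s2, std::string q2, int s) {
  int n = correct_ov(s1, q1, s2, q2, s);
  return List::create(_["seq1"] = s1, _["qual1"] = q1,
                      _["seq2"] = s2, _["qual2"] = q2, _["n_corrected"] = n);
}

// [[Rcpp::export]]
int cpp_quality_trim_keep(std::string qual, int window, double threshold) {
  return qtrim_keep(qual, window, threshold);
}

// ------------------------------------------------------------ batch driver

// Full per-pair pipeline over parallel vectors; reuses the per-pair internals
// above so that the batch path and the exported module operations cannot
// diverge.  Stage order: adapter trim -> consensus -> quality trim -> N-trim
// -> hard clip -> length filter (the filter is reported as a drop flag).
// [[Rcpp::export]]
List cpp_trim_batch(CharacterVector seq1, CharacterVector qual1,
                    CharacterVector seq2, CharacterVector qual2,
                    std::string adapter1, std::string adapter2,
                    int k, int cutoff, double trim_score, int tail_len,
                    bool tail_prose, bool consensus, double max_mismatch_ratio,
                    bool do_qtrim, int window, double quality_threshold,
                    bool do_ntrim, int clip_front, int clip_tail,
                    int min_length) {
  int n = seq1.size();
  Packed ad1 = pack(adapter1), ad2 = pack(adapter2);
  CharacterVector out_s1(n), out_q1(n), out_s2(n), out_q2(n);
  LogicalVector trimmed(n), corrected(n), dropped(n);
  IntegerVector ins1(n), ins2(n), reason(n);
  NumericVector score(n);
  for (int i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(seq1[i]), q1 = as<std::string>(qual1[i]);
    std::string s2 = as<std::string>(seq2[i]), q2 = as<std::string>(qual2[i]);
    if (s1.size() != q1.size() || s2.size() != q2.size())
      stop("sequence/quality length mismatch in pair %d", i + 1);
    Packed r1 = pack(s1), r2 = pack(s2);
    PairState st = four_way(r1, q1, r2, q2, ad1, ad2, k, cutoff);
    Verdict v = decide_pair(st, r1, q1, r2, q2, ad1, ad2,
                            trim_score, tail_len, tail_prose);
    trimmed[i] = v.trim; score[i] = v.score; reason[i] = v.reason;
    ins1[i] = v.s1; ins2[i] = v.s2;
    if (v.trim) {
      s1.resize((size_t)v.s1); q1.resize((size_t)v.s1);
      s2.resize((size_t)v.s2); q2.resize((size_t)v.s2);
    }
    if (consensus) {
      Packed t1 = pack(s1), t2 = pack(s2);
      OverlapPred p = predict_ov(t1, t2, v.trim, k);
      if (p.overlap && assess_ov(t1, t2, p.s, max_mismatch_ratio, nullptr)) {
        int ncorr = correct_ov(s1, q1, s2, q2, p.s);
        corrected[i] = ncorr > 0;
      }
    }
    if (do_qtrim) {
      int k1 = qtrim_keep(q1, window, quality_threshold);
      int k2 = qtrim_keep(q2, window, quality_threshold);
      s1.resize((size_t)k1); q1.resize((size_t)k1);
      s2.resize((size_t)k2); q2.resize((size_t)k2);
    }
    if (do_ntrim) {
      size_t p1 = s1.find_first_of("Nn");
      size_t p2 = s2.find_first_of("Nn");
      if (p1 != std::string::npos) { s1.resize(p1); q1.resize(p1); }
      if (p2 != std::string::npos) { s2.resize(p2); q2.resize(p2); }
    }
    if (clip_front > 0 || clip_tail > 0) {
      auto clip = [&](std::string& s, std::string& q) {
        int len = (int)s.size();
        int from = std::min(clip_front, len);
        int to = std::max(from, len - clip_tail);
        s = s.substr((size_t)from, (size_t)(to - from));
        q = q.substr((size_t)from, (size_t)(to - from));
      };
      clip(s1, q1); clip(s2, q2);
    }
    if ((int)s1.size() < min_length || (int)s2.size() < min_length)
      dropped[i] = true;
    out_s1[i] = s1; out_q1[i] = q1; out_s2[i] = s2; out_q2[i] = q2;
  }
  return List::create(
      _["seq1"] = out_s1, _["qual1"] = out_q1,
      _["seq2"] = out_s2, _["qual2"] = out_q2,
      _["trimmed"] = trimmed, _["insert_size_r1"] = ins1,
      _["insert_size_r2"] = ins2, _["combined_score"] = score,
      _["reason"] = reason, _["consensus_corrected"] = corrected,
      _["dropped"] = dropped);
}

// ---------------------------------------------------------------- simulator

// Base-by-base copy of a template with an error profile, mimicking sequencing
// by synthesis.  Uses R's RNG so that set.seed() governs reproducibility.
// Returns the emitted read and the final-read position of the first surviving
// base derived from template positions >= adapter_start (read_length if none).
static void copy_template(const std::string& tmpl, int adapter_start,
                          int read_length, double sub, double ins, double del,
                          std::string& read, int& true_pos) {
  static const char BASES[4] = { 'A', 'C', 'G', 'T' };
  read.clear();
  read.reserve((size_t)read_length);
  true_pos = read_length;
  for (size_t t = 0; t < tmpl.size() && (int)read.size() < read_length; ++t) {
    if (unif_rand() < del) continue; // base skipped
    if (unif_rand() < ins) {         // random base emitted before it
      read.push_back(BASES[(int)(unif_rand() * 4) & 3]);
      if ((int)read.size() >= read_length) break;
    }
    char b = tmpl[t];
    if (unif_rand() < sub) {
      int orig = 0;
      while (BASES[orig] != b && orig < 3) ++orig;
      b = BASES[(orig + 1 + ((int)(unif_rand() * 3) % 3)) & 3];
    }
    if ((int)t >= adapter_start && true_pos == read_length)
      true_pos = (int)read.size();
    read.push_back(b);
  }
  while ((int)read.size() < read_length)
    read.push_back(BASES[(int)(unif_rand() * 4) & 3]); // random filler
}

// [[Rcpp::export]]
List cpp_simulate_batch(IntegerVector insert_sizes, int read_length,
                        std::string adapter1, std::string adapter2,
                        double sub_rate, double ins_rate, double del_rate) {
  int n = insert_sizes.size();
  static const char BASES[4] = { 'A', 'C', 'G', 'T' };
  CharacterVector s1(n), s2(n);
  IntegerVector t1(n), t2(n);
  GetRNGstate();
  for (int i = 0; i < n; ++i) {
    int ins = insert_sizes[i];
    std::string insert((size_t)ins, 'A');
    for (int j = 0; j < ins; ++j)
      insert[(size_t)j] = BASES[(int)(unif_rand() * 4) & 3];
    std::string rcins((size_t)ins, 'A');
    for (int j = 0; j < ins; ++j) {
      int c = nib_comp(base_code(insert[(size_t)(ins - 1 - j)]));
      rcins[(size_t)j] = CODE2CHAR[c];
    }
    std::string tmpl1 = insert + adapter1;
    std::string tmpl2 = rcins + adapter2;
    std::string read; int tp;
    copy_template(tmpl1, ins, read_length, sub_rate, ins_rate, del_rate, read, tp);
    s1[i] = read; t1[i] = tp;
    copy_template(tmpl2, ins, read_length, sub_rate, ins_rate, del_rate, read, tp);
    s2[i] = read; t2[i] = tp;
  }
  PutRNGstate();
  return List::create(_["seq1"] = s1, _["seq2"] = s2,
                      _["true_trim_pos_r1"] = t1, _["true_trim_pos_r2"] = t2);
}
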