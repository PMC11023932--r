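#include <Rcpp.h>
#include <string>
#include <vector>
#include <climits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gap costs, Gotoh
// three-state recursion. Scores are integers so ties are exact and the
// traceback below is fully deterministic:
//   end state and match-state predecessors: M > Y > X on ties
//   within X (gap in reference, read base consumed): extend > from-M > from-Y
//   within Y (gap in read, reference base consumed): extend > from-M > from-X
// A gap of length L costs gap_open + L * gap_extend.  'N' never matches.

static const int NEG = INT_MIN / 4;

static inline int subscore(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

struct Aln {
  int score;
  std::string pat; // gapped read
  std::string sub; // gapped reference
};

static Aln gotoh(const std::string &read, const std::string &ref,
                 int match, int mismatch, int go, int ge) {
  const int n = (int)read.size(), m = (int)ref.size();
  const int W = m + 1;
  static std::vector<int> M, X, Y; // reused across calls
  M.assign((n + 1) * W, NEG); X.assign((n + 1) * W, NEG);
  Y.assign((n + 1) * W, NEG);
  M[0] = 0;
  for (int i = 1; i <= n; ++i) X[i * W] = go + ge * i;
  for (int j = 1; j <= m; ++j) Y[j] = go + ge * j;
  for (int i = 1; i <= n; ++i) {
    const char ri = read[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int d = (i - 1) * W + (j - 1), u = (i - 1) * W + j,
                l = i * W + (j - 1), c = i * W + j;
      int best = M[d];
      if (Y[d] > best) best = Y[d];
      if (X[d] > best) best = X[d];
      M[c] = best + subscore(ri, ref[j - 1], match, mismatch);
      int x = X[u] + ge;
      if (M[u] + go + ge > x) x = M[u] + go + ge;
      if (Y[u] + go + ge > x) x = Y[u] + go + ge;
      X[c] = x;
      int y = Y[l] + ge;
      if (M[l] + go + ge > y) y = M[l] + go + ge;
      if (X[l] + go + ge > y) y = X[l] + go + ge;
      Y[c] = y;
    }
  }
  // traceback
  int i = n, j = m, c = n * W + m;
  char st;
  int sc;
  if (M[c] >= Y[c] && M[c] >= X[c]) { st = 'M'; sc = M[c]; }
  else if (Y[c] >= X[c])            { st = 'Y'; sc = Y[c]; }
  else                              { st = 'X'; sc = X[c]; }
  std::string pat, sub;
  pat.reserve(n + m); sub.reserve(n + m);
  while (i > 0 || j > 0) {
    const int cc = i * W + j;
    if (st == 'M') {
      const int s = subscore(read[i - 1], ref[j - 1], match, mismatch);
      const int d = (i - 1) * W + (j - 1);
      pat.push_back(read[i - 1]); sub.push_back(ref[j - 1]);
      const int want = M[cc] - s;
      if (M[d] == want)      st = 'M';
      else if (Y[d] == want) st = 'Y';
      else                   st = 'X';
      --i; --j;
    } else if (st == 'X') {
      const int u = (i - 1) * W + j;
      pat.push_back(read[i - 1]); sub.push_back('-');
      if (X[u] + ge == X[cc])           st = 'X';
      else if (M[u] + go + ge == X[cc]) st = 'M';
      else                              st = 'Y';
      --i;
    } else { // Y
      const int l = i * W + (j - 1);
      pat.push_back('-'); sub.push_back(ref[j - 1]);
      if (Y[l] + ge == Y[cc])           st = 'Y';
      else if (M[l] + go + ge == Y[cc]) st = 'M';
      else                              st = 'X';
      --j;
    }
  }
  std::reverse(pat.begin(), pat.end());
  std::reverse(sub.begin(), sub.end());
  Aln out; out.score = sc; out.pat = pat; out.sub = sub;
  return out;
}

// fraction of alignment columns where read and reference carry the same
// non-N base; denominator is the full alignment length
static double identity_of(const Aln &a) {
  int match = 0;
  const size_t L = a.pat.size();
  for (size_t k = 0; k < L; ++k) {
    const char p = a.pat[k], s = a.sub[k];
    if (p != '-' && s != '-' && p == s && p != 'N') ++match;
  }
  return L == 0 ? 0.0 : (double)match / (double)L;
}

// does any indel of the alignment touch the half-open window [ws, we) in
// reference coordinates?  deletions [a,b) overlap iff a < we && b > ws;
// insertion runs count iff their left anchor (reference base immediately
// 5' of the run) lies in the window.
static bool window_indel(const Aln &a, int ws, int we) {
  int ref_pos = 0;
  const size_t L = a.pat.size();
  size_t k = 0;
  while (k < L) {
    if (a.sub[k] == '-') {
      const int anchor = ref_pos - 1;
      if (anchor >= ws && anchor < we) return true;
      while (k < L && a.sub[k] == '-') ++k;
    } else if (a.pat[k] == '-') {
      const int s = ref_pos;
      while (k < L && a.pat[k] == '-' && a.sub[k] != '-') { ++ref_pos; ++k; }
      if (s < we && ref_pos > ws) return true;
    } else {
      ++ref_pos; ++k;
    }
  }
  return false;
}

// read base aligned over reference position p (0-based); "-" if deleted
static char base_at(const Aln &a, int p) {
  int ref_pos = 0;
  for (size_t k = 0; k < a.pat.size(); ++k) {
    if (a.sub[k] == '-') continue;
    if (ref_pos == p) return a.pat[k];
    ++ref_pos;
  }
  return '\0';
}

// Substitution-only fast path.  For equal-length sequences whose Hamming
// distance is small enough that converting every mismatch to a match could
// not pay for even the cheapest gapped detour (two gap openings), the
// gap-free diagonal alignment is the unique optimum and the DP can be
// skipped.  Condition: ham * (match - mismatch) < 2 * (-gap_open - gap_ext).
struct Quick { bool ok; int score; double identity; };

static Quick quick_subst(const std::string &rd, const std::string &ref,
                         int match, int mismatch, int go, int ge) {
  Quick q; q.ok = false;
  if (rd.size() != ref.size()) return q;
  const int limit = (2 * (-go - ge)) / (match - mismatch);
  int ham = 0, nmatch = 0;
  const size_t L = rd.size();
  for (size_t k = 0; k < L; ++k) {
    const char a = rd[k], b = ref[k];
    if (a == 'N' || b == 'N' || a != b) {
      if (++ham > limit) return q;
    } else {
      ++nmatch;
    }
  }
  q.ok = true;
  q.score = nmatch * match + ((int)L - nmatch) * mismatch;
  q.identity = L == 0 ? 0.0 : (double)nmatch / (double)L;
  return q;
}

// [[Rcpp::export]]
List cpp_align(std::string read, std::string ref, int match, int mismatch,
               int gap_open, int gap_extend) {
  Aln a = gotoh(read, ref, match, mismatch, gap_open, gap_extend);
  return List::create(_["score"] = a.score, _["pattern"] = a.pat,
                      _["subject"] = a.sub, _["identity"] = identity_of(a));
}

// Batch classification of reads against the reference and expected-edit
// (HDR) alleles.  Class codes: 0 UNALIGNED, 1 HDR_CLEAN, 2 HDR_INDEL,
// 3 REF_INDEL, 4 REF_CLEAN.  Windows are half-open [s, e) on each allele.
// [[Rcpp::export]]
List cpp_classify_batch(CharacterVector reads, std::string ref, std::string hdr,
                        int wr_s, int wr_e, int wh_s, int wh_e,
                        double min_identity, bool tie_ref,
                        int match, int mismatch, int gap_open, int gap_extend) {
  const int n = reads.size();
  IntegerVector cls(n);
  IntegerVector score_ref(n), score_hdr(n);
  NumericVector identity(n);
  const int perfect_ref = match * (int)ref.size();
  const int perfect_hdr = match * (int)hdr.size();
  for (int r = 0; r < n; ++r) {
    const std::string rd = as<std::string>(reads[r]);
    // exact-sequence fast path (the common case for error-free reads)
    if (rd == ref) {
      cls[r] = 4; score_ref[r] = perfect_ref;
      score_hdr[r] = NA_INTEGER; identity[r] = 1.0;
      if (!(ref == hdr)) { } // hdr score not needed for assignment
      if (!tie_ref && rd == hdr) { cls[r] = 1; score_hdr[r] = perfect_hdr; }
      continue;
    }
    if (rd == hdr) {
      cls[r] = 1; score_hdr[r] = perfect_hdr;
      score_ref[r] = NA_INTEGER; identity[r] = 1.0;
      continue;
    }
    // per-allele evaluation: gap-free fast path where provably optimal
    Quick qr = quick_subst(rd, ref, match, mismatch, gap_open, gap_extend);
    Quick qh = quick_subst(rd, hdr, match, mismatch, gap_open, gap_extend);
    Aln ar, ah;
    int sr, sh;
    if (qr.ok) sr = qr.score;
    else { ar = gotoh(rd, ref, match, mismatch, gap_open, gap_extend); sr = ar.score; }
    if (qh.ok) sh = qh.score;
    else { ah = gotoh(rd, hdr, match, mismatch, gap_open, gap_extend); sh = ah.score; }
    score_ref[r] = sr; score_hdr[r] = sh;
    const bool to_hdr = tie_ref ? (sh > sr) : (sh >= sr);
    bool ind;
    if (to_hdr) {
      identity[r] = qh.ok ? qh.identity : identity_of(ah);
      ind = qh.ok ? false : window_indel(ah, wh_s, wh_e);
    } else {
      identity[r] = qr.ok ? qr.identity : identity_of(ar);
      ind = qr.ok ? false : window_indel(ar, wr_s, wr_e);
    }
    if (identity[r] < min_identity) { cls[r] = 0; continue; }
    cls[r] = to_hdr ? (ind ? 2 : 1) : (ind ? 3 : 4);
  }
  return List::create(_["class"] = cls, _["score_ref"] = score_ref,
                      _["score_hdr"] = score_hdr, _["identity"] = identity);
}

// Single-allele batch for off-target quantification.  Status codes:
// 0 unaligned, 1 window-indel, 2 aligned without window indel.  'base'
// is the read base over reference position site_pos ("-" if deleted,
// "" for unaligned or indel reads).
// [[Rcpp::export]]
List cpp_offtarget_batch(CharacterVector reads, std::string ref,
                         int ws, int we, int site_pos, double min_identity,
                         int match, int mismatch, int gap_open, int gap_extend) {
  const int n = reads.size();
  IntegerVector status(n);
  CharacterVector base(n);
  for (int r = 0; r < n; ++r) {
    const std::string rd = as<std::string>(reads[r]);
    if (rd == ref) {
      status[r] = 2;
      base[r] = std::string(1, ref[site_pos]);
      continue;
    }
    Quick q = quick_subst(rd, ref, match, mismatch, gap_open, gap_extend);
    if (q.ok) {
      if (q.identity < min_identity) { status[r] = 0; base[r] = ""; continue; }
      status[r] = 2;
      base[r] = std::string(1, rd[site_pos]);
      continue;
    }
    Aln a = gotoh(rd, ref, match, mismatch, gap_open, gap_extend);
    if (identity_of(a) < min_identity) { status[r] = 0; base[r] = ""; continue; }
    if (window_indel(a, ws, we)) { status[r] = 1; base[r] = ""; continue; }
    status[r] = 2;
    const char b = base_at(a, site_pos);
    base[r] = (b == '\0') ? "" : std::string(1, b);
  }
  return List::create(_["status"] = status, _["base"] = base);
}
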