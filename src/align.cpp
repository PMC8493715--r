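// Smith-Waterman local alignment with linear gap penalty, plus the batched
// segment-assignment loop used by annotate(). Kept in C++ because the
// pipeline aligns every read against every candidate germline segment.
#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

// 'N' never matches anything (including another 'N').
static inline bool base_match(char a, char b) {
  char ua = (a >= 'a') ? (char)(a - 32) : a;
  char ub = (b >= 'a') ? (char)(b - 32) : b;
  if (ua == 'N' || ub == 'N') return false;
  return ua == ub;
}

// Score-only SW, two-row DP. Returns the optimal local score (>= 0).
static int sw_score_one(const std::string& q, const std::string& r,
                        int match, int mismatch, int gap) {
  const int nq = (int)q.size(), nr = (int)r.size();
  std::vector<int> prev(nr + 1, 0), cur(nr + 1, 0);
  int best = 0;
  for (int i = 1; i <= nq; ++i) {
    cur[0] = 0;
    const char qc = q[i - 1];
    for (int j = 1; j <= nr; ++j) {
      int diag = prev[j - 1] + (base_match(qc, r[j - 1]) ? match : mismatch);
      int up   = prev[j] + gap;   // gap in reference (query base consumed)
      int left = cur[j - 1] + gap; // gap in query (reference base consumed)
      int h = diag;
      if (up > h) h = up;
      if (left > h) h = left;
      if (h < 0) h = 0;
      cur[j] = h;
      if (h > best) best = h;
    }
    std::swap(prev, cur);
  }
  return best;
}

struct AlnResult {
  int score = 0;
  int q_start = 0, q_end = 0, r_start = 0, r_end = 0;
  std::string cigar;
};

// Full DP with traceback. Tie-breaking among optimal alignments: smallest
// ref_start, then smallest query_start, then shortest alignment; traceback
// itself prefers diagonal, then gap-in-ref, then gap-in-query moves.
static AlnResult sw_traceback_one(const std::string& q, const std::string& r,
                                  int match, int mismatch, int gap) {
  const int nq = (int)q.size(), nr = (int)r.size();
  std::vector<int> H((size_t)(nq + 1) * (nr + 1), 0);
  auto at = [nr](int i, int j) { return (size_t)i * (nr + 1) + j; };
  int best = 0;
  for (int i = 1; i <= nq; ++i) {
    const char qc = q[i - 1];
    for (int j = 1; j <= nr; ++j) {
      int diag = H[at(i - 1, j - 1)] + (base_match(qc, r[j - 1]) ? match : mismatch);
      int up   = H[at(i - 1, j)] + gap;
      int left = H[at(i, j - 1)] + gap;
      int h = diag;
      if (up > h) h = up;
      if (left > h) h = left;
      if (h < 0) h = 0;
      H[at(i, j)] = h;
      if (h > best) best = h;
    }
  }
  AlnResult out;
  out.score = best;
  if (best == 0) return out; // empty alignment
  bool have = false;
  int b_rs = 0, b_qs = 0, b_len = 0, b_i = 0, b_j = 0;
  std::string b_cig;
  for (int i = 1; i <= nq; ++i) {
    for (int j = 1; j <= nr; ++j) {
      if (H[at(i, j)] != best) continue;
      // traceback from (i, j)
      int ci = i, cj = j, alen = 0;
      std::string ops;
      while (ci > 0 && cj > 0 && H[at(ci, cj)] > 0) {
        int h = H[at(ci, cj)];
        int diag = H[at(ci - 1, cj - 1)] +
                   (base_match(q[ci - 1], r[cj - 1]) ? match : mismatch);
        if (h == diag) { ops.push_back('M'); --ci; --cj; }
        else if (h == H[at(ci - 1, cj)] + gap) { ops.push_back('I'); --ci; }
        else { ops.push_back('D'); --cj; }
        ++alen;
      }
      int rs = cj, qs = ci;
      bool better = false;
      if (!have) better = true;
      else if (rs != b_rs) better = rs < b_rs;
      else if (qs != b_qs) better = qs < b_qs;
      else better = alen < b_len;
      if (better) {
        have = true; b_rs = rs; b_qs = qs; b_len = alen; b_i = i; b_j = j;
        b_cig = ops;
      }
    }
  }
  out.q_start = b_qs; out.q_end = b_i;
  out.r_start = b_rs; out.r_end = b_j;
  // run-length encode the reversed op string
  std::string cig;
  for (int k = (int)b_cig.size() - 1; k >= 0;) {
    char op = b_cig[k];
    int run = 0;
    while (k >= 0 && b_cig[k] == op) { ++run; --k; }
    cig += std::to_string(run); cig.push_back(op);
  }
  out.cigar = cig;
  return out;
}

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string ref,
                  int match, int mismatch, int gap) {
  AlnResult a = sw_traceback_one(query, ref, match, mismatch, gap);
  return List::create(_["score"] = a.score,
                      _["q_start"] = a.q_start, _["q_end"] = a.q_end,
                      _["r_start"] = a.r_start, _["r_end"] = a.r_end,
                      _["cigar"] = a.cigar);
}

// [[Rcpp::export]]
IntegerVector sw_score_multi_cpp(std::string query, CharacterVector refs,
                                 int match, int mismatch, int gap) {
  IntegerVector out(refs.size());
  for (R_xlen_t i = 0; i < refs.size(); ++i)
    out[i] = sw_score_one(query, as<std::string>(refs[i]), match, mismatch, gap);
  return out;
}

// ---- k-mer prescreen -------------------------------------------------------

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0; case 'C': case 'c': return 1;
    case 'G': case 'g': return 2; case 'T': case 't': return 3;
    default: return -1;
  }
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

static void index_add(KmerIndex& idx, const std::string& s, int id, int k) {
  if ((int)s.size() < k) return;
  uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      std::vector<int>& v = idx[key];
      if (v.empty() || v.back() != id) v.push_back(id);
    }
  }
}

static void collect_candidates(const KmerIndex& idx, const std::string& s,
                               int k, int step, std::vector<char>& seen,
                               std::vector<int>& out) {
  if ((int)s.size() < k) return;
  for (size_t i = 0; i + k <= s.size(); i += step) {
    uint64_t key = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int c = base_code(s[i + j]);
      if (c < 0) { ok = false; break; }
      key = (key << 2) | (uint64_t)c;
    }
    if (!ok) continue;
    KmerIndex::const_iterator it = idx.find(key);
    if (it == idx.end()) continue;
    for (size_t t = 0; t < it->second.size(); ++t) {
      int id = it->second[t];
      if (!seen[id]) { seen[id] = 1; out.push_back(id); }
    }
  }
}

// ---- batched assignment ----------------------------------------------------

// For each read: align (optionally both orientations) against every candidate
// reference, report the top score, the tied reference ids in input order, the
// winning strand, and the traceback alignment of the first tied reference.
// kmer = 0 disables the prescreen (all references are candidates).
// [[Rcpp::export]]
List assign_batch_cpp(CharacterVector reads, CharacterVector refs,
                      int match, int mismatch, int gap,
                      int min_score, int kmer, bool both_strands) {
  const int nref = (int)refs.size();
  std::vector<std::string> R(nref);
  for (int i = 0; i < nref; ++i) R[i] = as<std::string>(refs[i]);

  KmerIndex idx;
  int step = 1;
  if (kmer > 0) {
    if (kmer > 31) stop("kmer must be <= 31");
    for (int i = 0; i < nref; ++i) index_add(idx, R[i], i, kmer);
    step = std::max(1, kmer / 2);
  }

  const R_xlen_t n = reads.size();
  IntegerVector score(n), strand(n), qs(n), qe(n), rs(n), re(n);
  CharacterVector cigar(n);
  List ties(n);
  std::vector<char> seen(nref, 0);
  std::vector<int> cand;

  for (R_xlen_t ri = 0; ri < n; ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    std::string rev = both_strands ? revcomp(fwd) : std::string();
    int best = 0, best_strand = 1;
    std::vector<int> best_refs;        // tied ref ids on winning strand
    for (int s = 0; s < (both_strands ? 2 : 1); ++s) {
      const std::string& q = (s == 0) ? fwd : rev;
      cand.clear();
      if (kmer > 0) {
        std::fill(seen.begin(), seen.end(), 0);
        collect_candidates(idx, q, kmer, step, seen, cand);
        std::sort(cand.begin(), cand.end());
      } else {
        cand.resize(nref);
        for (int i = 0; i < nref; ++i) cand[i] = i;
      }
      for (size_t c = 0; c < cand.size(); ++c) {
        int sc = sw_score_one(q, R[cand[c]], match, mismatch, gap);
        if (sc > best) {
          best = sc; best_strand = (s == 0) ? 1 : -1;
          best_refs.assign(1, cand[c]);
        } else if (sc == best && sc > 0) {
          // same score: keep ties only within the strand that first attained
          // the best score (forward preferred since it is scanned first)
          int cur_strand = (s == 0) ? 1 : -1;
          if (cur_strand == best_strand) best_refs.push_back(cand[c]);
        }
      }
    }
    if (best < min_score || best_refs.empty()) {
      score[ri] = best; strand[ri] = 1; ties[ri] = IntegerVector(0);
      qs[ri] = qe[ri] = rs[ri] = re[ri] = NA_INTEGER; cigar[ri] = NA_STRING;
      continue;
    }
    score[ri] = best;
    strand[ri] = best_strand;
    ties[ri] = IntegerVector(best_refs.begin(), best_refs.end()); // 0-based
    const std::string& q = (best_strand == 1) ? fwd : rev;
    AlnResult a = sw_traceback_one(q, R[best_refs[0]], match, mismatch, gap);
    qs[ri] = a.q_start; qe[ri] = a.q_end;
    rs[ri] = a.r_start; re[ri] = a.r_end;
    cigar[ri] = a.cigar;
  }
  return List::create(_["score"] = score, _["strand"] = strand,
                      _["ties"] = ties, _["q_start"] = qs, _["q_end"] = qe,
                      _["r_start"] = rs, _["r_end"] = re, _["cigar"] = cigar);
}

// Map a 0-based reference position onto the query through an alignment.
// Returns -1 when the position falls outside the aligned reference span.
// Positions landing inside a deletion (reference consumed, query not) map to
// the query position at the deletion boundary.
// [[Rcpp::export]]
IntegerVector cigar_map_cpp(CharacterVector cigars, IntegerVector q_start,
                            IntegerVector r_start, IntegerVector r_end,
                            IntegerVector ref_pos) {
  R_xlen_t n = cigars.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (cigars[i] == NA_STRING || IntegerVector::is_na(ref_pos[i]) ||
        IntegerVector::is_na(r_start[i])) { out[i] = -1; continue; }
    int target = ref_pos[i];
    if (target < r_start[i] || target >= r_end[i]) { out[i] = -1; continue; }
    std::string cig = as<std::string>(cigars[i]);
    int qp = q_start[i], rp = r_start[i];
    size_t p = 0;
    bool found = false;
    while (p < cig.size()) {
      int run = 0;
      while (p < cig.size() && isdigit(cig[p])) run = run * 10 + (cig[p++] - '0');
      char op = cig[p++];
      if (op == 'M') {
        if (target < rp + run) { out[i] = qp + (target - rp); found = true; break; }
        qp += run; rp += run;
      } else if (op == 'I') {
        qp += run;
      } else { // 'D'
        if (target < rp + run) { out[i] = qp; found = true; break; }
        rp += run;
      }
    }
    if (!found) out[i] = -1;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    out[i] = revcomp(as<std::string>(x[i]));
  }
  return out;
}
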