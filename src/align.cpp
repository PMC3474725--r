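#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <unordered_map>
#include <limits>

using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP) with a fixed,
// documented traceback tie-break: diagonal (M) > up (X, gap in target)
// > left (Y, gap in query).  A gap of length L costs
// gap_open + (L - 1) * gap_extend (gap_open <= gap_extend <= 0).
//
// Two modes:
//   global      -- Needleman-Wunsch over both sequences end to end
//   semiglobal  -- end gaps free on the TARGET only: the query is aligned
//                  in full, the target contributes a contiguous span.

static const int NEG = std::numeric_limits<int>::min() / 4;

enum State { SM = 0, SX = 1, SY = 2 };

struct AlnResult {
  std::string aq, at;
  int score;
  int matches;
  int columns;
  int t_start; // 0-based, inclusive start of the target span
  int t_end;   // 0-based, exclusive end of the target span
};

// pick max with priority M > X > Y; returns chosen state
static inline int argmax3(int m, int x, int y, int &best) {
  best = m; int s = SM;
  if (x > best) { best = x; s = SX; }
  if (y > best) { best = y; s = SY; }
  return s;
}

// When band > 0, the DP is restricted to |j - (i + off)| <= band
// (query position i expected near target column i + off): the standard
// banded heuristic used after diagonal seeding.  band <= 0 = full DP.
static AlnResult align_core(const std::string &a, const std::string &b,
                            int match, int mismatch, int go, int ge,
                            bool semiglobal, bool want_strings,
                            int off = 0, int band = 0) {
  const int n = (int)a.size(), m = (int)b.size();
  const bool banded = band > 0;
  // rolling score rows
  std::vector<int> Mp(m + 2, NEG), Xp(m + 2, NEG), Yp(m + 2, NEG),
    Mc(m + 2, NEG), Xc(m + 2, NEG), Yc(m + 2, NEG);
  // packed traceback: 2 bits per state (predecessor state), 6 bits per cell
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);

  int jlo0 = 1, jhi0 = m;
  if (banded) {
    jlo0 = std::max(1, off - band);
    jhi0 = std::min(m, off + band);
  }
  Mp[0] = 0; Xp[0] = NEG; Yp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG; Xp[j] = NEG; Yp[j] = NEG;
  }
  for (int j = jlo0; j <= jhi0; ++j) {
    if (semiglobal) { // free leading target gap: start anywhere on target
      Mp[j] = 0;
    } else {
      Yp[j] = go + (j - 1) * ge;
    }
  }
  if (semiglobal && (!banded || off - band <= 0)) Mp[0] = 0;

  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (banded) {
      jlo = std::max(1, i + off - band);
      jhi = std::min(m, i + off + band);
      if (jlo > jhi) break;
      // cells just outside the band must read as unreachable
      Mc[jlo - 1] = NEG; Xc[jlo - 1] = NEG; Yc[jlo - 1] = NEG;
      if (jhi > (i - 1) + off + band) { // not computed in the previous row
        Mp[jhi] = NEG; Xp[jhi] = NEG; Yp[jhi] = NEG;
      }
    }
    if (jlo == 1) {
      Mc[0] = NEG; Yc[0] = NEG;
      Xc[0] = go + (i - 1) * ge;
    }
    uint8_t *tbrow = &tb[(size_t)i * (m + 1)];
    const char ai = a[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      const int s = (ai == b[j - 1] && ai != 'N' && b[j - 1] != 'N') ? match : mismatch;
      int best, st;
      // M: diagonal predecessors
      st = argmax3(Mp[j - 1], Xp[j - 1], Yp[j - 1], best);
      Mc[j] = (best <= NEG / 2) ? NEG : best + s;
      uint8_t packed = (uint8_t)st;
      // X: up predecessors (consume query against gap)
      st = argmax3(Mp[j] + go, Xp[j] + ge, Yp[j] + go, best);
      Xc[j] = (best <= NEG / 2) ? NEG : best;
      packed |= (uint8_t)(st << 2);
      // Y: left predecessors (consume target against gap)
      st = argmax3(Mc[j - 1] + go, Xc[j - 1] + go, Yc[j - 1] + ge, best);
      Yc[j] = (best <= NEG / 2) ? NEG : best;
      packed |= (uint8_t)(st << 4);
      tbrow[j] = packed;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    // keep last row accessible after loop via Mp/Xp/Yp
  }

  // end cell selection
  int end_j = m, state, best;
  if (semiglobal) {
    // free trailing target gap: end at any column of the last row;
    // tie-break: higher score, then state priority, then smallest j
    int jscan_lo = 0, jscan_hi = m;
    if (banded) {
      jscan_lo = std::max(0, n + off - band);
      jscan_hi = std::min(m, n + off + band);
    }
    int bscore = NEG; int bstate = SM; int bj = jscan_lo;
    for (int j = jscan_lo; j <= jscan_hi; ++j) {
      int st = argmax3(Mp[j], Xp[j], Yp[j], best);
      if (best > bscore) { bscore = best; bstate = st; bj = j; }
    }
    end_j = bj; state = bstate; best = bscore;
  } else {
    state = argmax3(Mp[m], Xp[m], Yp[m], best);
  }

  AlnResult res;
  res.score = best;
  res.t_end = end_j;

  // traceback
  std::string aq, at;
  int i = n, j = end_j;
  int matches = 0, columns = 0;
  while (i > 0 || (j > 0 && !semiglobal)) {
    if (i == 0) { // global only: leading target gap
      aq.push_back('-'); at.push_back(b[j - 1]); --j; ++columns; continue;
    }
    if (j == 0) {
      aq.push_back(a[i - 1]); at.push_back('-'); --i; ++columns; continue;
    }
    uint8_t packed = tb[(size_t)i * (m + 1) + j];
    if (state == SM) {
      char qa = a[i - 1], ta = b[j - 1];
      aq.push_back(qa); at.push_back(ta); ++columns;
      if (qa == ta && qa != 'N') ++matches;
      state = packed & 3; --i; --j;
      if (semiglobal && i == 0) break; // start of query reached
    } else if (state == SX) {
      aq.push_back(a[i - 1]); at.push_back('-'); ++columns;
      state = (packed >> 2) & 3; --i;
      if (semiglobal && i == 0) break;
    } else {
      aq.push_back('-'); at.push_back(b[j - 1]); ++columns;
      state = (packed >> 4) & 3; --j;
    }
  }
  res.t_start = j;
  res.matches = matches;
  res.columns = columns;
  if (want_strings) {
    res.aq.assign(aq.rbegin(), aq.rend());
    res.at.assign(at.rbegin(), at.rend());
  }
  return res;
}

// [[Rcpp::export(name = ".cpp_align")]]
List cpp_align(std::string a, std::string b,
               int match, int mismatch, int gap_open, int gap_extend,
               std::string type) {
  bool semi = (type == "semiglobal");
  AlnResult r = align_core(a, b, match, mismatch, gap_open, gap_extend, semi, true);
  return List::create(
    _["aligned_query"] = r.aq,
    _["aligned_target"] = r.at,
    _["score"] = r.score,
    _["matches"] = r.matches,
    _["columns"] = r.columns,
    _["t_start"] = r.t_start + 1, // 1-based inclusive
    _["t_end"] = r.t_end);
}

// Batch semi-global alignment of reads against windows of one reference.
// win_start/win_end are 1-based inclusive window bounds on `ref`;
// `off`/`band` restrict the DP to a diagonal band within the window
// (band <= 0 = full window DP).
// Returns a matrix with columns: score, matches, columns, t_start, t_end
// (t_* 1-based inclusive on the full reference).
// [[Rcpp::export(name = ".cpp_semiglobal_batch")]]
NumericMatrix cpp_semiglobal_batch(CharacterVector reads, std::string ref,
                                   IntegerVector win_start, IntegerVector win_end,
                                   int match, int mismatch,
                                   int gap_open, int gap_extend,
                                   IntegerVector off, IntegerVector band) {
  const int n = reads.size();
  NumericMatrix out(n, 5);
  colnames(out) = CharacterVector::create("score", "matches", "columns",
                                          "t_start", "t_end");
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int ws = win_start[i], we = win_end[i];
    std::string window = ref.substr(ws - 1, we - ws + 1);
    AlnResult r = align_core(rd, window, match, mismatch, gap_open, gap_extend,
                             true, false, off[i], band[i]);
    out(i, 0) = r.score;
    out(i, 1) = r.matches;
    out(i, 2) = r.columns;
    out(i, 3) = ws + r.t_start;       // 1-based on full ref
    out(i, 4) = ws + r.t_end - 1;     // 1-based inclusive
  }
  return out;
}

static inline int base2bits(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; default: return -1; }
}

// k-mer seeding: for each read, vote over diagonals (ref_pos - read_pos,
// 0-based) using exact k-mer hits sampled every `stride` positions along the
// read.  Returns per read the best diagonal (0-based) and its vote count
// (0 votes = no seed hit).
// [[Rcpp::export(name = ".cpp_seed_diagonals")]]
IntegerMatrix cpp_seed_diagonals(CharacterVector reads, std::string ref,
                                 int k, int stride) {
  const int m = (int)ref.size();
  std::unordered_map<uint64_t, std::vector<int> > index;
  index.reserve(m * 2);
  // rolling build of the reference index, skipping k-mers containing N
  {
    uint64_t key = 0; int run = 0;
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (int p = 0; p < m; ++p) {
      int b = base2bits(ref[p]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) index[key].push_back(p - k + 1);
    }
  }
  const int n = reads.size();
  IntegerMatrix out(n, 2);
  colnames(out) = CharacterVector::create("diag", "votes");
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    const int L = (int)rd.size();
    std::unordered_map<int, int> votes;
    for (int p = 0; p + k <= L; p += stride) {
      uint64_t key = 0; bool ok = true;
      for (int q = 0; q < k; ++q) {
        int b = base2bits(rd[p + q]);
        if (b < 0) { ok = false; break; }
        key = (key << 2) | (uint64_t)b;
      }
      if (!ok) continue;
      std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
        index.find(key);
      if (it == index.end()) continue;
      for (size_t h = 0; h < it->second.size(); ++h)
        votes[it->second[h] - p] += 1;
    }
    int bd = NA_INTEGER, bv = 0;
    for (std::unordered_map<int, int>::const_iterator v = votes.begin();
         v != votes.end(); ++v) {
      if (v->second > bv || (v->second == bv && bv > 0 && v->first < bd)) {
        bv = v->second; bd = v->first;
      }
    }
    out(i, 0) = bd; out(i, 1) = bv;
  }
  return out;
}
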