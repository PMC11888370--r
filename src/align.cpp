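// Semi-global (pattern-global, read-local) affine-gap alignment with
// wildcard-neutral scoring, plus per-section span recovery from the
// traceback.  The pattern is the rendered barcode schema: constant bases
// score match/mismatch, 'N' wildcards (building-block tags, UMI) score 0
// against anything so that constant regions anchor the alignment.
//
// Ties are broken toward the leftmost read start, then fewest errors.
// Errors = mismatches at non-wildcard positions + gap bases.

#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

static const double NEG = -1e18;

struct Cell {
  double score;
  int start;    // read index where the alignment begins (0-based)
  int errors;
  char from;    // predecessor state: 'M','X','Y','S' (start), '0' (invalid)
};

static inline bool better(const Cell& a, double sc, int st, int er) {
  // is (sc, st, er) better than a?
  if (sc > a.score + 1e-9) return true;
  if (sc < a.score - 1e-9) return false;
  if (st < a.start) return true;
  if (st > a.start) return false;
  return er < a.errors;
}

// [[Rcpp::export]]
List cpp_semi_global(CharacterVector reads, std::string pattern,
                     double match, double mismatch,
                     double gap_open, double gap_ext,
                     IntegerVector section_start, IntegerVector section_end) {
  const int m = pattern.size();
  const int n_reads = reads.size();
  const int n_sec = section_start.size();

  NumericVector out_score(n_reads);
  IntegerVector out_start(n_reads), out_end(n_reads), out_errors(n_reads);
  CharacterMatrix out_sections(n_reads, n_sec);
  IntegerMatrix out_sec_start(n_reads, n_sec), out_sec_end(n_reads, n_sec);

  for (int r = 0; r < n_reads; ++r) {
    const std::string read = as<std::string>(reads[r]);
    const int n = read.size();

    // DP matrices, (m+1) x (n+1)
    std::vector<Cell> M((m + 1) * (n + 1)), X((m + 1) * (n + 1)), Y((m + 1) * (n + 1));
    auto at = [n](int i, int j) { return i * (n + 1) + j; };
    for (int i = 0; i <= m; ++i) {
      for (int j = 0; j <= n; ++j) {
        M[at(i, j)] = X[at(i, j)] = Y[at(i, j)] = {NEG, 0, 0, '0'};
      }
    }
    // leading pattern deletions (pattern base aligned to gap before any read base)
    for (int i = 1; i <= m; ++i) {
      double sc = gap_open + (i - 1) * gap_ext;
      Y[at(i, 0)] = {sc, 0, i, i == 1 ? 'S' : 'Y'};
    }

    for (int i = 1; i <= m; ++i) {
      const char pc = pattern[i - 1];
      for (int j = 1; j <= n; ++j) {
        const char rc = read[j - 1];
        const bool wild = (pc == 'N');
        const double s = wild ? 0.0 : (pc == rc ? match : mismatch);
        const int e = (wild || pc == rc) ? 0 : 1;

        auto consider = [](Cell& acc, const Cell& pre, double delta, int e_delta, char from) {
          if (pre.from == '0') return;
          if (better(acc, pre.score + delta, pre.start, pre.errors + e_delta)) {
            acc = {pre.score + delta, pre.start, pre.errors + e_delta, from};
          }
        };

        // M: pattern[i-1] aligned to read[j-1]
        Cell bm = {NEG, 0, 0, '0'};
        if (i == 1) bm = {s, j - 1, e, 'S'};  // free leading read overhang
        consider(bm, M[at(i - 1, j - 1)], s, e, 'M');
        consider(bm, X[at(i - 1, j - 1)], s, e, 'X');
        consider(bm, Y[at(i - 1, j - 1)], s, e, 'Y');
        M[at(i, j)] = bm;

        // X: read[j-1] consumed as insertion (gap in pattern), interior only
        Cell bx = {NEG, 0, 0, '0'};
        consider(bx, M[at(i, j - 1)], gap_open, 1, 'M');
        consider(bx, X[at(i, j - 1)], gap_ext, 1, 'X');
        consider(bx, Y[at(i, j - 1)], gap_open, 1, 'Y');
        X[at(i, j)] = bx;

        // Y: pattern[i-1] aligned to gap (deletion from read)
        Cell by = {NEG, 0, 0, '0'};
        if (i == 1) by = {gap_open, j, 1, 'S'};  // leading deletion after skipped read prefix
        consider(by, M[at(i - 1, j)], gap_open, 1, 'M');
        consider(by, X[at(i - 1, j)], gap_open, 1, 'X');
        consider(by, Y[at(i - 1, j)], gap_ext, 1, 'Y');
        Y[at(i, j)] = by;
      }
    }

    // best end: pattern fully aligned (row m), trailing read overhang free
    Cell best = {NEG, 0, 0, '0'};
    int best_j = 0;
    char best_state = 'M';
    for (int j = 0; j <= n; ++j) {
      for (char st : {'M', 'Y'}) {
        const Cell& c = (st == 'M') ? M[at(m, j)] : Y[at(m, j)];
        if (c.from == '0') continue;
        if (c.score > best.score + 1e-9 ||
            (c.score > best.score - 1e-9 && (c.start < best.start ||
             (c.start == best.start && c.errors < best.errors)))) {
          best = c; best_j = j; best_state = st;
        }
      }
    }

    if (best.from == '0') {
      out_score[r] = NA_REAL;
      out_start[r] = out_end[r] = out_errors[r] = NA_INTEGER;
      for (int s = 0; s < n_sec; ++s) out_sections(r, s) = NA_STRING;
      continue;
    }

    // traceback: read interval consumed at each pattern position, and
    // insertion read indices attributed to the preceding pattern position
    std::vector<int> aligned_read(m, -1);           // read idx of pattern pos i (0-based), -1 if deleted
    std::vector<std::vector<int>> insertions(m + 1);  // read idxs inserted after pattern pos i
    {
      int i = m, j = best_j;
      char st = best_state;
      while (!(i == 0 && st == 'S')) {
        const Cell& c = (st == 'M') ? M[at(i, j)] : (st == 'X') ? X[at(i, j)] : Y[at(i, j)];
        if (st == 'M') {
          aligned_read[i - 1] = j - 1;
          char pre = c.from;
          --i; --j;
          if (pre == 'S') break;
          st = pre;
        } else if (st == 'X') {
          insertions[i].push_back(j - 1);
          char pre = c.from;
          --j;
          st = pre;
        } else {  // Y
          char pre = c.from;
          --i;
          if (pre == 'S') break;
          st = pre;
        }
      }
    }

    int read_start = best.start;
    // read_end = 1 + max consumed read index
    int read_end = read_start;
    for (int i = 0; i < m; ++i) if (aligned_read[i] >= 0) read_end = std::max(read_end, aligned_read[i] + 1);
    for (int i = 0; i <= m; ++i) for (int idx : insertions[i]) read_end = std::max(read_end, idx + 1);

    out_score[r] = best.score;
    out_start[r] = read_start;
    out_end[r] = read_end;
    out_errors[r] = best.errors;

    for (int s = 0; s < n_sec; ++s) {
      const int a = section_start[s], b = section_end[s];  // 0-based half-open in pattern
      int lo = -1, hi = -1;
      for (int i = a; i < b; ++i) {
        if (aligned_read[i] >= 0) {
          if (lo < 0 || aligned_read[i] < lo) lo = aligned_read[i];
          if (aligned_read[i] + 1 > hi) hi = aligned_read[i] + 1;
        }
      }
      // interior insertions (strictly inside the section)
      for (int i = a + 1; i < b; ++i) {
        for (int idx : insertions[i]) {
          if (lo < 0 || idx < lo) lo = idx;
          if (idx + 1 > hi) hi = idx + 1;
        }
      }
      if (lo < 0) {  // entire section deleted
        out_sec_start(r, s) = out_sec_end(r, s) = NA_INTEGER;
        out_sections(r, s) = "";
      } else {
        out_sec_start(r, s) = lo;
        out_sec_end(r, s) = hi;
        out_sections(r, s) = read.substr(lo, hi - lo);
      }
    }
  }

  return List::create(
    _["score"] = out_score, _["read_start"] = out_start, _["read_end"] = out_end,
    _["errors"] = out_errors, _["sections"] = out_sections,
    _["section_start"] = out_sec_start, _["section_end"] = out_sec_end);
}
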