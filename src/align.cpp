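#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>

using namespace Rcpp;

// Semi-global alignment of a short read against a longer reference sequence
// with unit-cost Levenshtein edits (mismatch / insertion / deletion).
//
// Returns the single best placement: lowest total edit count, then leftmost
// start, then shortest reference span. NULL when nothing is found within
// max_errors. Edit operations are reported relative to the read:
//   op 1 = mismatch  (read base differs from reference base)
//   op 2 = insertion (read base absent from the reference)
//   op 3 = deletion  (reference base skipped by the read)
// Positions are 1-based read positions (for a deletion, the read position
// after which the skipped reference base falls, possibly 0).
// distance-only prescan: minimal semi-global edit distance via a flat
// column-wise DP, so hopeless candidates are rejected cheaply
static int min_edit_semiglobal(const std::string &read, const std::string &text) {
    const int m = (int) read.size();
    const int n = (int) text.size();
    std::vector<int> col(m + 1), ncol(m + 1);
    for (int i = 0; i <= m; ++i) col[i] = i;
    int dmin = m;
    for (int j = 1; j <= n; ++j) {
        ncol[0] = 0;
        const char tj = text[j - 1];
        for (int i = 1; i <= m; ++i) {
            int d = col[i - 1] + (read[i - 1] == tj ? 0 : 1);
            const int up = ncol[i - 1] + 1;
            const int left = col[i] + 1;
            if (up < d) d = up;
            if (left < d) d = left;
            ncol[i] = d;
        }
        if (ncol[m] < dmin) dmin = ncol[m];
        col.swap(ncol);
    }
    return dmin;
}

// [[Rcpp::export]]
SEXP cpp_align_read(std::string read, std::string text, int max_errors) {
    const int m = (int) read.size();
    const int n = (int) text.size();
    if (m == 0 || n == 0) return R_NilValue;
    if (min_edit_semiglobal(read, text) > max_errors) return R_NilValue;

    // D[i][j]: minimal edits aligning read[0..i) against a text substring
    // ending at j (0-based half-open end). S[i][j]: smallest substring start
    // among alignments achieving D[i][j].
    std::vector< std::vector<int> > D(m + 1, std::vector<int>(n + 1, 0));
    std::vector< std::vector<int> > S(m + 1, std::vector<int>(n + 1, 0));
    for (int j = 0; j <= n; ++j) { D[0][j] = 0; S[0][j] = j; }
    for (int i = 1; i <= m; ++i) { D[i][0] = i; S[i][0] = 0; }

    for (int i = 1; i <= m; ++i) {
        for (int j = 1; j <= n; ++j) {
            const int sub = D[i - 1][j - 1] + (read[i - 1] == text[j - 1] ? 0 : 1);
            const int ins = D[i - 1][j] + 1;
            const int del = D[i][j - 1] + 1;
            int d = sub < ins ? sub : ins;
            if (del < d) d = del;
            int s = INT_MAX;
            if (sub == d && S[i - 1][j - 1] < s) s = S[i - 1][j - 1];
            if (ins == d && S[i - 1][j] < s) s = S[i - 1][j];
            if (del == d && S[i][j - 1] < s) s = S[i][j - 1];
            D[i][j] = d;
            S[i][j] = s;
        }
    }

    int dmin = INT_MAX;
    for (int j = 1; j <= n; ++j) if (D[m][j] < dmin) dmin = D[m][j];
    if (dmin > max_errors) return R_NilValue;

    // leftmost start wins; among equal starts the smallest end (shortest span)
    int best_j = -1, best_s = INT_MAX;
    for (int j = 1; j <= n; ++j) {
        if (D[m][j] == dmin && S[m][j] < best_s) { best_s = S[m][j]; best_j = j; }
    }

    // traceback constrained to predecessors that preserve (D, S)
    std::vector<int> epos, eop;
    std::vector<char> ebase;
    int i = m, j = best_j;
    while (i > 0 || j > best_s) {
        if (i > 0 && j > best_s) {
            const int sub = D[i - 1][j - 1] + (read[i - 1] == text[j - 1] ? 0 : 1);
            if (sub == D[i][j] && S[i - 1][j - 1] == S[i][j]) {
                if (read[i - 1] != text[j - 1]) {
                    epos.push_back(i); eop.push_back(1); ebase.push_back(read[i - 1]);
                }
                --i; --j;
                continue;
            }
        }
        if (i > 0 && D[i - 1][j] + 1 == D[i][j] && S[i - 1][j] == S[i][j]) {
            epos.push_back(i); eop.push_back(2); ebase.push_back(read[i - 1]);
            --i;
            continue;
        }
        epos.push_back(i); eop.push_back(3); ebase.push_back(text[j - 1]);
        --j;
    }

    const int ne = (int) epos.size();
    IntegerVector pos(ne), op(ne);
    CharacterVector base(ne);
    for (int k = 0; k < ne; ++k) {           // reverse into read order
        pos[k] = epos[ne - 1 - k];
        op[k] = eop[ne - 1 - k];
        base[k] = std::string(1, ebase[ne - 1 - k]);
    }

    return List::create(
        _["errors"] = dmin,
        _["offset"] = best_s,      // 0-based start in text
        _["end"] = best_j,         // 0-based half-open end
        _["edit_pos"] = pos,
        _["edit_op"] = op,
        _["edit_base"] = base);
}
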