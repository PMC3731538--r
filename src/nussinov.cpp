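#include <Rcpp.h>
#include <vector>
#include <string>
#include <utility>

using namespace Rcpp;

static inline bool can_pair(char a, char b) {
    // Watson-Crick plus G-U wobble, uppercase RNA alphabet
    return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
           (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
           (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Base-pair maximization over nested secondary structures (Nussinov-style
// interval dynamic program) with a minimum hairpin loop of min_loop
// unpaired nucleotides. Returns a 1-based partner vector (0 = unpaired).
// Traceback is deterministic: at each interval the 5'-most position is
// paired with its lowest admissible partner among optimal structures,
// otherwise left unpaired.
// [[Rcpp::export]]
IntegerVector cpp_nussinov(std::string seq, int min_loop) {
    const int n = (int) seq.size();
    IntegerVector pt(n, 0);
    if (n < min_loop + 2) return pt;

    std::vector< std::vector<short> > N(n, std::vector<short>(n, 0));

    for (int len = min_loop + 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            const int j = i + len - 1;
            short best = N[i + 1][j];  // i unpaired (len >= 2 so i+1 <= j)
            for (int k = i + min_loop + 1; k <= j; ++k) {
                if (!can_pair(seq[i], seq[k])) continue;
                const short left = (k - 1 >= i + 1) ? N[i + 1][k - 1] : (short) 0;
                const short right = (k + 1 <= j) ? N[k + 1][j] : (short) 0;
                const short v = (short) (1 + left + right);
                if (v > best) best = v;
            }
            N[i][j] = best;
        }
    }

    std::vector< std::pair<int, int> > todo;
    todo.push_back(std::make_pair(0, n - 1));
    while (!todo.empty()) {
        const int i = todo.back().first;
        const int j = todo.back().second;
        todo.pop_back();
        if (i >= j || N[i][j] == 0) continue;
        bool paired = false;
        for (int k = i + min_loop + 1; k <= j && !paired; ++k) {
            if (!can_pair(seq[i], seq[k])) continue;
            const short left = (k - 1 >= i + 1) ? N[i + 1][k - 1] : (short) 0;
            const short right = (k + 1 <= j) ? N[k + 1][j] : (short) 0;
            if ((short) (1 + left + right) == N[i][j]) {
                pt[i] = k + 1;
                pt[k] = i + 1;
                if (k - 1 >= i + 1) todo.push_back(std::make_pair(i + 1, k - 1));
                if (k + 1 <= j) todo.push_back(std::make_pair(k + 1, j));
                paired = true;
            }
        }
        if (!paired) todo.push_back(std::make_pair(i + 1, j));
    }
    return pt;
}
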