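#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Semi-global Levenshtein distance: the barcode must be fully consumed,
// the window flanks are free (no cost for unaligned window prefix/suffix).
// dp[i][j] = min edits aligning barcode[1..i] against a suffix of
// window[1..j]; row 0 is all zero (free prefix), the answer is the row-m
// minimum (free suffix).
static int semiglobal_one(const std::string &bc, const std::string &win) {
    const int m = (int) bc.size(), n = (int) win.size();
    std::vector<int> prev(n + 1), cur(n + 1);
    for (int j = 0; j <= n; ++j) prev[j] = 0;
    for (int i = 1; i <= m; ++i) {
        cur[0] = i;
        const char bi = bc[i - 1];
        for (int j = 1; j <= n; ++j) {
            int sub = prev[j - 1] + (bi == win[j - 1] ? 0 : 1);
            int del = prev[j] + 1;   // barcode base unmatched
            int ins = cur[j - 1] + 1; // extra window base inside alignment
            cur[j] = std::min(sub, std::min(del, ins));
        }
        std::swap(prev, cur);
    }
    int best = prev[0];
    for (int j = 1; j <= n; ++j) best = std::min(best, prev[j]);
    return best;
}

// [[Rcpp::export]]
IntegerMatrix semiglobal_distance_matrix(CharacterVector windows,
                                         CharacterVector barcodes) {
    const int nw = windows.size(), nb = barcodes.size();
    std::vector<std::string> bcs(nb);
    for (int b = 0; b < nb; ++b) bcs[b] = as<std::string>(barcodes[b]);
    IntegerMatrix out(nw, nb);
    for (int w = 0; w < nw; ++w) {
        std::string win = as<std::string>(windows[w]);
        for (int b = 0; b < nb; ++b)
            out(w, b) = semiglobal_one(bcs[b], win);
    }
    return out;
}

// Batched best-match calling: for each window report the minimal distance,
// the 1-based index of the unique minimizer (0 if tied), and the number of
// whitelist entries attaining the minimum.
// [[Rcpp::export]]
List semiglobal_best_call(CharacterVector windows, CharacterVector barcodes) {
    const int nw = windows.size(), nb = barcodes.size();
    std::vector<std::string> bcs(nb);
    for (int b = 0; b < nb; ++b) bcs[b] = as<std::string>(barcodes[b]);
    IntegerVector dist(nw), idx(nw), nmin(nw);
    for (int w = 0; w < nw; ++w) {
        std::string win = as<std::string>(windows[w]);
        int best = INT_MAX, bestIdx = 0, ties = 0;
        for (int b = 0; b < nb; ++b) {
            int d = semiglobal_one(bcs[b], win);
            if (d < best) { best = d; bestIdx = b + 1; ties = 1; }
            else if (d == best) ++ties;
        }
        dist[w] = best; idx[w] = (ties == 1) ? bestIdx : 0; nmin[w] = ties;
    }
    return List::create(_["distance"] = dist, _["index"] = idx,
                        _["n_min"] = nmin);
}
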