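#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Nearest-neighbour-chain agglomeration with the UPGMA (unweighted
// average) Lance-Williams update, on a full symmetric distance matrix.
// Average linkage is reducible, so the chain algorithm yields the exact
// UPGMA dendrogram in O(n^2) time. Ties are resolved deterministically:
// the reciprocal chain neighbour wins, otherwise the smallest index.
//
// Returns chronological merges as (rep_lo, rep_hi, height) where rep_*
// are representative leaf indices (0-based) of the two clusters at merge
// time; the merged cluster keeps rep_lo as its representative.
// [[Rcpp::export(name = ".nnChainAverage")]]
List nnChainAverage(NumericMatrix dmat) {
    const int n = dmat.nrow();
    if (n < 2) stop("need at least 2 items");
    std::vector<double> d(dmat.begin(), dmat.end());
    std::vector<char> active(n, 1);
    std::vector<double> csize(n, 1.0);
    std::vector<int> rep(n);
    for (int i = 0; i < n; ++i) rep[i] = i;

    std::vector<int> chain;
    chain.reserve(n);
    NumericVector h(n - 1);
    IntegerVector repLo(n - 1), repHi(n - 1);

    int nActive = n;
    int m = 0;
    while (nActive > 1) {
        if (chain.empty()) {
            for (int i = 0; i < n; ++i)
                if (active[i]) { chain.push_back(i); break; }
        }
        for (;;) {
            int a = chain.back();
            int prev = (chain.size() >= 2) ? chain[chain.size() - 2] : -1;
            int best = -1;
            double bestd = std::numeric_limits<double>::infinity();
            if (prev >= 0) { best = prev; bestd = d[(size_t)a * n + prev]; }
            for (int i = 0; i < n; ++i) {
                if (!active[i] || i == a || i == prev) continue;
                double di = d[(size_t)a * n + i];
                if (di < bestd) { bestd = di; best = i; }
            }
            if (best == prev && prev >= 0) {
                // reciprocal nearest neighbours: merge a and prev
                chain.pop_back();
                chain.pop_back();
                int lo = a < prev ? a : prev;
                int hi = a < prev ? prev : a;
                h[m] = bestd;
                repLo[m] = rep[lo];
                repHi[m] = rep[hi];
                double sl = csize[lo], sh = csize[hi];
                for (int k = 0; k < n; ++k) {
                    if (!active[k] || k == lo || k == hi) continue;
                    double dn = (sl * d[(size_t)lo * n + k] +
                                 sh * d[(size_t)hi * n + k]) / (sl + sh);
                    d[(size_t)lo * n + k] = dn;
                    d[(size_t)k * n + lo] = dn;
                }
                active[hi] = 0;
                csize[lo] = sl + sh;
                ++m;
                --nActive;
                break;
            }
            chain.push_back(best);
        }
    }
    return List::create(_["height"] = h, _["repLo"] = repLo,
                        _["repHi"] = repHi);
}
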