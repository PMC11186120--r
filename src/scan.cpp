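#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Maximal runs of consecutive equal values in the sliding-window product
// list LC, where LC[i] = prod(values[i..i+m-1]) (1-based, i = 1..n-m+1).
//
// Two interchangeable paths:
//   use_products = true  : materialize LC with 64-bit integer products
//                          (values are <= 7, so exact for m <= 22);
//   use_products = false : rolling comparison — LC[i] == LC[i+1] iff
//                          values[i] == values[i+m], since all values are
//                          nonzero. O(n) for any m, nothing materialized.
// Both must yield identical runs on every input; tests assert this.
//
// [[Rcpp::export(name = ".period_runs_cpp")]]
List period_runs_cpp(IntegerVector values, int m, bool use_products = false) {
    int n = values.size();
    int nw = n - m + 1;  // number of windows
    std::vector<int> starts, lens;
    if (m < 1) stop("m must be >= 1");
    if (nw >= 1) {
        if (use_products) {
            if (m > 22) stop("product path supports m <= 22 only");
            std::vector<int64_t> lc(nw);
            for (int i = 0; i < nw; ++i) {
                int64_t p = 1;
                for (int j = 0; j < m; ++j) p *= values[i + j];
                lc[i] = p;
            }
            int run_start = 0;
            for (int i = 1; i <= nw; ++i) {
                if (i == nw || lc[i] != lc[i - 1]) {
                    starts.push_back(run_start + 1);
                    lens.push_back(i - run_start);
                    run_start = i;
                }
            }
        } else {
            int run_start = 0;
            for (int i = 1; i <= nw; ++i) {
                // window i equals window i-1 (0-based) iff the residue
                // leaving equals the residue entering
                if (i == nw || values[i - 1] != values[i - 1 + m]) {
                    starts.push_back(run_start + 1);
                    lens.push_back(i - run_start);
                    run_start = i;
                }
            }
        }
    }
    return List::create(_["start"] = wrap(starts), _["run_length"] = wrap(lens));
}

// Does values[start..end] (1-based, inclusive) contain a 1 (ambiguous base)?
// [[Rcpp::export(name = ".has_ambiguous_cpp")]]
bool has_ambiguous_cpp(IntegerVector values, int start, int end) {
    for (int i = start - 1; i < end; ++i)
        if (values[i] == 1) return true;
    return false;
}
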