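#include <Rcpp.h>
using namespace Rcpp;

// Substitution cost with the wildcard rule: 'N' mismatches everything,
// including another 'N'.
static inline int subCost(char a, char b) {
    if (a == 'N' || b == 'N') return 1;
    return a == b ? 0 : 1;
}

//' Semi-global approximate scan of a seed against a text
//'
//' Computes, for every end position in the text, the minimum edit distance
//' (substitutions and indels each cost 1) of an alignment that consumes the
//' whole seed with free ends on the text, together with the leftmost start
//' position achieving that minimum. Positions are 1-based inclusive.
//'
//' @noRd
// [[Rcpp::export]]
DataFrame cpp_semiglobal_scan(std::string text, std::string seed, int budget) {
    const int n = text.size(), m = seed.size();
    std::vector<int> prev(m + 1), cur(m + 1);   // cost columns
    std::vector<int> oprev(m + 1), ocur(m + 1); // origin (start) columns

    std::vector<int> hs, he, hd;

    // column j = 0: seed aligned against empty text prefix
    for (int i = 0; i <= m; ++i) { prev[i] = i; oprev[i] = 1; }

    for (int j = 1; j <= n; ++j) {
        cur[0] = 0;
        ocur[0] = j + 1; // an alignment starting just after position j
        const char tj = text[j - 1];
        for (int i = 1; i <= m; ++i) {
            const int diag = prev[i - 1] + subCost(seed[i - 1], tj);
            const int up   = cur[i - 1] + 1;  // seed char against gap
            const int left = prev[i] + 1;     // text char against gap
            int best = diag, orig = oprev[i - 1];
            if (up < best) { best = up; orig = ocur[i - 1]; }
            else if (up == best && ocur[i - 1] < orig) orig = ocur[i - 1];
            if (left < best) { best = left; orig = oprev[i]; }
            else if (left == best && oprev[i] < orig) orig = oprev[i];
            cur[i] = best;
            ocur[i] = orig;
        }
        if (cur[m] <= budget) {
            int start = ocur[m];
            if (start < 1) start = 1;
            if (start <= j) { // require a non-empty genomic span
                hs.push_back(start);
                he.push_back(j);
                hd.push_back(cur[m]);
            }
        }
        std::swap(prev, cur);
        std::swap(oprev, ocur);
    }

    return DataFrame::create(_["start"] = hs, _["end"] = he, _["dist"] = hd);
}

//' Elementwise Levenshtein distance with the N-wildcard rule
//'
//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_lev(CharacterVector a, CharacterVector b) {
    const R_xlen_t n = a.size();
    if (b.size() != n) stop("a and b must have equal length");
    IntegerVector out(n);
    for (R_xlen_t k = 0; k < n; ++k) {
        if (a[k] == NA_STRING || b[k] == NA_STRING) { out[k] = NA_INTEGER; continue; }
        std::string x = as<std::string>(a[k]);
        std::string y = as<std::string>(b[k]);
        const int nx = x.size(), ny = y.size();
        std::vector<int> prev(ny + 1), cur(ny + 1);
        for (int j = 0; j <= ny; ++j) prev[j] = j;
        for (int i = 1; i <= nx; ++i) {
            cur[0] = i;
            for (int j = 1; j <= ny; ++j) {
                const int diag = prev[j - 1] + subCost(x[i - 1], y[j - 1]);
                const int del  = prev[j] + 1;
                const int ins  = cur[j - 1] + 1;
                cur[j] = std::min(diag, std::min(del, ins));
            }
            std::swap(prev, cur);
        }
        out[k] = prev[ny];
    }
    return out;
}
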