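#include <Rcpp.h>
#include <algorithm>
#include <functional>
#include <string>
#include <vector>
using namespace Rcpp;

// Global Needleman-Wunsch with a linear gap penalty.
// Traceback prefers diagonal moves on ties so aligned (non-gap) pairs are
// maximised among equal-score alignments, then the "up" move (gap in b).
static List nw_core(int n, int m,
                    const std::function<double(int, int)> &score,
                    double gap) {
    NumericMatrix F(n + 1, m + 1);
    IntegerMatrix ptr(n + 1, m + 1);  // 0 diag, 1 up, 2 left

    for (int i = 1; i <= n; ++i) { F(i, 0) = i * gap; ptr(i, 0) = 1; }
    for (int j = 1; j <= m; ++j) { F(0, j) = j * gap; ptr(0, j) = 2; }

    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double d = F(i - 1, j - 1) + score(i - 1, j - 1);
            double u = F(i - 1, j) + gap;
            double l = F(i, j - 1) + gap;
            double best = d; int p = 0;
            if (u > best) { best = u; p = 1; }
            if (l > best) { best = l; p = 2; }
            F(i, j) = best; ptr(i, j) = p;
        }
    }

    std::vector<int> ai, bi;
    int i = n, j = m;
    while (i > 0 || j > 0) {
        int p = ptr(i, j);
        if (i > 0 && j > 0 && p == 0) {
            ai.push_back(i); bi.push_back(j);
            --i; --j;
        } else if (i > 0 && (p == 1 || j == 0)) {
            --i;
        } else {
            --j;
        }
    }
    std::reverse(ai.begin(), ai.end());
    std::reverse(bi.begin(), bi.end());

    return List::create(_["score"] = F(n, m),
                        _["ai"] = wrap(ai),
                        _["bi"] = wrap(bi));
}

// [[Rcpp::export]]
List cpp_nw_seq(std::string a, std::string b,
                double match, double mismatch, double gap) {
    int n = (int) a.size(), m = (int) b.size();
    List res = nw_core(n, m, [&](int i, int j) {
        return a[i] == b[j] ? match : mismatch;
    }, gap);
    IntegerVector ai = res["ai"], bi = res["bi"];
    int nmatch = 0;
    for (int k = 0; k < ai.size(); ++k)
        if (a[ai[k] - 1] == b[bi[k] - 1]) ++nmatch;
    res["nmatch"] = nmatch;
    return res;
}

// [[Rcpp::export]]
List cpp_nw_matrix(NumericMatrix S, double gap) {
    return nw_core(S.nrow(), S.ncol(), [&](int i, int j) {
        return S(i, j);
    }, gap);
}
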