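#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>

using namespace Rcpp;

// Global pairwise alignment with affine gap penalties (Gotoh, 1982).
// A gap of length k costs gap_open + (k - 1) * gap_extend, so
// align("ACGT","ACGT") with match = 2 scores 8.
//
// Traceback is fully deterministic: on score ties the diagonal move is
// preferred over a gap in the second sequence ("up", consuming seq_a),
// which in turn beats a gap in the first sequence ("left").

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// state codes: 0 = M (diagonal), 1 = X (gap in b, consumes a), 2 = Y (gap in a)
// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b,
                 double match, double mismatch,
                 double gap_open, double gap_extend) {
    const int n = a.size(), m = b.size();
    const int w = m + 1;

    std::vector<double> M((n + 1) * w, NEG_INF);
    std::vector<double> X((n + 1) * w, NEG_INF);
    std::vector<double> Y((n + 1) * w, NEG_INF);
    // traceback: which predecessor state fed each cell's state
    std::vector<signed char> tbM((n + 1) * w, -1);
    std::vector<signed char> tbX((n + 1) * w, -1);
    std::vector<signed char> tbY((n + 1) * w, -1);

    M[0] = 0.0;
    for (int i = 1; i <= n; ++i) {
        X[i * w] = gap_open + (i - 1) * gap_extend;
        tbX[i * w] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= m; ++j) {
        Y[j] = gap_open + (j - 1) * gap_extend;
        tbY[j] = (j == 1) ? 0 : 2;
    }

    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            const int c = i * w + j, d = (i - 1) * w + (j - 1);
            const int u = (i - 1) * w + j, l = i * w + (j - 1);

            // M: substitution; predecessor preference M > X > Y on ties
            double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
            double best = M[d]; signed char from = 0;
            if (X[d] > best) { best = X[d]; from = 1; }
            if (Y[d] > best) { best = Y[d]; from = 2; }
            M[c] = best + s; tbM[c] = from;

            // X: gap in b (vertical)
            best = M[u] + gap_open; from = 0;
            if (X[u] + gap_extend > best) { best = X[u] + gap_extend; from = 1; }
            if (Y[u] + gap_open > best)   { best = Y[u] + gap_open;   from = 2; }
            X[c] = best; tbX[c] = from;

            // Y: gap in a (horizontal)
            best = M[l] + gap_open; from = 0;
            if (X[l] + gap_open > best)   { best = X[l] + gap_open;   from = 1; }
            if (Y[l] + gap_extend > best) { best = Y[l] + gap_extend; from = 2; }
            Y[c] = best; tbY[c] = from;
        }
    }

    const int end = n * w + m;
    double score = M[end]; int state = 0;
    if (X[end] > score) { score = X[end]; state = 1; }
    if (Y[end] > score) { score = Y[end]; state = 2; }

    std::string ga, gb;
    ga.reserve(n + m); gb.reserve(n + m);
    int i = n, j = m;
    while (i > 0 || j > 0) {
        const int c = i * w + j;
        if (state == 0) {
            signed char from = tbM[c];
            ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
            --i; --j; state = from;
        } else if (state == 1) {
            signed char from = tbX[c];
            ga.push_back(a[i - 1]); gb.push_back('-');
            --i; state = from;
        } else {
            signed char from = tbY[c];
            ga.push_back('-'); gb.push_back(b[j - 1]);
            --j; state = from;
        }
    }
    std::reverse(ga.begin(), ga.end());
    std::reverse(gb.begin(), gb.end());

    return List::create(_["aligned_a"] = ga, _["aligned_b"] = gb,
                        _["score"] = score);
}
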