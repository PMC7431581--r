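#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Template-match pair counts for Sample Entropy, all embedding dimensions
// m = 1..max_m in a single O(N^2) pass.
//
// For every pair of start indices i < j (1-based, j = i + d), the run length
// L(i) of consecutive sample matches |x(i+k) - x(j+k)| <= r starting at
// (i, j) determines every template match the pair participates in: the pair
// is an m-template match iff L(i) >= m, and the index restriction
// i, j <= N - m (self-matches excluded, normalisation over N - m templates)
// translates to m <= N - d - i.  Histogramming
// K_B(i) = min(L(i), N - d - i, max_m) over all pairs and suffix-summing
// yields B_m for all m at once; K_A(i) = min(L(i) - 1, N - d - i, max_m)
// likewise yields the (m+1)-sample match counts A_m over the same i, j
// ranges.  Counts are unordered pair counts; the -ln(A/B) statistic is
// invariant to the common normalisation so it is left to the caller.
static void pair_counts(const double* x, int N, int max_m, double r,
                        std::vector<double>& B, std::vector<double>& A) {
    std::vector<double> histB(max_m + 1, 0.0), histA(max_m + 1, 0.0);
    for (int d = 1; d <= N - 1; ++d) {
        const int len = N - d;  // start positions 0 .. len-1 (0-based)
        int run = 0;
        for (int i = len - 1; i >= 0; --i) {
            run = (std::fabs(x[i] - x[i + d]) <= r) ? run + 1 : 0;
            const int bound = len - 1 - i;  // = N - d - i_1based
            int kb = std::min(std::min(run, bound), max_m);
            if (kb >= 1) histB[kb] += 1.0;
            int ka = std::min(std::min(run - 1, bound), max_m);
            if (ka >= 1) histA[ka] += 1.0;
        }
    }
    B.assign(max_m + 1, 0.0);
    A.assign(max_m + 1, 0.0);
    double accB = 0.0, accA = 0.0;
    for (int m = max_m; m >= 1; --m) {
        accB += histB[m];
        accA += histA[m];
        B[m] = accB;
        A[m] = accA;
    }
}

// Same as pair_counts but for several tolerances in one pass over the
// diagonals: the |x(i) - x(j)| differences are the dominant memory
// traffic and are shared across tolerances.
static void pair_counts_multi(const double* x, int N, int max_m,
                              const double* r, int n_r,
                              std::vector<double>& B,
                              std::vector<double>& A) {
    std::vector<double> histB(n_r * (max_m + 1), 0.0);
    std::vector<double> histA(n_r * (max_m + 1), 0.0);
    std::vector<int> run(n_r);
    for (int d = 1; d <= N - 1; ++d) {
        const int len = N - d;
        std::fill(run.begin(), run.end(), 0);
        for (int i = len - 1; i >= 0; --i) {
            const double diff = std::fabs(x[i] - x[i + d]);
            const int bound = std::min(len - 1 - i, max_m);
            for (int q = 0; q < n_r; ++q) {
                int rn = (diff <= r[q]) ? run[q] + 1 : 0;
                run[q] = rn;
                int kb = rn < bound ? rn : bound;
                if (kb >= 1) histB[q * (max_m + 1) + kb] += 1.0;
                int ka = rn - 1 < bound ? rn - 1 : bound;
                if (ka >= 1) histA[q * (max_m + 1) + ka] += 1.0;
            }
        }
    }
    B.assign(n_r * (max_m + 1), 0.0);
    A.assign(n_r * (max_m + 1), 0.0);
    for (int q = 0; q < n_r; ++q) {
        double accB = 0.0, accA = 0.0;
        for (int m = max_m; m >= 1; --m) {
            accB += histB[q * (max_m + 1) + m];
            accA += histA[q * (max_m + 1) + m];
            B[q * (max_m + 1) + m] = accB;
            A[q * (max_m + 1) + m] = accA;
        }
    }
}

// [[Rcpp::export(name = ".sampen_counts")]]
NumericMatrix sampen_counts(NumericVector x, int max_m, double r) {
    const int N = x.size();
    if (max_m < 1) stop("max_m must be >= 1");
    if (N < max_m + 2) stop("series too short for requested max_m");
    std::vector<double> B, A;
    pair_counts(REAL(x), N, max_m, r, B, A);
    NumericMatrix out(2, max_m);
    for (int m = 1; m <= max_m; ++m) {
        out(0, m - 1) = B[m];
        out(1, m - 1) = A[m];
    }
    return out;
}

// Sliding-window Sample Entropy for every (m, r_factor) setting.
// Tolerance is r_factor * SD(window) (sample SD, n-1 denominator).
// Returns an array dim = c(max_m, n_r, n_windows); NA_real_ where the
// window SD is zero or no template matches exist (B = 0 or A = 0).
// [[Rcpp::export(name = ".se_sliding_kernel")]]
NumericVector se_sliding_kernel(NumericVector x, IntegerVector starts,
                                int win_len, int max_m,
                                NumericVector r_factors) {
    const int n_win = starts.size();
    const int n_r = r_factors.size();
    if (win_len < max_m + 3) stop("window shorter than max_m + 3 samples");
    NumericVector out(Dimension(max_m, n_r, n_win));
    std::fill(out.begin(), out.end(), NA_REAL);
    const double* xs = REAL(x);
    std::vector<double> B, A;
    for (int w = 0; w < n_win; ++w) {
        const int s0 = starts[w] - 1;  // 1-based from R
        if (s0 < 0 || s0 + win_len > x.size()) stop("window out of range");
        const double* xw = xs + s0;
        double mean = 0.0;
        for (int i = 0; i < win_len; ++i) mean += xw[i];
        mean /= win_len;
        double ss = 0.0;
        for (int i = 0; i < win_len; ++i) {
            const double dlt = xw[i] - mean;
            ss += dlt * dlt;
        }
        const double sd = std::sqrt(ss / (win_len - 1));
        if (!(sd > 0.0) || !std::isfinite(sd)) continue;  // all NA
        std::vector<double> r_abs(n_r);
        for (int ri = 0; ri < n_r; ++ri) r_abs[ri] = r_factors[ri] * sd;
        pair_counts_multi(xw, win_len, max_m, r_abs.data(), n_r, B, A);
        for (int ri = 0; ri < n_r; ++ri) {
            for (int m = 1; m <= max_m; ++m) {
                const double b = B[ri * (max_m + 1) + m];
                const double a = A[ri * (max_m + 1) + m];
                if (b > 0.0 && a > 0.0)
                    out[m - 1 + max_m * (ri + (R_xlen_t)n_r * w)] =
                        -std::log(a / b);
            }
        }
    }
    return out;
}
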