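#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double lse(const std::vector<double>& v) {
    double m = v[0];
    for (size_t i = 1; i < v.size(); ++i) if (v[i] > m) m = v[i];
    if (!std::isfinite(m)) return m;
    double s = 0.0;
    for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
    return m + std::log(s);
}

// Forward-backward in log space over one or more contiguous segments.
// The forward recursion restarts (from the initial distribution) at each
// segment boundary so that no transition is scored across a recording gap.
//
// logdens: T x K per-hour per-state Gaussian log-densities
// logA:    K x K log transition matrix
// logpi:   K log initial distribution
// seg:     length-T integer segment labels (contiguous runs)
//
// Returns total log-likelihood (sum over segments), the T x K posterior
// (gamma), the K x K matrix of expected transition counts (xi summed over
// within-segment steps), and the summed posterior at segment starts.
// [[Rcpp::export]]
List hmm_fb_cpp(NumericMatrix logdens, NumericMatrix logA,
                NumericVector logpi, IntegerVector seg) {
    const int T = logdens.nrow(), K = logdens.ncol();
    NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
    NumericMatrix xi(K, K);
    NumericVector gstart(K);
    double total_ll = 0.0;

    std::vector<int> starts;
    for (int t = 0; t < T; ++t)
        if (t == 0 || seg[t] != seg[t - 1]) starts.push_back(t);
    starts.push_back(T);

    std::vector<double> buf(K);
    for (size_t s = 0; s + 1 < starts.size(); ++s) {
        const int a = starts[s], b = starts[s + 1] - 1;  // inclusive range
        // forward
        for (int k = 0; k < K; ++k) alpha(a, k) = logpi[k] + logdens(a, k);
        for (int t = a + 1; t <= b; ++t) {
            for (int j = 0; j < K; ++j) {
                for (int i = 0; i < K; ++i) buf[i] = alpha(t - 1, i) + logA(i, j);
                alpha(t, j) = lse(buf) + logdens(t, j);
            }
        }
        for (int k = 0; k < K; ++k) buf[k] = alpha(b, k);
        const double ll = lse(buf);
        total_ll += ll;
        // backward
        for (int k = 0; k < K; ++k) beta(b, k) = 0.0;
        for (int t = b - 1; t >= a; --t) {
            for (int i = 0; i < K; ++i) {
                for (int j = 0; j < K; ++j)
                    buf[j] = logA(i, j) + logdens(t + 1, j) + beta(t + 1, j);
                beta(t, i) = lse(buf);
            }
        }
        // posteriors and expected transition counts
        for (int t = a; t <= b; ++t)
            for (int k = 0; k < K; ++k)
                gamma(t, k) = std::exp(alpha(t, k) + beta(t, k) - ll);
        for (int t = a; t < b; ++t)
            for (int i = 0; i < K; ++i)
                for (int j = 0; j < K; ++j)
                    xi(i, j) += std::exp(alpha(t, i) + logA(i, j) +
                                         logdens(t + 1, j) + beta(t + 1, j) - ll);
        for (int k = 0; k < K; ++k) gstart[k] += gamma(a, k);
    }

    return List::create(_["log_likelihood"] = total_ll,
                        _["gamma"] = gamma,
                        _["xi_sum"] = xi,
                        _["gamma_start"] = gstart);
}

// Viterbi decoding per segment; returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericMatrix logdens, NumericMatrix logA,
                              NumericVector logpi, IntegerVector seg) {
    const int T = logdens.nrow(), K = logdens.ncol();
    IntegerVector path(T);
    std::vector<int> starts;
    for (int t = 0; t < T; ++t)
        if (t == 0 || seg[t] != seg[t - 1]) starts.push_back(t);
    starts.push_back(T);

    NumericMatrix delta(T, K);
    IntegerMatrix psi(T, K);
    for (size_t s = 0; s + 1 < starts.size(); ++s) {
        const int a = starts[s], b = starts[s + 1] - 1;
        for (int k = 0; k < K; ++k) delta(a, k) = logpi[k] + logdens(a, k);
        for (int t = a + 1; t <= b; ++t) {
            for (int j = 0; j < K; ++j) {
                double best = delta(t - 1, 0) + logA(0, j);
                int arg = 0;
                for (int i = 1; i < K; ++i) {
                    const double v = delta(t - 1, i) + logA(i, j);
                    if (v > best) { best = v; arg = i; }
                }
                delta(t, j) = best + logdens(t, j);
                psi(t, j) = arg;
            }
        }
        double best = delta(b, 0);
        int arg = 0;
        for (int k = 1; k < K; ++k)
            if (delta(b, k) > best) { best = delta(b, k); arg = k; }
        path[b] = arg + 1;
        for (int t = b; t > a; --t) {
            arg = psi(t, arg);
            path[t - 1] = arg + 1;
        }
    }
    return path;
}
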