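#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// log(sum(exp(x))) guarded against all -Inf
static inline double logsumexp(const double *x, int n) {
    double m = R_NegInf;
    for (int i = 0; i < n; ++i)
        if (x[i] > m) m = x[i];
    if (m == R_NegInf) return R_NegInf;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += std::exp(x[i] - m);
    return m + std::log(s);
}

// Forward recursion in log space. log_emis is T x N (log L_j(t)).
// [[Rcpp::export(name = ".cpp_forward")]]
List cpp_forward(NumericVector log_init, NumericMatrix log_trans,
                 NumericMatrix log_emis) {
    const int T = log_emis.nrow(), N = log_emis.ncol();
    NumericMatrix la(T, N);
    std::vector<double> buf(N);
    for (int j = 0; j < N; ++j) la(0, j) = log_init[j] + log_emis(0, j);
    for (int t = 1; t < T; ++t) {
        for (int j = 0; j < N; ++j) {
            for (int i = 0; i < N; ++i)
                buf[i] = la(t - 1, i) + log_trans(i, j);
            la(t, j) = logsumexp(buf.data(), N) + log_emis(t, j);
        }
    }
    for (int i = 0; i < N; ++i) buf[i] = la(T - 1, i);
    const double ll = logsumexp(buf.data(), N);
    return List::create(_["log_alpha"] = la, _["log_likelihood"] = ll);
}

// Backward recursion in log space; beta_{T-1} = 1.
// [[Rcpp::export(name = ".cpp_backward")]]
NumericMatrix cpp_backward(NumericMatrix log_trans, NumericMatrix log_emis) {
    const int T = log_emis.nrow(), N = log_emis.ncol();
    NumericMatrix lb(T, N);
    std::vector<double> buf(N);
    for (int j = 0; j < N; ++j) lb(T - 1, j) = 0.0;
    for (int t = T - 2; t >= 0; --t) {
        for (int i = 0; i < N; ++i) {
            for (int j = 0; j < N; ++j)
                buf[j] = log_trans(i, j) + log_emis(t + 1, j) + lb(t + 1, j);
            lb(t, i) = logsumexp(buf.data(), N);
        }
    }
    return lb;
}

// Viterbi: ties broken toward the smallest state index (strict >).
// psi and path are 0-based.
// [[Rcpp::export(name = ".cpp_viterbi")]]
List cpp_viterbi(NumericVector log_init, NumericMatrix log_trans,
                 NumericMatrix log_emis) {
    const int T = log_emis.nrow(), N = log_emis.ncol();
    NumericMatrix ld(T, N);
    IntegerMatrix psi(T, N);
    for (int j = 0; j < N; ++j) {
        ld(0, j) = log_init[j] + log_emis(0, j);
        psi(0, j) = 0;
    }
    for (int t = 1; t < T; ++t) {
        for (int j = 0; j < N; ++j) {
            double best = R_NegInf;
            int arg = 0;
            for (int i = 0; i < N; ++i) {
                const double v = ld(t - 1, i) + log_trans(i, j);
                if (v > best) { best = v; arg = i; }
            }
            ld(t, j) = best + log_emis(t, j);
            psi(t, j) = arg;
        }
    }
    double best = R_NegInf;
    int arg = 0;
    for (int i = 0; i < N; ++i)
        if (ld(T - 1, i) > best) { best = ld(T - 1, i); arg = i; }
    IntegerVector path(T);
    path[T - 1] = arg;
    for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
    return List::create(
        _["log_delta"] = ld, _["psi"] = psi,
        _["log_best"] = best, _["path"] = path);
}

// Pairwise state posteriors xi_t(i,j) (t = 0..T-2) and state posteriors
// gamma_t(i) = alpha_t(i) beta_t(i) / p(y|lambda), all t.
// [[Rcpp::export(name = ".cpp_xi_gamma")]]
List cpp_xi_gamma(NumericMatrix log_trans, NumericMatrix log_emis,
                  NumericMatrix la, NumericMatrix lb, double ll) {
    const int T = log_emis.nrow(), N = log_emis.ncol();
    NumericMatrix gamma(T, N);
    for (int t = 0; t < T; ++t)
        for (int i = 0; i < N; ++i)
            gamma(t, i) = std::exp(la(t, i) + lb(t, i) - ll);
    NumericVector xi(std::max(T - 1, 0) * N * N);
    xi.attr("dim") = IntegerVector::create(std::max(T - 1, 0), N, N);
    for (int t = 0; t < T - 1; ++t) {
        for (int j = 0; j < N; ++j) {
            const double ej = log_emis(t + 1, j) + lb(t + 1, j);
            for (int i = 0; i < N; ++i) {
                xi[t + (T - 1) * (i + N * j)] =
                    std::exp(la(t, i) + log_trans(i, j) + ej - ll);
            }
        }
    }
    return List::create(_["xi"] = xi, _["gamma"] = gamma);
}

// Sample a state path of length T from cumulative transition rows and a
// cumulative initial distribution, using R's RNG (seed-reproducible).
// [[Rcpp::export(name = ".cpp_sample_path")]]
IntegerVector cpp_sample_path(NumericVector cum_init,
                              NumericMatrix cum_trans, int T) {
    const int N = cum_init.size();
    IntegerVector path(T);
    RNGScope scope;
    double u = unif_rand();
    int s = 0;
    while (s < N - 1 && u > cum_init[s]) ++s;
    path[0] = s;
    for (int t = 1; t < T; ++t) {
        u = unif_rand();
        int j = 0;
        while (j < N - 1 && u > cum_trans(s, j)) ++j;
        s = j;
        path[t] = s;
    }
    return path;
}
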