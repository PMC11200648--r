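#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Kernel PLS1 with covariance-vector deflation (Dayal & MacGregor).
// Identical to NIPALS with X deflation for a single response; see the
// R-level documentation of plsFit(). Centering is folded into the
// products so X is never copied.
// [[Rcpp::export(name = ".plsKernelCpp")]]
List plsKernel(const arma::mat& X, const arma::vec& y, int A) {
    const int n = X.n_rows, p = X.n_cols;
    int Amax = std::min(A, std::min(n - 1, p));
    if (Amax < 0) Amax = 0;

    arma::rowvec xm = arma::mean(X, 0);
    double ym = arma::mean(y);
    arma::vec yc = y - ym;
    double ssx = arma::accu(arma::square(X)) - n * arma::accu(arma::square(xm));
    double tolr = 1e-12 * std::max(1.0, ssx);

    arma::mat W(p, std::max(Amax, 1), arma::fill::zeros);
    arma::mat P(p, std::max(Amax, 1), arma::fill::zeros);
    arma::mat R(p, std::max(Amax, 1), arma::fill::zeros);
    arma::mat T(n, std::max(Amax, 1), arma::fill::zeros);
    arma::vec q(std::max(Amax, 1), arma::fill::zeros);

    arma::vec s = X.t() * yc;   // = Xc'yc since yc sums to zero
    int a = 0;
    for (int k = 0; k < Amax; ++k) {
        double wn2 = arma::dot(s, s);
        if (wn2 <= tolr * 1e-6 || wn2 == 0.0) break;
        arma::vec w = s / std::sqrt(wn2);
        arma::vec r = w;
        if (k > 0)
            r -= R.cols(0, k - 1) * (P.cols(0, k - 1).t() * w);
        arma::vec t = X * r;
        t -= arma::dot(xm, r);
        double tss = arma::dot(t, t);
        if (tss <= tolr) break;
        arma::vec pv = (X.t() * t - xm.t() * arma::accu(t)) / tss;
        double qk = arma::dot(yc, t) / tss;
        s -= pv * (qk * tss);
        W.col(k) = w; P.col(k) = pv; R.col(k) = r; T.col(k) = t;
        q(k) = qk;
        a = k + 1;
    }

    arma::mat cp(p, std::max(a, 1), arma::fill::zeros);
    arma::vec acc(p, arma::fill::zeros);
    for (int k = 0; k < a; ++k) {
        acc += R.col(k) * q(k);
        cp.col(k) = acc;
    }

    if (a == 0) {
        return List::create(
            _["W"] = arma::mat(p, 0), _["R"] = arma::mat(p, 0),
            _["Tm"] = arma::mat(n, 0), _["P"] = arma::mat(p, 0),
            _["q"] = NumericVector(0), _["coefPath"] = cp,
            _["xm"] = NumericVector(xm.begin(), xm.end()),
            _["ym"] = ym, _["a"] = 0, _["requested"] = Amax);
    }
    return List::create(
        _["W"] = W.head_cols(a), _["R"] = R.head_cols(a),
        _["Tm"] = T.head_cols(a), _["P"] = P.head_cols(a),
        _["q"] = NumericVector(q.begin(), q.begin() + a),
        _["coefPath"] = cp,
        _["xm"] = NumericVector(xm.begin(), xm.end()),
        _["ym"] = ym, _["a"] = a, _["requested"] = Amax);
}
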