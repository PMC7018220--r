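#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Sum over sites of the projected multivariate-normal log-density with
// per-site covariance epsv_i * (A0 + sum_k cf(i,k) * M_k), all matrices
// given in projected (K-1)-dimensional form, flattened column-major.
// [[Rcpp::export(name = ".compositeLoglikCpp")]]
double compositeLoglikCpp(const arma::vec& a0, const arma::mat& matsP,
                          const arma::mat& cf, const arma::mat& z0,
                          const arma::vec& epsv) {
    const int km1 = z0.n_rows;
    const int n = z0.n_cols;
    const double log2pi = std::log(2.0 * M_PI);
    double ll = 0.0;
    arma::mat A(km1, km1);
    for (int i = 0; i < n; ++i) {
        arma::vec av = a0;
        if (matsP.n_cols > 0)
            av += matsP * cf.row(i).t();
        A = arma::reshape(av, km1, km1);
        arma::mat R;
        bool ok = arma::chol(R, A);
        if (!ok) {
            arma::mat Aj = A + 1e-8 * arma::eye(km1, km1);
            if (!arma::chol(R, Aj))
                stop("covariance not positive definite at site %d", i + 1);
        }
        arma::vec z = arma::solve(arma::trimatl(R.t()), z0.col(i));
        double logdet = 2.0 * arma::sum(arma::log(R.diag()));
        ll += -0.5 * (km1 * log2pi + km1 * std::log(epsv[i]) + logdet +
                      arma::dot(z, z) / epsv[i]);
    }
    return ll;
}
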