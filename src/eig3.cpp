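// Batched symmetric 3x3 eigendecomposition for per-voxel diffusion tensors.
// Input rows are the six unique tensor components (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz);
// output eigenvalues are sorted descending, eigenvectors are the matching
// orthonormal columns flattened row-wise per voxel.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".eig3SymBatch")]]
Rcpp::List eig3SymBatch(const arma::mat& comps, bool vectors) {
    const arma::uword n = comps.n_rows;
    if (comps.n_cols != 6)
        Rcpp::stop("expected 6 tensor components per row");
    arma::mat evals(n, 3);
    arma::mat evecs;
    if (vectors) evecs.set_size(n, 9);
    arma::mat33 D;
    arma::vec3 lam;
    arma::mat33 V;
    for (arma::uword i = 0; i < n; ++i) {
        D(0, 0) = comps(i, 0); D(1, 1) = comps(i, 1); D(2, 2) = comps(i, 2);
        D(0, 1) = D(1, 0) = comps(i, 3);
        D(0, 2) = D(2, 0) = comps(i, 4);
        D(1, 2) = D(2, 1) = comps(i, 5);
        if (vectors) {
            arma::eig_sym(lam, V, D);   // ascending
            for (int j = 0; j < 3; ++j) {
                evals(i, j) = lam(2 - j);
                for (int k = 0; k < 3; ++k)
                    evecs(i, 3 * j + k) = V(k, 2 - j);
            }
        } else {
            arma::eig_sym(lam, D);
            evals(i, 0) = lam(2); evals(i, 1) = lam(1); evals(i, 2) = lam(0);
        }
    }
    if (vectors)
        return Rcpp::List::create(Rcpp::Named("values") = evals,
                                  Rcpp::Named("vectors") = evecs);
    return Rcpp::List::create(Rcpp::Named("values") = evals);
}
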