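#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Seeded K-means core: k-means++ initialization, Lloyd iterations, empty
// clusters re-seeded at the point farthest from its current centroid.
// All randomness goes through R's RNG so set.seed() governs the fit.
// Distances use the ||x||^2 - 2 x.c + ||c||^2 expansion so the assignment
// step is a BLAS matrix product.

// k-means++ seeding (Arthur & Vassilvitskii): first centre uniform, later
// centres sampled with probability proportional to squared distance to the
// nearest centre already chosen.
static arma::mat kmeanspp_init(const arma::mat &X, const arma::vec &xnorm,
                               int k) {
    int n = X.n_rows;
    arma::mat C(k, X.n_cols);

    int first = (int)std::floor(unif_rand() * n);
    if (first >= n) first = n - 1;
    C.row(0) = X.row(first);
    arma::vec d2 = xnorm - 2.0 * (X * C.row(0).t()) +
        arma::dot(C.row(0), C.row(0));
    d2.clamp(0.0, arma::datum::inf);

    for (int c = 1; c < k; ++c) {
        double total = arma::accu(d2);
        int pick;
        if (total > 0.0) {
            double r = unif_rand() * total, cum = 0.0;
            pick = n - 1;
            for (int i = 0; i < n; ++i) {
                cum += d2[i];
                if (cum >= r) { pick = i; break; }
            }
        } else {
            pick = (int)std::floor(unif_rand() * n);
            if (pick >= n) pick = n - 1;
        }
        C.row(c) = X.row(pick);
        arma::vec nd = xnorm - 2.0 * (X * C.row(c).t()) +
            arma::dot(C.row(c), C.row(c));
        nd.clamp(0.0, arma::datum::inf);
        d2 = arma::min(d2, nd);
    }
    return C;
}

// One full Lloyd run from a k-means++ start.
static List lloyd_run(const arma::mat &X, const arma::vec &xnorm, int k,
                      int max_iter, double tol) {
    int n = X.n_rows, d = X.n_cols;
    arma::mat C = kmeanspp_init(X, xnorm, k);
    arma::uvec assign(n, arma::fill::zeros);
    bool converged = false;
    int iter = 0;

    for (iter = 0; iter < max_iter; ++iter) {
        // assignment step: argmin_c ||x - c||^2 = argmax_c (x.c - ||c||^2/2)
        arma::vec chalf = 0.5 * arma::sum(arma::square(C), 1);
        arma::mat score = X * C.t();
        score.each_row() -= chalf.t();
        for (int i = 0; i < n; ++i) assign[i] = score.row(i).index_max();

        // empty clusters: re-seed at the point farthest from its centroid
        arma::uvec counts(k, arma::fill::zeros);
        for (int i = 0; i < n; ++i) counts[assign[i]]++;
        for (int c = 0; c < k; ++c) {
            if (counts[c] == 0) {
                int far = -1;
                double fd = -1.0;
                for (int i = 0; i < n; ++i) {
                    if (counts[assign[i]] <= 1) continue;
                    // ||x - c||^2 = ||x||^2 - 2 (x.c - ||c||^2 / 2)
                    double own = xnorm[i] - 2.0 * score(i, assign[i]);
                    if (own > fd) { fd = own; far = i; }
                }
                if (far >= 0) {
                    counts[assign[far]]--;
                    assign[far] = c;
                    counts[c] = 1;
                    C.row(c) = X.row(far);
                }
            }
        }

        // update step
        arma::mat sums(k, d, arma::fill::zeros);
        for (int i = 0; i < n; ++i) sums.row(assign[i]) += X.row(i);
        double shift = 0.0;
        for (int c = 0; c < k; ++c) {
            arma::rowvec nc = sums.row(c) / counts[c];
            double sh = arma::norm(nc - C.row(c), 2);
            if (sh > shift) shift = sh;
            C.row(c) = nc;
        }
        if (shift < tol) { converged = true; ++iter; break; }
    }

    // final assignment against converged centroids
    arma::vec chalf = 0.5 * arma::sum(arma::square(C), 1);
    arma::mat score = X * C.t();
    score.each_row() -= chalf.t();
    double sse = 0.0;
    IntegerVector assign_out(n);
    for (int i = 0; i < n; ++i) {
        arma::uword a = score.row(i).index_max();
        double d2 = xnorm[i] - 2.0 * score(i, a);
        if (d2 < 0.0) d2 = 0.0;
        sse += d2;
        assign_out[i] = (int)a + 1; // 1-based for R
    }

    NumericMatrix Cout(k, d);
    for (int c = 0; c < k; ++c)
        for (int j = 0; j < d; ++j) Cout(c, j) = C(c, j);
    return List::create(_["centroids"] = Cout, _["assignments"] = assign_out,
                        _["sse"] = sse, _["iter"] = iter,
                        _["converged"] = converged);
}

// [[Rcpp::export]]
List cpp_kmeans(NumericMatrix Xr, int k, int n_init, int max_iter,
                double tol) {
    if (k < 1) stop("k must be >= 1");
    if (Xr.nrow() < k) stop("fewer rows than clusters");
    arma::mat X(Xr.begin(), Xr.nrow(), Xr.ncol(), false);
    arma::vec xnorm = arma::sum(arma::square(X), 1);
    List best;
    double best_sse = R_PosInf;
    for (int r = 0; r < n_init; ++r) {
        List run = lloyd_run(X, xnorm, k, max_iter, tol);
        double s = run["sse"];
        if (s < best_sse) { best_sse = s; best = run; }
    }
    return best;
}
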