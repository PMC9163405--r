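#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// L1 (Manhattan) distance from every row of X to every row of C.
// [[Rcpp::export]]
arma::mat l1_dist_cpp(const arma::mat& X, const arma::mat& C) {
  const uword n = X.n_rows, k = C.n_rows;
  mat D(n, k);
  for (uword s = 0; s < k; ++s) {
    rowvec c = C.row(s);
    for (uword i = 0; i < n; ++i)
      D(i, s) = accu(abs(X.row(i) - c));
  }
  return D;
}

static void assign_l1(const mat& X, const mat& C, uvec& lab, vec& dist) {
  const uword n = X.n_rows, k = C.n_rows;
  for (uword i = 0; i < n; ++i) {
    double best = datum::inf;
    uword bs = 0;
    for (uword s = 0; s < k; ++s) {
      double d = accu(abs(X.row(i) - C.row(s)));
      if (d < best) { best = d; bs = s; }  // strict <: ties -> lowest index
    }
    lab(i) = bs;
    dist(i) = best;
  }
}

// Lloyd-type k-means with L1 assignment and element-wise median updates,
// from a fixed initial centroid matrix. Empty clusters are re-seeded from
// the window farthest from its assigned centroid. Returns 1-based labels,
// final centroids, the objective (total L1 distance) and the per-iteration
// objective trace (recorded after each assignment step).
// [[Rcpp::export]]
Rcpp::List kmeans_l1_core(const arma::mat& X, arma::mat C, int max_iter,
                          double tol) {
  const uword n = X.n_rows, k = C.n_rows;
  uvec lab(n);
  vec dist(n);
  std::vector<double> trace_obj;
  uvec lab_prev(n, fill::zeros);
  bool first = true;

  for (int it = 0; it < max_iter; ++it) {
    assign_l1(X, C, lab, dist);
    // re-seed empty clusters from the farthest assigned window
    for (uword s = 0; s < k; ++s) {
      if (!any(lab == s)) {
        uword far = dist.index_max();
        C.row(s) = X.row(far);
        lab(far) = s;
        dist(far) = 0.0;
      }
    }
    double obj = accu(dist);
    if (!first && trace_obj.back() - obj < tol && all(lab == lab_prev)) {
      trace_obj.push_back(obj);
      break;
    }
    trace_obj.push_back(obj);
    lab_prev = lab;
    first = false;
    // median update
    for (uword s = 0; s < k; ++s) {
      uvec idx = find(lab == s);
      if (idx.n_elem == 1) C.row(s) = X.row(idx(0));
      else if (idx.n_elem > 1) C.row(s) = median(X.rows(idx), 0);
    }
  }
  // final assignment so labels and objective match the returned centroids
  assign_l1(X, C, lab, dist);
  double obj = accu(dist);
  trace_obj.push_back(obj);

  return Rcpp::List::create(
      Rcpp::Named("labels") = Rcpp::IntegerVector(lab.begin(), lab.end()),
      Rcpp::Named("centroids") = C,
      Rcpp::Named("objective") = obj,
      Rcpp::Named("objective_trace") = trace_obj);
}
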