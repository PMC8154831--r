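// Sparse LU solve of the monolithic Newton system via Eigen (COLAMD
// ordering). Triplets arrive 1-based from the assembly kernels.

#include <RcppEigen.h>
#include <Eigen/SparseLU>
// [[Rcpp::depends(RcppEigen)]]

// [[Rcpp::export(name = "cpp_sparse_solve")]]
Rcpp::NumericVector cpp_sparse_solve(const Rcpp::IntegerVector& ti,
                                     const Rcpp::IntegerVector& tj,
                                     const Rcpp::NumericVector& tv,
                                     int n,
                                     const Rcpp::NumericVector& rhs) {
  typedef Eigen::Triplet<double> T;
  std::vector<T> trip;
  trip.reserve(ti.size());
  for (int k = 0; k < ti.size(); ++k)
    trip.emplace_back(ti[k] - 1, tj[k] - 1, tv[k]);
  Eigen::SparseMatrix<double> A(n, n);
  A.setFromTriplets(trip.begin(), trip.end());
  A.makeCompressed();
  Eigen::SparseLU<Eigen::SparseMatrix<double>, Eigen::COLAMDOrdering<int> >
      lu;
  lu.analyzePattern(A);
  lu.factorize(A);
  if (lu.info() != Eigen::Success)
    Rcpp::stop("cpp_sparse_solve: factorization failed (singular system?)");
  Eigen::Map<const Eigen::VectorXd> b(&rhs[0], n);
  Eigen::VectorXd x = lu.solve(b);
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = x(i);
  return out;
}
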