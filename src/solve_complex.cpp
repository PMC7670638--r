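// [[Rcpp::depends(RcppEigen)]]
#include <RcppEigen.h>
#include <Eigen/SparseLU>
#include <Eigen/IterativeLinearSolvers>
#include <complex>

using namespace Rcpp;
typedef std::complex<double> cd;
typedef Eigen::SparseMatrix<cd> SpMatC;

// Solve A x = B for sparse complex A given in triplet form (1-based indices).
// [[Rcpp::export]]
ComplexMatrix cplx_sparse_solve(int n, IntegerVector i, IntegerVector j,
                                ComplexVector x, ComplexMatrix B) {
  std::vector<Eigen::Triplet<cd>> trips;
  trips.reserve(x.size());
  for (R_xlen_t k = 0; k < x.size(); ++k)
    trips.push_back(Eigen::Triplet<cd>(i[k] - 1, j[k] - 1, cd(x[k].r, x[k].i)));
  SpMatC A(n, n);
  A.setFromTriplets(trips.begin(), trips.end());
  A.makeCompressed();
  Eigen::SparseLU<SpMatC, Eigen::COLAMDOrdering<int>> lu;
  lu.analyzePattern(A);
  lu.factorize(A);
  if (lu.info() != Eigen::Success)
    stop("sparse LU factorization failed (singular or ill-conditioned system)");
  int m = B.ncol();
  Eigen::MatrixXcd Bm(n, m);
  for (int c = 0; c < m; ++c)
    for (int r = 0; r < n; ++r)
      Bm(r, c) = cd(B(r, c).r, B(r, c).i);
  Eigen::MatrixXcd X = lu.solve(Bm);
  ComplexMatrix out(n, m);
  for (int c = 0; c < m; ++c)
    for (int r = 0; r < n; ++r) {
      out(r, c).r = X(r, c).real();
      out(r, c).i = X(r, c).imag();
    }
  return out;
}

// Iterative solve (BiCGSTAB with incomplete-LU preconditioning) for the
// large full-domain forward systems; returns the achieved residual so the
// caller can fall back to the direct solver if convergence fails.
// [[Rcpp::export]]
List cplx_sparse_solve_iter(int n, IntegerVector i, IntegerVector j,
                            ComplexVector x, ComplexMatrix B,
                            double tol = 1e-10) {
  std::vector<Eigen::Triplet<cd>> trips;
  trips.reserve(x.size());
  for (R_xlen_t k = 0; k < x.size(); ++k)
    trips.push_back(Eigen::Triplet<cd>(i[k] - 1, j[k] - 1, cd(x[k].r, x[k].i)));
  SpMatC A(n, n);
  A.setFromTriplets(trips.begin(), trips.end());
  A.makeCompressed();
  Eigen::BiCGSTAB<SpMatC, Eigen::IncompleteLUT<cd>> solver;
  solver.preconditioner().setFillfactor(30);
  solver.preconditioner().setDroptol(1e-4);
  solver.setTolerance(tol);
  solver.setMaxIterations(40000);
  solver.compute(A);
  int m = B.ncol();
  Eigen::MatrixXcd Bm(n, m);
  for (int c = 0; c < m; ++c)
    for (int r = 0; r < n; ++r)
      Bm(r, c) = cd(B(r, c).r, B(r, c).i);
  Eigen::MatrixXcd X = solver.solve(Bm);
  ComplexMatrix out(n, m);
  for (int c = 0; c < m; ++c)
    for (int r = 0; r < n; ++r) {
      out(r, c).r = X(r, c).real();
      out(r, c).i = X(r, c).imag();
    }
  return List::create(_["X"] = out, _["error"] = solver.error(),
                      _["converged"] = (solver.info() == Eigen::Success));
}

// Forward + adjoint solve sharing one factorization. Solves A U = B, forms
// the residual R = U - D, and solves A L = conj(R) (A is complex symmetric,
// so L is the adjoint state for the squared-misfit objective).
// [[Rcpp::export]]
List cplx_sparse_solve2(int n, IntegerVector i, IntegerVector j,
                        ComplexVector x, ComplexMatrix B, ComplexMatrix D) {
  std::vector<Eigen::Triplet<cd>> trips;
  trips.reserve(x.size());
  for (R_xlen_t k = 0; k < x.size(); ++k)
    trips.push_back(Eigen::Triplet<cd>(i[k] - 1, j[k] - 1, cd(x[k].r, x[k].i)));
  SpMatC A(n, n);
  A.setFromTriplets(trips.begin(), trips.end());
  A.makeCompressed();
  Eigen::SparseLU<SpMatC, Eigen::COLAMDOrdering<int>> lu;
  lu.analyzePattern(A);
  lu.factorize(A);
  if (lu.info() != Eigen::Success)
    stop("sparse LU factorization failed (singular or ill-conditioned system)");
  int m = B.ncol();
  Eigen::MatrixXcd Bm(n, m), Dm(n, m);
  for (int c = 0; c < m; ++c)
    for (int r = 0; r < n; ++r) {
      Bm(r, c) = cd(B(r, c).r, B(r, c).i);
      Dm(r, c) = cd(D(r, c).r, D(r, c).i);
    }
  Eigen::MatrixXcd U = lu.solve(Bm);
  Eigen::MatrixXcd R = U - Dm;
  Eigen::MatrixXcd L = lu.solve(R.conjugate());
  double obj = R.squaredNorm();
  ComplexMatrix Uo(n, m), Lo(n, m);
  for (int c = 0; c < m; ++c)
    for (int r = 0; r < n; ++r) {
      Uo(r, c).r = U(r, c).real(); Uo(r, c).i = U(r, c).imag();
      Lo(r, c).r = L(r, c).real(); Lo(r, c).i = L(r, c).imag();
    }
  return List::create(_["U"] = Uo, _["lambda"] = Lo, _["objective"] = obj);
}

// Persistent subzone state: static structure, measured data, and the
// symbolic LU pattern, so repeated evaluations only refactorize numerically.
struct SubzoneData {
  int n, nS;
  std::vector<int> e_row, e_iS, e_nS, e_nint, int_S;
  double inv2h2, rho_om2;
  Eigen::MatrixXcd dS;   // nS x 3 measured displacements
  Eigen::MatrixXcd D;    // n x 3 interior data
  SpMatC A;
  std::vector<int> vi_off;   // per edge: index into A.valuePtr(), -1 if none
  std::vector<int> vi_diag;  // per row: index of the diagonal entry
  Eigen::SparseLU<SpMatC, Eigen::COLAMDOrdering<int>> lu;
  bool analyzed = false;
};

static int value_index(const SpMatC &A, int row, int col) {
  for (SpMatC::InnerIterator it(A, col); it; ++it)
    if (it.row() == row) return (int)(&it.valueRef() - A.valuePtr());
  return -1;
}

// [[Rcpp::export]]
SEXP subzone_new(int n, IntegerVector e_row, IntegerVector e_iS,
                 IntegerVector e_nS, IntegerVector e_nint,
                 IntegerVector int_S, ComplexMatrix dS, double h,
                 double rho_om2) {
  XPtr<SubzoneData> p(new SubzoneData(), true);
  p->n = n;
  p->nS = dS.nrow();
  R_xlen_t nE = e_row.size();
  p->e_row.assign(e_row.begin(), e_row.end());
  p->e_iS.assign(e_iS.begin(), e_iS.end());
  p->e_nS.assign(e_nS.begin(), e_nS.end());
  p->e_nint.assign(e_nint.begin(), e_nint.end());
  p->int_S.assign(int_S.begin(), int_S.end());
  p->inv2h2 = 1.0 / (2.0 * h * h);
  p->rho_om2 = rho_om2;
  p->dS.resize(p->nS, 3);
  for (int r = 0; r < p->nS; ++r)
    for (int c = 0; c < 3; ++c)
      p->dS(r, c) = cd(dS(r, c).r, dS(r, c).i);
  p->D.resize(n, 3);
  for (int r = 0; r < n; ++r)
    for (int c = 0; c < 3; ++c)
      p->D(r, c) = p->dS(int_S[r] - 1, c);
  // symbolic pattern from unit values
  std::vector<Eigen::Triplet<cd>> trips;
  trips.reserve(nE + n);
  for (R_xlen_t e = 0; e < nE; ++e)
    if (e_nint[e] > 0)
      trips.push_back(Eigen::Triplet<cd>(e_row[e] - 1, e_nint[e] - 1,
                                         cd(1.0, 0.0)));
  for (int r = 0; r < n; ++r)
    trips.push_back(Eigen::Triplet<cd>(r, r, cd(1.0, 0.0)));
  p->A.resize(n, n);
  p->A.setFromTriplets(trips.begin(), trips.end());
  p->A.makeCompressed();
  p->lu.analyzePattern(p->A);
  p->analyzed = true;
  p->vi_diag.resize(n);
  for (int r = 0; r < n; ++r) p->vi_diag[r] = value_index(p->A, r, r);
  p->vi_off.resize(nE);
  for (R_xlen_t e = 0; e < nE; ++e)
    p->vi_off[e] = (e_nint[e] > 0)
      ? value_index(p->A, e_row[e] - 1, e_nint[e] - 1) : -1;
  return p;
}

// [[Rcpp::export]]
List subzone_eval_ptr(SEXP ptr, ComplexVector gS, bool grad) {
  XPtr<SubzoneData> p(ptr);
  int n = p->n, nS = p->nS;
  R_xlen_t nE = p->e_row.size();
  double inv2h2 = p->inv2h2;
  std::vector<cd> g(nS);
  for (int k = 0; k < nS; ++k) g[k] = cd(gS[k].r, gS[k].i);
  // zero the stored values, then accumulate (pattern is fixed)
  cd *vals = p->A.valuePtr();
  for (int k = 0; k < p->A.nonZeros(); ++k) vals[k] = cd(0.0, 0.0);
  Eigen::MatrixXcd B = Eigen::MatrixXcd::Zero(n, 3);
  for (R_xlen_t e = 0; e < nE; ++e) {
    cd c = (g[p->e_iS[e] - 1] + g[p->e_nS[e] - 1]) * inv2h2;
    int r = p->e_row[e] - 1;
    vals[p->vi_diag[r]] -= c;
    if (p->vi_off[e] >= 0) {
      vals[p->vi_off[e]] += c;
    } else {
      int nb = p->e_nS[e] - 1;
      for (int comp = 0; comp < 3; ++comp)
        B(r, comp) -= c * p->dS(nb, comp);
    }
  }
  for (int r = 0; r < n; ++r)
    vals[p->vi_diag[r]] += cd(p->rho_om2, 0.0);
  p->lu.factorize(p->A);
  if (p->lu.info() != Eigen::Success)
    stop("subzone forward solve failed (singular local system)");
  Eigen::MatrixXcd U = p->lu.solve(B);
  Eigen::MatrixXcd R = U - p->D;
  double obj = R.squaredNorm();
  if (!grad)
    return List::create(_["objective"] = obj);
  Eigen::MatrixXcd lam = p->lu.solve(R.conjugate());
  std::vector<cd> q(nS, cd(0.0, 0.0));
  for (int comp = 0; comp < 3; ++comp) {
    for (R_xlen_t e = 0; e < nE; ++e) {
      int r = p->e_row[e] - 1;
      cd un = (p->e_nint[e] > 0) ? U(p->e_nint[e] - 1, comp)
                                 : p->dS(p->e_nS[e] - 1, comp);
      cd qe = -lam(r, comp) * (un - U(r, comp)) * inv2h2;
      q[p->e_iS[e] - 1] += qe;
      q[p->e_nS[e] - 1] += qe;
    }
  }
  NumericVector dgp(nS), dgpp(nS);
  for (int k = 0; k < nS; ++k) {
    dgp[k] = 2.0 * q[k].real();
    dgpp[k] = -2.0 * q[k].imag();
  }
  return List::create(_["objective"] = obj, _["dJ_dgp"] = dgp,
                      _["dJ_dgpp"] = dgpp);
}

// One subzone objective/gradient evaluation for the nonlinear inversion.
// Inputs describe the static subzone structure (1-based indices):
//   e_row  : interior equation row of each directed edge
//   e_iS   : subzone-voxel index of the edge's origin (the row voxel)
//   e_nS   : subzone-voxel index of the edge's neighbour
//   e_nint : interior index of the neighbour, 0 if it is Dirichlet boundary
//   int_S  : subzone-voxel index of each interior row
// gS are the complex moduli (Pa) at the subzone voxels, dS the measured
// displacements (nS x 3). Returns J and, if grad, dJ/dG' and dJ/dG''.
// [[Rcpp::export]]
List subzone_eval_cpp(int n, IntegerVector e_row, IntegerVector e_iS,
                      IntegerVector e_nS, IntegerVector e_nint,
                      IntegerVector int_S, ComplexVector gS,
                      ComplexMatrix dS, double h, double rho_om2,
                      bool grad) {
  R_xlen_t nE = e_row.size();
  int nS = gS.size();
  double inv2h2 = 1.0 / (2.0 * h * h);
  std::vector<cd> g(nS);
  for (int k = 0; k < nS; ++k) g[k] = cd(gS[k].r, gS[k].i);
  std::vector<cd> ce(nE);
  std::vector<Eigen::Triplet<cd>> trips;
  trips.reserve(nE + n);
  std::vector<cd> diag(n, cd(rho_om2, 0.0));
  Eigen::MatrixXcd B = Eigen::MatrixXcd::Zero(n, 3);
  for (R_xlen_t e = 0; e < nE; ++e) {
    cd c = (g[e_iS[e] - 1] + g[e_nS[e] - 1]) * inv2h2;
    ce[e] = c;
    int r = e_row[e] - 1;
    diag[r] -= c;
    if (e_nint[e] > 0) {
      trips.push_back(Eigen::Triplet<cd>(r, e_nint[e] - 1, c));
    } else {
      int nb = e_nS[e] - 1;
      for (int comp = 0; comp < 3; ++comp)
        B(r, comp) -= c * cd(dS(nb, comp).r, dS(nb, comp).i);
    }
  }
  for (int r = 0; r < n; ++r)
    trips.push_back(Eigen::Triplet<cd>(r, r, diag[r]));
  SpMatC A(n, n);
  A.setFromTriplets(trips.begin(), trips.end());
  A.makeCompressed();
  Eigen::SparseLU<SpMatC, Eigen::COLAMDOrdering<int>> lu;
  lu.analyzePattern(A);
  lu.factorize(A);
  if (lu.info() != Eigen::Success)
    stop("subzone forward solve failed (singular local system)");
  Eigen::MatrixXcd D(n, 3);
  for (int r = 0; r < n; ++r)
    for (int comp = 0; comp < 3; ++comp) {
      int s = int_S[r] - 1;
      D(r, comp) = cd(dS(s, comp).r, dS(s, comp).i);
    }
  Eigen::MatrixXcd U = lu.solve(B);
  Eigen::MatrixXcd R = U - D;
  double obj = R.squaredNorm();
  if (!grad)
    return List::create(_["objective"] = obj);
  Eigen::MatrixXcd lam = lu.solve(R.conjugate());
  std::vector<cd> q(nS, cd(0.0, 0.0));
  for (int comp = 0; comp < 3; ++comp) {
    for (R_xlen_t e = 0; e < nE; ++e) {
      int r = e_row[e] - 1;
      cd un = (e_nint[e] > 0) ? U(e_nint[e] - 1, comp)
                              : cd(dS(e_nS[e] - 1, comp).r,
                                   dS(e_nS[e] - 1, comp).i);
      cd qe = -lam(r, comp) * (un - U(r, comp)) * inv2h2;
      q[e_iS[e] - 1] += qe;
      q[e_nS[e] - 1] += qe;
    }
  }
  NumericVector dgp(nS), dgpp(nS);
  for (int k = 0; k < nS; ++k) {
    dgp[k] = 2.0 * q[k].real();
    dgpp[k] = -2.0 * q[k].imag();
  }
  return List::create(_["objective"] = obj, _["dJ_dgp"] = dgp,
                      _["dJ_dgpp"] = dgpp);
}
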