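// Computational kernels: exact nearest-neighbour queries, 26-connectivity
// component labelling, and the DTIBS assignment step. All distances are in
// world millimetres; indices returned to R are 1-based.
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Nearest reference point for every query point (brute force, exact).
// Returns 1-based indices and distances (mm).
// [[Rcpp::export(name = ".nnIndexCpp")]]
List nnIndexCpp(const arma::mat& query, const arma::mat& ref) {
  const arma::uword nq = query.n_rows, nr = ref.n_rows;
  arma::ivec idx(nq);
  arma::vec dist(nq);
  for (arma::uword i = 0; i < nq; ++i) {
    double best = arma::datum::inf;
    arma::uword bi = 0;
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (arma::uword j = 0; j < nr; ++j) {
      const double dx = qx - ref(j, 0), dy = qy - ref(j, 1), dz = qz - ref(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bi = j; }
    }
    idx[i] = (int)bi + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Nearest labelled reference point with deterministic tie-breaking: among
// reference points at (numerically) equal distance the smallest label wins.
// [[Rcpp::export(name = ".nearestLabelCpp")]]
IntegerVector nearestLabelCpp(const arma::mat& query, const arma::mat& ref,
                              const IntegerVector& labels, double tol = 1e-9) {
  const arma::uword nq = query.n_rows, nr = ref.n_rows;
  IntegerVector out(nq);
  for (arma::uword i = 0; i < nq; ++i) {
    double best = arma::datum::inf;
    int blab = NA_INTEGER;
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (arma::uword j = 0; j < nr; ++j) {
      const double dx = qx - ref(j, 0), dy = qy - ref(j, 1), dz = qz - ref(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best - tol) {
        best = d2; blab = labels[j];
      } else if (std::abs(d2 - best) <= tol && labels[j] < blab) {
        blab = labels[j];
      }
    }
    out[i] = blab;
  }
  return out;
}

// 26-connectivity component labelling of a 3D logical array (flattened,
// column-major, dims = c(nx, ny, nz)). Returns component id per voxel
// (0 outside the mask), components numbered from 1 in discovery order.
// [[Rcpp::export(name = ".ccLabelCpp")]]
IntegerVector ccLabelCpp(const LogicalVector& mask, const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector comp(n, 0);
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || comp[s] != 0) continue;
    ++cur;
    comp[s] = cur;
    q.push(s);
    while (!q.empty()) {
      const R_xlen_t v = q.front(); q.pop();
      const int x = (int)(v % nx);
      const int y = (int)((v / nx) % ny);
      const int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        const int zz = z + dz; if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int xx = x + dx; if (xx < 0 || xx >= nx) continue;
            const R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[w] && comp[w] == 0) { comp[w] = cur; q.push(w); }
          }
        }
      }
    }
  }
  return comp;
}

// One DTIBS assignment sweep. Arguments:
//   X      N x 3 voxel world coordinates (mm)
//   F      N x 3 scaled tensor-shape features (trace, FA, mode)
//   U      N x 6 orientation dyadic components (xx, xy, xz, yy, yz, zz)
//   C      K x 3 cluster centroids
//   Winv   3 x 3 x K inverse (regularized) spatial covariances
//   CF     K x 3 scaled shape features of the cluster mean tensors
//   CU     K x 6 orientation dyadics of the cluster mean tensors
//   alpha  shape-vs-orientation weight in [0, 1]
// Distance per Eq.: Mahalanobis spatial term + alpha * ||dF|| +
// (1 - alpha) * Frobenius norm of the dyadic difference. Ties go to the
// lowest cluster index (strict < comparison over ascending k).
// [[Rcpp::export(name = ".dtibsAssignCpp")]]
List dtibsAssignCpp(const arma::mat& X, const arma::mat& F, const arma::mat& U,
                    const arma::mat& C, const arma::cube& Winv,
                    const arma::mat& CF, const arma::mat& CU, double alpha) {
  const arma::uword n = X.n_rows, K = C.n_rows;
  arma::ivec assign(n);
  arma::vec dmin(n);
  for (arma::uword i = 0; i < n; ++i) {
    double best = arma::datum::inf;
    arma::uword bk = 0;
    for (arma::uword k = 0; k < K; ++k) {
      const double dx = X(i, 0) - C(k, 0);
      const double dy = X(i, 1) - C(k, 1);
      const double dz = X(i, 2) - C(k, 2);
      const arma::mat& W = Winv.slice(k);
      double m =
        dx * (W(0,0) * dx + W(0,1) * dy + W(0,2) * dz) +
        dy * (W(1,0) * dx + W(1,1) * dy + W(1,2) * dz) +
        dz * (W(2,0) * dx + W(2,1) * dy + W(2,2) * dz);
      if (m < 0) m = 0;
      double d = std::sqrt(m);
      if (alpha > 0) {
        const double f0 = F(i,0) - CF(k,0), f1 = F(i,1) - CF(k,1), f2 = F(i,2) - CF(k,2);
        d += alpha * std::sqrt(f0*f0 + f1*f1 + f2*f2);
      }
      if (alpha < 1) {
        const double u0 = U(i,0) - CU(k,0), u1 = U(i,1) - CU(k,1), u2 = U(i,2) - CU(k,2);
        const double u3 = U(i,3) - CU(k,3), u4 = U(i,4) - CU(k,4), u5 = U(i,5) - CU(k,5);
        // Frobenius norm of a symmetric matrix from its 6 components:
        // off-diagonals counted twice.
        d += (1.0 - alpha) *
          std::sqrt(u0*u0 + u3*u3 + u5*u5 + 2.0 * (u1*u1 + u2*u2 + u4*u4));
      }
      if (d < best) { best = d; bk = k; }
    }
    assign[i] = (int)bk + 1;
    dmin[i] = best;
  }
  return List::create(_["assign"] = assign, _["distance"] = dmin);
}
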