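#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-time-warping alignment of a query series x against a reference
// series y, with the symmetric step set {(1,0),(0,1),(1,1)} and local cost
// |x_i - y_j|. Backtracking tie-break: diagonal first, then the vertical
// (reference-axis) move, then horizontal. Returns the warping path as
// 0-based (x, y) index pairs ordered from (0,0) to (nx-1, ny-1), plus the
// minimal cumulative distance.
// [[Rcpp::export]]
List dtw_path_cpp(NumericVector query, NumericVector reference) {
  const int nx = query.size();
  const int ny = reference.size();
  if (nx < 1 || ny < 1) stop("empty series");

  // accumulated cost, column-major: D(i, j) = D[i + j*nx]
  std::vector<double> D((size_t)nx * ny);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double c = std::abs(query[i] - reference[j]);
      double best;
      if (i == 0 && j == 0) {
        best = 0.0;
      } else if (i == 0) {
        best = D[(size_t)(j - 1) * nx];
      } else if (j == 0) {
        best = D[i - 1];
      } else {
        double d = D[(i - 1) + (size_t)(j - 1) * nx]; // diagonal
        double v = D[i + (size_t)(j - 1) * nx];       // vertical
        double h = D[(i - 1) + (size_t)j * nx];       // horizontal
        best = std::min(d, std::min(v, h));
      }
      D[i + (size_t)j * nx] = c + best;
    }
  }

  // backtrack from (nx-1, ny-1); prefer diagonal, then vertical, then horizontal
  std::vector<int> px, py;
  int i = nx - 1, j = ny - 1;
  px.push_back(i); py.push_back(j);
  while (i > 0 || j > 0) {
    if (i == 0) {
      --j;
    } else if (j == 0) {
      --i;
    } else {
      double d = D[(i - 1) + (size_t)(j - 1) * nx];
      double v = D[i + (size_t)(j - 1) * nx];
      double h = D[(i - 1) + (size_t)j * nx];
      if (d <= v && d <= h) {
        --i; --j;
      } else if (v <= h) {
        --j;
      } else {
        --i;
      }
    }
    px.push_back(i); py.push_back(j);
  }
  std::reverse(px.begin(), px.end());
  std::reverse(py.begin(), py.end());

  IntegerMatrix path(px.size(), 2);
  for (size_t k = 0; k < px.size(); ++k) {
    path(k, 0) = px[k];
    path(k, 1) = py[k];
  }
  colnames(path) = CharacterVector::create("x", "y");
  return List::create(_["path"] = path,
                      _["cumulative_distance"] = D[(nx - 1) + (size_t)(ny - 1) * nx]);
}
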