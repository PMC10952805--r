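#include <Rcpp.h>
using namespace Rcpp;

// Online self-organizing map with a gaussian neighborhood kernel.
// The presentation order and the initial codebook are generated in R so that
// all randomness flows through R's RNG; schedules decay linearly per step.
// [[Rcpp::export(name = ".som_train_cpp")]]
List som_train_cpp(NumericMatrix X, NumericMatrix codebook,
                   IntegerVector order, int grid_rows, int grid_cols,
                   double alpha_start, double alpha_end,
                   double radius_start, double radius_end) {
  const int n = X.nrow(), p = X.ncol(), m = codebook.nrow();
  const R_xlen_t steps = order.size();
  NumericMatrix W = clone(codebook);
  // grid coordinates of each node (row-major over rows)
  std::vector<double> gr(m), gc(m);
  for (int k = 0; k < m; ++k) {
    gr[k] = k % grid_rows;
    gc[k] = k / grid_rows;
  }
  for (R_xlen_t s = 0; s < steps; ++s) {
    const int i = order[s] - 1;
    const double frac = (steps > 1) ? (double)s / (double)(steps - 1) : 0.0;
    const double alpha = alpha_start + (alpha_end - alpha_start) * frac;
    const double radius = radius_start + (radius_end - radius_start) * frac;
    // best matching unit
    int bmu = 0;
    double best = R_PosInf;
    for (int k = 0; k < m; ++k) {
      double d = 0.0;
      for (int j = 0; j < p; ++j) {
        const double diff = X(i, j) - W(k, j);
        d += diff * diff;
      }
      if (d < best) { best = d; bmu = k; }
    }
    const double sigma2 = std::max(radius * radius, 1e-12);
    for (int k = 0; k < m; ++k) {
      const double dr = gr[k] - gr[bmu], dc = gc[k] - gc[bmu];
      const double g2 = dr * dr + dc * dc;
      if (g2 > 9.0 * sigma2) continue;  // negligible update
      const double h = alpha * std::exp(-g2 / (2.0 * sigma2));
      for (int j = 0; j < p; ++j)
        W(k, j) += h * (X(i, j) - W(k, j));
    }
  }
  // final hard assignment + quantization error
  IntegerVector assign(n);
  double qe = 0.0;
  for (int i = 0; i < n; ++i) {
    int bmu = 0;
    double best = R_PosInf;
    for (int k = 0; k < m; ++k) {
      double d = 0.0;
      for (int j = 0; j < p; ++j) {
        const double diff = X(i, j) - W(k, j);
        d += diff * diff;
      }
      if (d < best) { best = d; bmu = k; }
    }
    assign[i] = bmu + 1;
    qe += std::sqrt(best);
  }
  qe = (n > 0) ? qe / n : 0.0;
  return List::create(_["codebook"] = W, _["assignments"] = assign,
                      _["quant_error"] = qe);
}

// Map every sample to its nearest codebook row (1-based).
// [[Rcpp::export(name = ".nearest_codebook_cpp")]]
IntegerVector nearest_codebook_cpp(NumericMatrix X, NumericMatrix W) {
  const int n = X.nrow(), p = X.ncol(), m = W.nrow();
  IntegerVector assign(n);
  for (int i = 0; i < n; ++i) {
    int bmu = 0;
    double best = R_PosInf;
    for (int k = 0; k < m; ++k) {
      double d = 0.0;
      for (int j = 0; j < p; ++j) {
        const double diff = X(i, j) - W(k, j);
        d += diff * diff;
      }
      if (d < best) { best = d; bmu = k; }
    }
    assign[i] = bmu + 1;
  }
  return assign;
}

// Euclidean nearest-seed label for every pixel of an H x W raster
// (planar Voronoi tessellation used by the synthetic tissue generator).
// Seeds are 1-based pixel coordinates; ties go to the lowest seed index.
// [[Rcpp::export(name = ".nearest_seed_cpp")]]
IntegerMatrix nearest_seed_cpp(int H, int W, IntegerVector sr, IntegerVector sc) {
  const int ns = sr.size();
  IntegerMatrix lab(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int bestk = 0;
      double best = R_PosInf;
      for (int k = 0; k < ns; ++k) {
        const double dr = (double)(r + 1 - sr[k]);
        const double dc = (double)(c + 1 - sc[k]);
        const double d = dr * dr + dc * dc;
        if (d < best) { best = d; bestk = k; }
      }
      lab(r, c) = bestk + 1;
    }
  }
  return lab;
}
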