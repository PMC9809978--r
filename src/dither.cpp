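#include <Rcpp.h>
using namespace Rcpp;

// Floyd–Steinberg error diffusion over a K-material palette.
//
// `lin` is an nx x ny x 3 array of linear-light RGB values, `alive` marks
// pixels with alpha > 0 (everything else is the no-material sentinel 0 and
// neither receives nor absorbs error), `palette` is K x 3 in the same linear
// space. Rows are scanned serpentine (boustrophedon); quantisation error is
// pushed to unprocessed neighbours with weights 7/16 (ahead), 3/16
// (behind-below), 5/16 (below), 1/16 (ahead-below), mirrored with the scan
// direction. Accumulated error is clamped to [-1, 1] per channel before the
// nearest-palette search; ties go to the lowest palette index. Fully
// deterministic.
//
// [[Rcpp::export(name = ".fs_dither")]]
IntegerMatrix fs_dither(NumericVector lin, LogicalMatrix alive,
                        NumericMatrix palette) {
  IntegerVector dims = lin.attr("dim");
  const int nx = dims[0], ny = dims[1];
  const int K = palette.nrow();
  if (K < 2) stop("palette must have at least 2 materials");
  IntegerMatrix out(nx, ny);
  std::vector<double> err(3 * (size_t)nx * ny, 0.0);
  const double w[4] = {7.0 / 16, 3.0 / 16, 5.0 / 16, 1.0 / 16};

  for (int y = 0; y < ny; ++y) {
    const int dir = (y % 2 == 0) ? 1 : -1;
    const int x0 = (dir == 1) ? 0 : nx - 1;
    for (int s = 0; s < nx; ++s) {
      const int x = x0 + dir * s;
      if (!alive(x, y)) { out(x, y) = 0; continue; }
      double c0[3];
      for (int c = 0; c < 3; ++c) {
        double e = err[c + 3 * ((size_t)x + (size_t)nx * y)];
        if (e > 1.0) e = 1.0;
        if (e < -1.0) e = -1.0;
        c0[c] = lin[x + (size_t)nx * (y + (size_t)ny * c)] + e;
      }
      int best = 0;
      double bestd = R_PosInf;
      for (int k = 0; k < K; ++k) {
        double d = 0;
        for (int c = 0; c < 3; ++c) {
          const double t = c0[c] - palette(k, c);
          d += t * t;
        }
        if (d < bestd) { bestd = d; best = k; }
      }
      out(x, y) = best + 1;
      double q[3];
      for (int c = 0; c < 3; ++c) q[c] = c0[c] - palette(best, c);
      const int tx[4] = {x + dir, x - dir, x, x + dir};
      const int ty[4] = {y, y + 1, y + 1, y + 1};
      for (int t = 0; t < 4; ++t) {
        const int xx = tx[t], yy = ty[t];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny) continue;
        if (!alive(xx, yy)) continue;  // sentinel pixels absorb nothing
        for (int c = 0; c < 3; ++c) {
          err[c + 3 * ((size_t)xx + (size_t)nx * yy)] += w[t] * q[c];
        }
      }
    }
  }
  return out;
}
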