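#include <Rcpp.h>
#include <climits>
#include <vector>
using namespace Rcpp;

// 8-connected component labelling of a binary mask. Labels are assigned in
// column-major scan order of the first pixel encountered, so the result is
// deterministic for a given mask.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) != 0 && lab(i, j) == 0) {
        ++next;
        lab(i, j) = next;
        stack.push_back(std::make_pair(i, j));
        while (!stack.empty()) {
          int ci = stack.back().first, cj = stack.back().second;
          stack.pop_back();
          for (int dj = -1; dj <= 1; ++dj) {
            for (int di = -1; di <= 1; ++di) {
              int ni = ci + di, nj = cj + dj;
              if (ni >= 0 && ni < nr && nj >= 0 && nj < nc &&
                  mask(ni, nj) != 0 && lab(ni, nj) == 0) {
                lab(ni, nj) = next;
                stack.push_back(std::make_pair(ni, nj));
              }
            }
          }
        }
      }
    }
  }
  return lab;
}

// Exact nearest-nucleus maps for background pixels within max_r_px (pixel
// units, centre-to-centre Euclidean) of any labelled nucleus.
//
// Returns, per pixel:
//   best_d2    squared pixel distance to the nearest nucleus (INT_MAX if
//              none within range, or the pixel is itself inside a nucleus)
//   best_label the label of that nucleus (0 if none); equal distances to two
//              nuclei resolve to the lower label
//   second_d2  squared distance to the nearest nucleus with a DIFFERENT
//              label than best_label (INT_MAX if none in range)
//
// Distances are kept as exact integer squared distances so that ties and
// width cutoffs are free of floating-point ambiguity.
// [[Rcpp::export]]
List cpp_nearest_nucleus(IntegerMatrix labels, double max_r_px) {
  const int nr = labels.nrow(), nc = labels.ncol();
  const double r2max = max_r_px * max_r_px;
  const int R = (int)std::floor(max_r_px);

  // disk of integer offsets with 0 < di^2 + dj^2 <= r2max
  std::vector<int> odi, odj, od2;
  for (int dj = -R; dj <= R; ++dj) {
    for (int di = -R; di <= R; ++di) {
      int d2 = di * di + dj * dj;
      if (d2 > 0 && (double)d2 <= r2max) {
        odi.push_back(di);
        odj.push_back(dj);
        od2.push_back(d2);
      }
    }
  }
  const int noff = (int)odi.size();

  // group border pixels by label (a pixel is border if any 8-neighbour,
  // including out-of-image, carries a different label)
  int maxlab = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (labels(i, j) > maxlab) maxlab = labels(i, j);

  std::vector<std::vector<std::pair<int, int> > > border(maxlab + 1);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = labels(i, j);
      if (k <= 0) continue;
      bool isb = false;
      for (int dj = -1; dj <= 1 && !isb; ++dj) {
        for (int di = -1; di <= 1 && !isb; ++di) {
          if (di == 0 && dj == 0) continue;
          int ni = i + di, nj = j + dj;
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc || labels(ni, nj) != k)
            isb = true;
        }
      }
      if (isb) border[k].push_back(std::make_pair(i, j));
    }
  }

  IntegerMatrix bestd2(nr, nc), bestlab(nr, nc), secd2(nr, nc);
  std::fill(bestd2.begin(), bestd2.end(), INT_MAX);
  std::fill(secd2.begin(), secd2.end(), INT_MAX);

  // labels processed in ascending order so that equal-distance ties keep the
  // lower label as best
  for (int k = 1; k <= maxlab; ++k) {
    for (size_t b = 0; b < border[k].size(); ++b) {
      int bi = border[k][b].first, bj = border[k][b].second;
      for (int o = 0; o < noff; ++o) {
        int ti = bi + odi[o], tj = bj + odj[o];
        if (ti < 0 || ti >= nr || tj < 0 || tj >= nc) continue;
        if (labels(ti, tj) != 0) continue;  // only background pixels
        int d2 = od2[o];
        int bd = bestd2(ti, tj);
        if (bestlab(ti, tj) == k) {
          if (d2 < bd) bestd2(ti, tj) = d2;
        } else if (d2 < bd) {
          secd2(ti, tj) = bd;
          bestd2(ti, tj) = d2;
          bestlab(ti, tj) = k;
        } else if (d2 < secd2(ti, tj)) {
          secd2(ti, tj) = d2;
        }
      }
    }
  }

  return List::create(_["best_d2"] = bestd2, _["best_label"] = bestlab,
                      _["second_d2"] = secd2);
}
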