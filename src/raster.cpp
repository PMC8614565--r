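#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Squared distance from point (px,py) to segment (x1,y1)-(x2,y2).
static inline double seg_dist2(double px, double py,
                               double x1, double y1, double x2, double y2) {
  double dx = x2 - x1, dy = y2 - y1;
  double len2 = dx * dx + dy * dy;
  double t = 0.0;
  if (len2 > 0.0) {
    t = ((px - x1) * dx + (py - y1) * dy) / len2;
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  }
  double qx = x1 + t * dx - px, qy = y1 + t * dy - py;
  return qx * qx + qy * qy;
}

// Paint a list of stroke polylines onto a white sheet.
//
// Each stroke is swept as a disc of diameter `width_mm`; pressure p renders
// the mark as p * colour + (1 - p) * white.  Strokes are painted in list
// order (last on top).  A per-pixel bitmask records every stroke colour that
// touched the pixel, independent of paint order, so overlap ground truth
// survives occlusion.
//
// pts:      list of n x 2 matrices (x_mm, y_mm)
// pal:      16 x 3 matrix of reference RGB (0-255)
// Returns list(r, g, b, mask): integer matrices H x W.
// [[Rcpp::export]]
List paint_strokes_cpp(List pts, IntegerVector colour_id,
                       NumericVector width_mm, NumericVector pressure,
                       NumericMatrix pal,
                       double sheet_w_mm, double sheet_h_mm, double px_per_mm) {
  const int W = (int) std::lround(sheet_w_mm * px_per_mm);
  const int H = (int) std::lround(sheet_h_mm * px_per_mm);
  IntegerMatrix R(H, W), G(H, W), B(H, W), M(H, W);
  std::fill(R.begin(), R.end(), 255);
  std::fill(G.begin(), G.end(), 255);
  std::fill(B.begin(), B.end(), 255);

  const int ns = pts.size();
  for (int s = 0; s < ns; ++s) {
    NumericMatrix P = pts[s];
    const int n = P.nrow();
    if (n < 2) continue;
    const int cid = colour_id[s];
    const double p = pressure[s];
    const double rad = width_mm[s] / 2.0;
    const int cr = (int) std::lround(255.0 + p * (pal(cid - 1, 0) - 255.0));
    const int cg = (int) std::lround(255.0 + p * (pal(cid - 1, 1) - 255.0));
    const int cb = (int) std::lround(255.0 + p * (pal(cid - 1, 2) - 255.0));
    const int bit = 1 << (cid - 1);
    const double r2 = rad * rad;

    for (int i = 0; i + 1 < n; ++i) {
      double x1 = P(i, 0), y1 = P(i, 1), x2 = P(i + 1, 0), y2 = P(i + 1, 1);
      double xmin = std::min(x1, x2) - rad, xmax = std::max(x1, x2) + rad;
      double ymin = std::min(y1, y2) - rad, ymax = std::max(y1, y2) + rad;
      // pixel (row r, col c) has centre ((c + .5)/ppm, (r + .5)/ppm), 0-based
      int c0 = std::max(0, (int) std::floor(xmin * px_per_mm - 0.5));
      int c1 = std::min(W - 1, (int) std::ceil(xmax * px_per_mm - 0.5));
      int r0 = std::max(0, (int) std::floor(ymin * px_per_mm - 0.5));
      int r1 = std::min(H - 1, (int) std::ceil(ymax * px_per_mm - 0.5));
      for (int rr = r0; rr <= r1; ++rr) {
        double py = (rr + 0.5) / px_per_mm;
        for (int cc = c0; cc <= c1; ++cc) {
          double px = (cc + 0.5) / px_per_mm;
          if (seg_dist2(px, py, x1, y1, x2, y2) <= r2) {
            R(rr, cc) = cr; G(rr, cc) = cg; B(rr, cc) = cb;
            M(rr, cc) |= bit;
          }
        }
      }
    }
  }
  return List::create(_["r"] = R, _["g"] = G, _["b"] = B, _["mask"] = M);
}

// Assign every pixel to background (0) or the crayon whose white->colour
// blend ray passes nearest in RGB space.  Pressure renders marks as convex
// blends towards white, so the nearest-ray rule inverts the rendering model
// exactly for any pressure; pixels within bg_delta of white are background.
// Also returns, from the same pass: per-pixel Rec.601 luminance in [0,1],
// its population mean and sd over the sheet, and per image row the first
// and last marked column (1-based; NA when the row is empty), which is
// enough to reconstruct the convex hull of the marked area.
// [[Rcpp::export]]
List label_pixels_full_cpp(IntegerMatrix R, IntegerMatrix G, IntegerMatrix B,
                           NumericMatrix pal, double bg_delta) {
  const int H = R.nrow(), W = R.ncol();
  const int K = pal.nrow();
  std::vector<double> vx(K), vy(K), vz(K), vv(K);
  for (int k = 0; k < K; ++k) {
    vx[k] = pal(k, 0) - 255.0;
    vy[k] = pal(k, 1) - 255.0;
    vz[k] = pal(k, 2) - 255.0;
    vv[k] = vx[k] * vx[k] + vy[k] * vy[k] + vz[k] * vz[k];
  }
  const double bg2 = bg_delta * bg_delta;
  IntegerMatrix L(H, W);
  NumericMatrix lum(H, W);
  IntegerVector rmin(H, NA_INTEGER), rmax(H, NA_INTEGER);
  double lsum = 0.0, lsum2 = 0.0;
  std::unordered_map<int, int> memo;
  memo.reserve(256);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double y = (0.299 * R(r, c) + 0.587 * G(r, c) + 0.114 * B(r, c)) / 255.0;
      lum(r, c) = y;
      lsum += y; lsum2 += y * y;
      int key = (R(r, c) << 16) | (G(r, c) << 8) | B(r, c);
      int lab;
      auto hit = memo.find(key);
      if (hit != memo.end()) lab = hit->second;
      else {
        double dx = R(r, c) - 255.0, dy = G(r, c) - 255.0, dz = B(r, c) - 255.0;
        double dw2 = dx * dx + dy * dy + dz * dz;
        lab = 0;
        if (dw2 > bg2) {
          double bestd = R_PosInf;
          for (int k = 0; k < K; ++k) {
            double t = (dx * vx[k] + dy * vy[k] + dz * vz[k]) / vv[k];
            if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
            double qx = t * vx[k] - dx, qy = t * vy[k] - dy, qz = t * vz[k] - dz;
            double d = qx * qx + qy * qy + qz * qz;
            if (d < bestd) { bestd = d; lab = k + 1; }
          }
        }
        memo[key] = lab;
      }
      L(r, c) = lab;
      if (lab != 0) {
        if (rmin[r] == NA_INTEGER) rmin[r] = c + 1;
        rmax[r] = c + 1;
      }
    }
  }
  const double n = (double) H * W;
  double m = lsum / n;
  double v = lsum2 / n - m * m;
  if (v < 0) v = 0;
  return List::create(_["labels"] = L, _["luminance"] = lum,
                      _["lum_mean"] = m, _["lum_sd"] = std::sqrt(v),
                      _["row_min"] = rmin, _["row_max"] = rmax);
}

// Label assignment alone (see label_pixels_full_cpp).
// [[Rcpp::export]]
IntegerMatrix label_pixels_cpp(IntegerMatrix R, IntegerMatrix G, IntegerMatrix B,
                               NumericMatrix pal, double bg_delta) {
  const int H = R.nrow(), W = R.ncol();
  const int K = pal.nrow();
  std::vector<double> vx(K), vy(K), vz(K), vv(K);
  for (int k = 0; k < K; ++k) {
    vx[k] = pal(k, 0) - 255.0;
    vy[k] = pal(k, 1) - 255.0;
    vz[k] = pal(k, 2) - 255.0;
    vv[k] = vx[k] * vx[k] + vy[k] * vy[k] + vz[k] * vz[k];
  }
  const double bg2 = bg_delta * bg_delta;
  IntegerMatrix L(H, W);
  // a drawing holds few distinct RGB values; label each one once
  std::unordered_map<int, int> memo;
  memo.reserve(256);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int key = (R(r, c) << 16) | (G(r, c) << 8) | B(r, c);
      auto hit = memo.find(key);
      if (hit != memo.end()) { L(r, c) = hit->second; continue; }
      double dx = R(r, c) - 255.0, dy = G(r, c) - 255.0, dz = B(r, c) - 255.0;
      double dw2 = dx * dx + dy * dy + dz * dz;
      int best = 0;
      if (dw2 > bg2) {
        double bestd = R_PosInf;
        for (int k = 0; k < K; ++k) {
          double t = (dx * vx[k] + dy * vy[k] + dz * vz[k]) / vv[k];
          if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
          double qx = t * vx[k] - dx, qy = t * vy[k] - dy, qz = t * vz[k] - dz;
          double d = qx * qx + qy * qy + qz * qz;
          if (d < bestd) { bestd = d; best = k + 1; }
        }
      }
      memo[key] = best;
      L(r, c) = best;
    }
  }
  return L;
}

// Per-grid-cell tallies of an integer pixel map (labels 0..16 or a colour
// bitmask).  Cells follow the half-open mm convention: cell (i, j) (0-based)
// owns pixels whose centre falls in [j*W/cols, (j+1)*W/cols) x
// [i*H/rows, (i+1)*H/rows).  Returns, per cell: total pixels, marked
// (non-zero) pixels, and either per-label counts or the OR of bitmasks.
// [[Rcpp::export]]
List cell_tally_cpp(IntegerMatrix X, double sheet_w_mm, double sheet_h_mm,
                    double px_per_mm, int grid_rows, int grid_cols,
                    bool bitmask) {
  const int H = X.nrow(), W = X.ncol();
  const double cw = sheet_w_mm / grid_cols, ch = sheet_h_mm / grid_rows;
  const int ncell = grid_rows * grid_cols;
  IntegerVector total(ncell), marked(ncell), ormask(ncell);
  IntegerMatrix counts(ncell, 17);   // label 0..16 by column
  std::vector<int> colcell(W), rowcell(H);
  for (int c = 0; c < W; ++c) {
    int j = (int) std::floor(((c + 0.5) / px_per_mm) / cw);
    colcell[c] = std::min(j, grid_cols - 1);
  }
  for (int r = 0; r < H; ++r) {
    int i = (int) std::floor(((r + 0.5) / px_per_mm) / ch);
    rowcell[r] = std::min(i, grid_rows - 1);
  }
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int cell = rowcell[r] * grid_cols + colcell[c];
      total[cell]++;
      int v = X(r, c);
      if (v != 0) {
        marked[cell]++;
        if (bitmask) ormask[cell] |= v;
      }
      if (!bitmask && v >= 0 && v <= 16) counts(cell, v)++;
    }
  }
  return List::create(_["total"] = total, _["marked"] = marked,
                      _["ormask"] = ormask, _["counts"] = counts);
}

// All transverse crossings between non-adjacent segments of one polyline.
// Endpoint touches (t or u at 0/1) are excluded, so a stroke revisiting a
// vertex exactly does not register a crossing.  Returns a matrix with one
// row per crossing: seg_i, seg_j (1-based), t_i, t_j, incidence angle (deg,
// 0..90).
// [[Rcpp::export]]
NumericMatrix seg_intersections_cpp(NumericMatrix P) {
  const int n = P.nrow() - 1;   // number of segments
  std::vector<double> out;
  const double eps = 1e-9;
  for (int i = 0; i < n; ++i) {
    double ax = P(i, 0), ay = P(i, 1);
    double bx = P(i + 1, 0), by = P(i + 1, 1);
    double r1x = bx - ax, r1y = by - ay;
    for (int j = i + 2; j < n; ++j) {
      double cx = P(j, 0), cy = P(j, 1);
      double dx2 = P(j + 1, 0), dy2 = P(j + 1, 1);
      double r2x = dx2 - cx, r2y = dy2 - cy;
      double den = r1x * r2y - r1y * r2x;
      if (std::fabs(den) < 1e-12) continue;      // parallel: not transverse
      double qx = cx - ax, qy = cy - ay;
      double t = (qx * r2y - qy * r2x) / den;
      double u = (qx * r1y - qy * r1x) / den;
      if (t <= eps || t >= 1.0 - eps || u <= eps || u >= 1.0 - eps) continue;
      double n1 = std::sqrt(r1x * r1x + r1y * r1y);
      double n2 = std::sqrt(r2x * r2x + r2y * r2y);
      double ca = std::fabs(r1x * r2x + r1y * r2y) / (n1 * n2);
      if (ca > 1.0) ca = 1.0;
      double ang = std::acos(ca) * 180.0 / M_PI;
      out.push_back(i + 1); out.push_back(j + 1);
      out.push_back(t); out.push_back(u); out.push_back(ang);
    }
  }
  NumericMatrix M(out.size() / 5, 5);
  for (int k = 0; k < M.nrow(); ++k)
    for (int l = 0; l < 5; ++l) M(k, l) = out[5 * k + l];
  colnames(M) = CharacterVector::create("seg_i", "seg_j", "t_i", "t_j", "angle");
  return M;
}
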