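#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Parallel-beam forward projector. The volume is an R array with dim
// (ny, nx, nz); in-plane slices must be square (ny == nx). Rotation is about
// the z (vertical) axis. For detector column u (0-based) the ray coordinate is
// s = u - cu - cor_offset, so a positive cor_offset moves the image of the
// rotation axis to the right of the detector center. Bilinear interpolation,
// zero outside the grid. Returns an array with dim (nz, W, n_angles), W = nx.
// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol, IntegerVector dims,
                                  NumericVector angles, double cor_offset) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const int W = nx, na = angles.size();
  if (ny != nx) stop("in-plane slices must be square (ny == nx)");
  NumericVector out(static_cast<R_xlen_t>(nz) * W * na);
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cu = (W - 1) / 2.0;
  const double* v = vol.begin();
  double* o = out.begin();

  for (int a = 0; a < na; ++a) {
    const double c = std::cos(angles[a]), s = std::sin(angles[a]);
    for (int u = 0; u < W; ++u) {
      const double su = u - cu - cor_offset;
      double* frame_col = o + static_cast<R_xlen_t>(nz) * (u + static_cast<R_xlen_t>(W) * a);
      for (int t = 0; t < W; ++t) {
        const double tt = t - cu;
        const double x = cx + su * c - tt * s;
        const double y = cy + su * s + tt * c;
        if (x < -1.0 || x > nx || y < -1.0 || y > ny) continue;
        const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
        const double fx = x - x0, fy = y - y0;
        // corner weights; voxels outside the grid contribute zero
        const bool okx0 = x0 >= 0 && x0 < nx, okx1 = x0 + 1 >= 0 && x0 + 1 < nx;
        const bool oky0 = y0 >= 0 && y0 < ny, oky1 = y0 + 1 >= 0 && y0 + 1 < ny;
        const double w00 = (1 - fx) * (1 - fy), w01 = fx * (1 - fy);
        const double w10 = (1 - fx) * fy, w11 = fx * fy;
        // element (y, x, z) sits at y + ny*(x + nx*z)
        const R_xlen_t zstride = static_cast<R_xlen_t>(ny) * nx;
        const R_xlen_t i00 = (okx0 && oky0) ? y0 + static_cast<R_xlen_t>(ny) * x0 : -1;
        const R_xlen_t i01 = (okx1 && oky0) ? y0 + static_cast<R_xlen_t>(ny) * (x0 + 1) : -1;
        const R_xlen_t i10 = (okx0 && oky1) ? (y0 + 1) + static_cast<R_xlen_t>(ny) * x0 : -1;
        const R_xlen_t i11 = (okx1 && oky1) ? (y0 + 1) + static_cast<R_xlen_t>(ny) * (x0 + 1) : -1;
        if (i00 >= 0 && i01 >= 0 && i10 >= 0 && i11 >= 0) {
          for (int z = 0; z < nz; ++z) {
            const R_xlen_t base = static_cast<R_xlen_t>(z) * zstride;
            frame_col[z] += w00 * v[base + i00] + w01 * v[base + i01] +
                            w10 * v[base + i10] + w11 * v[base + i11];
          }
        } else {
          for (int z = 0; z < nz; ++z) {
            const R_xlen_t base = static_cast<R_xlen_t>(z) * zstride;
            double acc = 0.0;
            if (i00 >= 0) acc += w00 * v[base + i00];
            if (i01 >= 0) acc += w01 * v[base + i01];
            if (i10 >= 0) acc += w10 * v[base + i10];
            if (i11 >= 0) acc += w11 * v[base + i11];
            frame_col[z] += acc;
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nz, W, na);
  return out;
}

// Back-projection of one filtered sinogram (n_angles x W) onto a W x W
// section. Geometry matches cpp_forward_project with cor_offset = 0:
// u = cu + (x - cx) cos(theta) + (y - cy) sin(theta). Linear interpolation
// along the detector row; rays falling outside the detector contribute zero.
// The caller applies the pi / (2 n_angles) scaling.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix sino, NumericVector angles) {
  const int na = sino.nrow(), W = sino.ncol();
  if (na != angles.size()) stop("sinogram rows must match angle count");
  NumericMatrix out(W, W); // (y, x)
  const double cx = (W - 1) / 2.0, cy = (W - 1) / 2.0, cu = (W - 1) / 2.0;
  for (int a = 0; a < na; ++a) {
    const double c = std::cos(angles[a]), s = std::sin(angles[a]);
    const double* row = &sino(a, 0); // stride na
    for (int x = 0; x < W; ++x) {
      const double xc = (x - cx) * c + cu;
      double* ocol = &out(0, x);
      for (int y = 0; y < W; ++y) {
        const double u = xc + (y - cy) * s;
        if (u < 0.0 || u > W - 1) continue;
        const int u0 = (int)u;
        const double fu = u - u0;
        const double lo = row[static_cast<R_xlen_t>(u0) * na];
        const double hi = (u0 + 1 < W) ? row[static_cast<R_xlen_t>(u0 + 1) * na] : lo;
        ocol[y] += (1 - fu) * lo + fu * hi;
      }
    }
  }
  return out;
}

// 3D connected-component labeling by flood fill. mask is a logical/integer
// vector over dim (ny, nx, nz); connectivity is 6, 18 or 26. Labels are
// assigned consecutively from 1 in raster-scan order of each component's
// first voxel.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(ny) * nx * nz;
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  IntegerVector labels(n, 0);
  // neighbour offsets in (dy, dx, dz)
  std::vector<int> dy, dx, dz;
  for (int az = -1; az <= 1; ++az)
    for (int ax = -1; ax <= 1; ++ax)
      for (int ay = -1; ay <= 1; ++ay) {
        const int nn = std::abs(ax) + std::abs(ay) + std::abs(az);
        if (nn == 0) continue;
        if (connectivity == 6 && nn > 1) continue;
        if (connectivity == 18 && nn > 2) continue;
        dy.push_back(ay); dx.push_back(ax); dz.push_back(az);
      }
  const int nb = (int)dy.size();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i]) continue;
    ++next;
    labels[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int y = (int)(cur % ny);
      const int x = (int)((cur / ny) % nx);
      const int z = (int)(cur / (static_cast<R_xlen_t>(ny) * nx));
      for (int k = 0; k < nb; ++k) {
        const int yy = y + dy[k], xx = x + dx[k], zz = z + dz[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) continue;
        const R_xlen_t j = yy + static_cast<R_xlen_t>(ny) * (xx + static_cast<R_xlen_t>(nx) * zz);
        if (mask[j] && !labels[j]) {
          labels[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// Binary dilation (erode = dilate the complement) with an arbitrary offset
// list (k x 3 matrix of dy, dx, dz). Out-of-bounds neighbours are treated as
// background for dilation.
// [[Rcpp::export]]
LogicalVector cpp_dilate3d(LogicalVector mask, IntegerVector dims, IntegerMatrix offsets) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(ny) * nx * nz;
  LogicalVector out(n, false);
  const int k = offsets.nrow();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    const int y = (int)(i % ny);
    const int x = (int)((i / ny) % nx);
    const int z = (int)(i / (static_cast<R_xlen_t>(ny) * nx));
    for (int o = 0; o < k; ++o) {
      const int yy = y + offsets(o, 0), xx = x + offsets(o, 1), zz = z + offsets(o, 2);
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) continue;
      out[yy + static_cast<R_xlen_t>(ny) * (xx + static_cast<R_xlen_t>(nx) * zz)] = true;
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Separable box (running-mean) blur along one axis (0 = y, 1 = x, 2 = z),
// repeated `passes` times; values outside the grid are treated as zero.
// Three passes approximate a Gaussian closely (central limit of the uniform
// kernel) at O(1) cost per voxel.
// [[Rcpp::export]]
NumericVector cpp_box_blur_axis(NumericVector vol, IntegerVector dims,
                                int radius, int axis, int passes) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(ny) * nx * nz;
  NumericVector out = clone(vol);
  double* o = out.begin();
  const int len = (axis == 0) ? ny : (axis == 1) ? nx : nz;
  const R_xlen_t stride = (axis == 0) ? 1
                        : (axis == 1) ? static_cast<R_xlen_t>(ny)
                                      : static_cast<R_xlen_t>(ny) * nx;
  const R_xlen_t nlines = n / len;
  const double norm = 1.0 / (2 * radius + 1);
  std::vector<double> line(len);
  for (int p = 0; p < passes; ++p) {
    for (R_xlen_t li = 0; li < nlines; ++li) {
      R_xlen_t base;
      if (axis == 0) {
        base = li * ny;
      } else if (axis == 1) {
        const R_xlen_t y = li % ny, z = li / ny;
        base = y + static_cast<R_xlen_t>(ny) * nx * z;
      } else {
        base = li;
      }
      for (int t = 0; t < len; ++t) line[t] = o[base + stride * t];
      double acc = 0.0;
      for (int t = 0; t < std::min(radius + 1, len); ++t) acc += line[t];
      for (int t = 0; t < len; ++t) {
        o[base + stride * t] = acc * norm;
        const int add = t + radius + 1, drop = t - radius;
        if (add < len) acc += line[add];
        if (drop >= 0) acc -= line[drop];
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Per-label reductions over a label volume and a matched intensity volume:
// voxel count, intensity sum / max, centroid sums, and bounding boxes.
// Returns a list of numeric matrices indexed by label 1..nlab.
// [[Rcpp::export]]
List cpp_label_stats(IntegerVector labels, IntegerVector dims, NumericVector intensity) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(ny) * nx * nz;
  const bool has_int = intensity.size() == n;
  int nlab = 0;
  for (R_xlen_t i = 0; i < n; ++i) if (labels[i] > nlab) nlab = labels[i];
  NumericVector count(nlab), isum(nlab), imax(nlab, R_NegInf);
  NumericVector cy(nlab), cx(nlab), cz(nlab);
  IntegerVector ymin(nlab, ny), ymax(nlab, -1), xmin(nlab, nx), xmax(nlab, -1),
      zmin(nlab, nz), zmax(nlab, -1);
  for (R_xlen_t i = 0; i < n; ++i) {
    const int l = labels[i];
    if (l <= 0) continue;
    const int y = (int)(i % ny);
    const int x = (int)((i / ny) % nx);
    const int z = (int)(i / (static_cast<R_xlen_t>(ny) * nx));
    const int j = l - 1;
    count[j] += 1;
    cy[j] += y; cx[j] += x; cz[j] += z;
    if (y < ymin[j]) ymin[j] = y;
    if (y > ymax[j]) ymax[j] = y;
    if (x < xmin[j]) xmin[j] = x;
    if (x > xmax[j]) xmax[j] = x;
    if (z < zmin[j]) zmin[j] = z;
    if (z > zmax[j]) zmax[j] = z;
    if (has_int) {
      isum[j] += intensity[i];
      if (intensity[i] > imax[j]) imax[j] = intensity[i];
    }
  }
  for (int j = 0; j < nlab; ++j) {
    if (count[j] > 0) { cy[j] /= count[j]; cx[j] /= count[j]; cz[j] /= count[j]; }
  }
  return List::create(_["count"] = count, _["sum"] = isum, _["max"] = imax,
                      _["cy"] = cy, _["cx"] = cx, _["cz"] = cz,
                      _["ymin"] = ymin, _["ymax"] = ymax,
                      _["xmin"] = xmin, _["xmax"] = xmax,
                      _["zmin"] = zmin, _["zmax"] = zmax);
}
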