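#include <Rcpp.h>
#include <vector>
#include <array>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Volumes are R arrays with dim = (nz, ny, nx), column-major, so the linear
// index of (z, y, x) (0-based) is z + nz * (y + ny * x).

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---- 3D median (27-neighborhood majority vote, edge replication) ----------

// Separable 3x3x3 box sum (clamped/replicated borders), thresholded at the
// majority count 14.
// [[Rcpp::export]]
IntegerVector cpp_median3d(const IntegerVector& bin, int nz, int ny, int nx) {
  long n = (long)nz * ny * nx;
  std::vector<short> t1(n), t2(n);
  // sum along z (fastest axis)
  for (long c = 0; c < n; c += nz) {
    for (int z = 0; z < nz; ++z) {
      int zm = clampi(z - 1, 0, nz - 1), zp = clampi(z + 1, 0, nz - 1);
      t1[c + z] = (short)(bin[c + zm] + bin[c + z] + bin[c + zp]);
    }
  }
  // sum along y (stride nz within each x-plane)
  for (int x = 0; x < nx; ++x) {
    long p = (long)nz * ny * x;
    for (int y = 0; y < ny; ++y) {
      int ym = clampi(y - 1, 0, ny - 1), yp = clampi(y + 1, 0, ny - 1);
      long ry = p + (long)nz * y, rm = p + (long)nz * ym, rp = p + (long)nz * yp;
      for (int z = 0; z < nz; ++z)
        t2[ry + z] = (short)(t1[rm + z] + t1[ry + z] + t1[rp + z]);
    }
  }
  // sum along x (stride nz*ny)
  IntegerVector out(bin.size());
  long s = (long)nz * ny;
  for (int x = 0; x < nx; ++x) {
    int xm = clampi(x - 1, 0, nx - 1), xp = clampi(x + 1, 0, nx - 1);
    long rx = s * x, rm = s * xm, rp = s * xp;
    for (long i = 0; i < s; ++i)
      out[rx + i] = (t2[rm + i] + t2[rx + i] + t2[rp + i]) >= 14 ? 1 : 0;
  }
  return out;
}

// ---- 3D erosion (cross = 6 face neighbors, or full 3x3x3 cube) ------------
// Outside the array counts as background, so border voxels erode.

// [[Rcpp::export]]
IntegerVector cpp_erode3d(const IntegerVector& bin, int nz, int ny, int nx,
                          int iterations, bool cube) {
  std::vector<unsigned char> cur(bin.begin(), bin.end());
  std::vector<unsigned char> nxt(cur.size());
  for (int it = 0; it < iterations; ++it) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        for (int z = 0; z < nz; ++z) {
          long idx = z + (long)nz * (y + (long)ny * x);
          if (!cur[idx]) { nxt[idx] = 0; continue; }
          bool keep = true;
          if (cube) {
            for (int dx = -1; dx <= 1 && keep; ++dx)
              for (int dy = -1; dy <= 1 && keep; ++dy)
                for (int dz = -1; dz <= 1 && keep; ++dz) {
                  int xx = x + dx, yy = y + dy, zz = z + dz;
                  if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                      zz < 0 || zz >= nz) { keep = false; break; }
                  if (!cur[zz + (long)nz * (yy + (long)ny * xx)]) keep = false;
                }
          } else {
            const int d[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
            for (int k = 0; k < 6 && keep; ++k) {
              int zz = z + d[k][0], yy = y + d[k][1], xx = x + d[k][2];
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                  xx < 0 || xx >= nx) { keep = false; break; }
              if (!cur[zz + (long)nz * (yy + (long)ny * xx)]) keep = false;
            }
          }
          nxt[idx] = keep ? 1 : 0;
        }
      }
    }
    cur.swap(nxt);
  }
  return IntegerVector(cur.begin(), cur.end());
}

// ---- neighbor offset tables -----------------------------------------------

static void offsets_for(int connectivity, std::vector<std::array<int,3> >& off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dz, dy, dx});
      }
}

// ---- seeded flood fill (connected component containing seed) --------------

// [[Rcpp::export]]
IntegerVector cpp_flood(const IntegerVector& bin, int nz, int ny, int nx,
                        int seed_z, int seed_y, int seed_x, int connectivity) {
  IntegerVector out(bin.size(), 0);
  long seed = seed_z + (long)nz * (seed_y + (long)ny * seed_x);
  if (!bin[seed]) stop("seed voxel is background");
  std::vector<std::array<int,3> > off;
  offsets_for(connectivity, off);
  std::vector<unsigned char> seen(bin.size(), 0);
  std::queue<std::array<int,3> > q;
  q.push({seed_z, seed_y, seed_x});
  seen[seed] = 1; out[seed] = 1;
  while (!q.empty()) {
    std::array<int,3> p = q.front(); q.pop();
    for (size_t k = 0; k < off.size(); ++k) {
      int zz = p[0] + off[k][0], yy = p[1] + off[k][1], xx = p[2] + off[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      long idx = zz + (long)nz * (yy + (long)ny * xx);
      if (seen[idx] || !bin[idx]) continue;
      seen[idx] = 1; out[idx] = 1;
      q.push({zz, yy, xx});
    }
  }
  return out;
}

// ---- full component labeling ----------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(const IntegerVector& bin, int nz, int ny,
                                   int nx, int connectivity) {
  IntegerVector lab(bin.size(), 0);
  std::vector<std::array<int,3> > off;
  offsets_for(connectivity, off);
  int next = 0;
  for (long i = 0; i < (long)bin.size(); ++i) {
    if (!bin[i] || lab[i]) continue;
    ++next;
    std::queue<long> q;
    q.push(i); lab[i] = next;
    while (!q.empty()) {
      long cur = q.front(); q.pop();
      int z = (int)(cur % nz);
      int y = (int)((cur / nz) % ny);
      int x = (int)(cur / ((long)nz * ny));
      for (size_t k = 0; k < off.size(); ++k) {
        int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        long idx = zz + (long)nz * (yy + (long)ny * xx);
        if (bin[idx] && !lab[idx]) { lab[idx] = next; q.push(idx); }
      }
    }
  }
  return lab;
}

// ---- nearest foreground voxel to a (background) position -------------------

// [[Rcpp::export]]
IntegerVector cpp_nearest_fg(const IntegerVector& bin, int nz, int ny, int nx,
                             int seed_z, int seed_y, int seed_x) {
  // BFS over the full grid (26-connectivity) from the seed position.
  std::vector<std::array<int,3> > off;
  offsets_for(26, off);
  std::vector<unsigned char> seen(bin.size(), 0);
  std::queue<std::array<int,3> > q;
  q.push({seed_z, seed_y, seed_x});
  seen[seed_z + (long)nz * (seed_y + (long)ny * seed_x)] = 1;
  while (!q.empty()) {
    std::array<int,3> p = q.front(); q.pop();
    long idx = p[0] + (long)nz * (p[1] + (long)ny * p[2]);
    if (bin[idx]) return IntegerVector::create(p[0], p[1], p[2]);
    for (size_t k = 0; k < off.size(); ++k) {
      int zz = p[0] + off[k][0], yy = p[1] + off[k][1], xx = p[2] + off[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      long j = zz + (long)nz * (yy + (long)ny * xx);
      if (!seen[j]) { seen[j] = 1; q.push({zz, yy, xx}); }
    }
  }
  return IntegerVector::create(-1, -1, -1);
}

// ---- 26-neighbor counts within a binary set --------------------------------

// [[Rcpp::export]]
IntegerVector cpp_neighbor_counts(const IntegerVector& bin, int nz, int ny, int nx) {
  IntegerVector out(bin.size(), -1);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        long idx = z + (long)nz * (y + (long)ny * x);
        if (!bin[idx]) continue;
        int c = 0;
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              if (dz == 0 && dy == 0 && dx == 0) continue;
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                continue;
              if (bin[zz + (long)nz * (yy + (long)ny * xx)]) ++c;
            }
        out[idx] = c;
      }
  return out;
}

// ---- 2D Sobel gradient magnitude, slice by slice ---------------------------
// Border handling by edge replication. Kernels: Gx = [-1 0 1; -2 0 2; -1 0 1]
// over (y rows, x cols), Gy its transpose; magnitude sqrt(Gx^2 + Gy^2).

// [[Rcpp::export]]
NumericVector cpp_sobel2d(const NumericVector& vol, int nz, int ny, int nx) {
  NumericVector out(vol.size());
  // copy each z-slice into a contiguous (y fastest) buffer for locality
  std::vector<double> sl((size_t)ny * nx);
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        sl[y + (size_t)ny * x] = vol[z + (long)nz * (y + (long)ny * x)];
    for (int x = 0; x < nx; ++x) {
      int xm = clampi(x - 1, 0, nx - 1), xp = clampi(x + 1, 0, nx - 1);
      const double* cm = &sl[(size_t)ny * xm];
      const double* cc = &sl[(size_t)ny * x];
      const double* cp = &sl[(size_t)ny * xp];
      for (int y = 0; y < ny; ++y) {
        int ym = clampi(y - 1, 0, ny - 1), yp = clampi(y + 1, 0, ny - 1);
        double gx = (cp[ym] + 2.0 * cp[y] + cp[yp]) -
                    (cm[ym] + 2.0 * cm[y] + cm[yp]);
        double gy = (cm[yp] + 2.0 * cc[yp] + cp[yp]) -
                    (cm[ym] + 2.0 * cc[ym] + cp[ym]);
        out[z + (long)nz * (y + (long)ny * x)] = std::sqrt(gx * gx + gy * gy);
      }
    }
  }
  return out;
}

// ---- topology helpers for thinning ----------------------------------------

// Foreground 26-connectivity components within the 26-neighborhood (center
// excluded); background 6-connectivity components within the 18-neighborhood
// seeded at face neighbors. A voxel is simple iff both counts are 1
// (Malandain & Bertrand characterization for (26, 6) digital topology).
static bool is_simple(const std::vector<unsigned char>& v,
                      long Nz, long Ny, int z, int y, int x) {
  unsigned char nb[3][3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      for (int c = 0; c < 3; ++c)
        nb[a][b][c] = v[(z + a - 1) + Nz * ((y + b - 1) + Ny * (x + c - 1))];
  nb[1][1][1] = 0;

  // C*: 26-components of foreground in N26
  int lab[27];
  for (int i = 0; i < 27; ++i) lab[i] = 0;
  int ncomp = 0;
  int stack[27];
  for (int i = 0; i < 27; ++i) {
    int a = i / 9, b = (i / 3) % 3, c = i % 3;
    if (i == 13 || !nb[a][b][c] || lab[i]) continue;
    ++ncomp;
    if (ncomp > 1) return false;
    int top = 0;
    stack[top++] = i; lab[i] = ncomp;
    while (top > 0) {
      int j = stack[--top];
      int ja = j / 9, jb = (j / 3) % 3, jc = j % 3;
      for (int da = -1; da <= 1; ++da)
        for (int db = -1; db <= 1; ++db)
          for (int dc = -1; dc <= 1; ++dc) {
            int ka = ja + da, kb = jb + db, kc = jc + dc;
            if (ka < 0 || ka > 2 || kb < 0 || kb > 2 || kc < 0 || kc > 2) continue;
            int k = ka * 9 + kb * 3 + kc;
            if (k == 13 || k == j) continue;
            if (nb[ka][kb][kc] && !lab[k]) { lab[k] = ncomp; stack[top++] = k; }
          }
    }
  }
  if (ncomp != 1) return false;

  // C-bar: 6-components of background within N18, seeded at the 6 face
  // neighbors, with 6-connected paths restricted to N18.
  for (int i = 0; i < 27; ++i) lab[i] = 0;
  const int faces[6] = {4, 22, 10, 16, 12, 14}; // (0,1,1),(2,1,1),(1,0,1),(1,2,1),(1,1,0),(1,1,2)
  int nbg = 0;
  for (int f = 0; f < 6; ++f) {
    int i = faces[f];
    int a = i / 9, b = (i / 3) % 3, c = i % 3;
    if (nb[a][b][c] || lab[i]) continue;
    ++nbg;
    if (nbg > 1) return false;
    int top = 0;
    stack[top++] = i; lab[i] = nbg;
    while (top > 0) {
      int j = stack[--top];
      int ja = j / 9, jb = (j / 3) % 3, jc = j % 3;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k6 = 0; k6 < 6; ++k6) {
        int ka = ja + d6[k6][0], kb = jb + d6[k6][1], kc = jc + d6[k6][2];
        if (ka < 0 || ka > 2 || kb < 0 || kb > 2 || kc < 0 || kc > 2) continue;
        int manh = std::abs(ka - 1) + std::abs(kb - 1) + std::abs(kc - 1);
        if (manh > 2) continue; // restrict to N18
        int k = ka * 9 + kb * 3 + kc;
        if (k == 13) continue;
        if (!nb[ka][kb][kc] && !lab[k]) { lab[k] = nbg; stack[top++] = k; }
      }
    }
  }
  return nbg == 1;
}

static int count26(const std::vector<unsigned char>& v, long Nz, long Ny,
                   int z, int y, int x) {
  int c = 0;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int d = -1; d <= 1; ++d) {
        if (a == 0 && b == 0 && d == 0) continue;
        if (v[(z + a) + Nz * ((y + b) + Ny * (x + d))]) ++c;
      }
  return c;
}

// ---- 3D thinning to a unit-width curve skeleton ----------------------------
// Directional border peeling (6 subiterations per cycle) deleting simple,
// non-endpoint voxels, with sequential re-checking so topology is preserved
// exactly. Optionally extends each resulting tip along its local branch
// direction while still inside the original foreground, to compensate the
// end retraction inherent to iterative thinning.

// [[Rcpp::export]]
IntegerVector cpp_thin3d(const IntegerVector& bin, int nz, int ny, int nx,
                         bool extend_tips) {
  long Nz = nz + 2, Ny = ny + 2, Nx = nx + 2;
  std::vector<unsigned char> v(Nz * Ny * Nx, 0), orig;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z)
        v[(z + 1) + Nz * ((y + 1) + Ny * (x + 1))] =
          bin[z + (long)nz * (y + (long)ny * x)] ? 1 : 0;
  orig = v;

  const int dirs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  std::vector<long> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int x = 1; x <= nx; ++x)
        for (int y = 1; y <= ny; ++y)
          for (int z = 1; z <= nz; ++z) {
            long idx = z + Nz * (y + Ny * x);
            if (!v[idx]) continue;
            long bidx = (z + dirs[d][0]) + Nz * ((y + dirs[d][1]) + Ny * (x + dirs[d][2]));
            if (v[bidx]) continue; // not a border point in direction d
            if (count26(v, Nz, Ny, z, y, x) <= 1) continue; // endpoint/isolated
            if (is_simple(v, Nz, Ny, z, y, x)) cand.push_back(idx);
          }
      for (size_t i = 0; i < cand.size(); ++i) {
        long idx = cand[i];
        int z = (int)(idx % Nz);
        int y = (int)((idx / Nz) % Ny);
        int x = (int)(idx / (Nz * Ny));
        if (count26(v, Nz, Ny, z, y, x) <= 1) continue;
        if (!is_simple(v, Nz, Ny, z, y, x)) continue;
        v[idx] = 0;
        changed = true;
      }
    }
  }

  if (extend_tips) {
    // collect tips of the thinned skeleton
    std::vector<std::array<int,3> > tips;
    for (int x = 1; x <= nx; ++x)
      for (int y = 1; y <= ny; ++y)
        for (int z = 1; z <= nz; ++z) {
          long idx = z + Nz * (y + Ny * x);
          if (v[idx] && count26(v, Nz, Ny, z, y, x) == 1) tips.push_back({z, y, x});
        }
    for (size_t t = 0; t < tips.size(); ++t) {
      // walk back up to 4 unambiguous steps to estimate the tip direction
      int cz = tips[t][0], cy = tips[t][1], cx = tips[t][2];
      int pz = -1, py = -1, px = -1;
      int bz = cz, by = cy, bx = cx;
      for (int step = 0; step < 4; ++step) {
        int nzv = -1, nyv = -1, nxv = -1, nfound = 0;
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
              if (a == 0 && b == 0 && c == 0) continue;
              int zz = bz + a, yy = by + b, xx = bx + c;
              if (zz == pz && yy == py && xx == px) continue;
              if (v[zz + Nz * (yy + Ny * xx)]) { ++nfound; nzv = zz; nyv = yy; nxv = xx; }
            }
        if (nfound != 1) break;
        pz = bz; py = by; px = bx;
        bz = nzv; by = nyv; bx = nxv;
      }
      double dz = tips[t][0] - bz, dy = tips[t][1] - by, dx = tips[t][2] - bx;
      double nrm = std::sqrt(dz * dz + dy * dy + dx * dx);
      if (nrm < 1e-9) continue;
      dz /= nrm; dy /= nrm; dx /= nrm;
      // local radius at the tip: Chebyshev distance to the nearest
      // background voxel in the original volume; caps the extension so a
      // spurious surface tip cannot run through the object interior
      int rloc = 30;
      for (int rad = 1; rad <= 30 && rloc == 30; ++rad) {
        for (int a = -rad; a <= rad && rloc == 30; ++a)
          for (int b = -rad; b <= rad && rloc == 30; ++b)
            for (int c = -rad; c <= rad; ++c) {
              if (std::max(std::abs(a), std::max(std::abs(b), std::abs(c))) != rad)
                continue;
              int zz = tips[t][0] + a, yy = tips[t][1] + b, xx = tips[t][2] + c;
              if (zz < 0 || zz >= (int)Nz || yy < 0 || yy >= (int)Ny ||
                  xx < 0 || xx >= (int)Nx) { rloc = rad; break; }
              if (!orig[zz + Nz * (yy + Ny * xx)]) { rloc = rad; break; }
            }
      }
      double max_len = 2.0 * rloc + 2.0, travelled = 0.0;
      double fz = tips[t][0], fy = tips[t][1], fx = tips[t][2];
      int lz = tips[t][0], ly = tips[t][1], lx = tips[t][2];
      for (int step = 0; step < 100000; ++step) {
        fz += 0.45 * dz; fy += 0.45 * dy; fx += 0.45 * dx;
        int rz = (int)std::lround(fz), ry = (int)std::lround(fy), rx = (int)std::lround(fx);
        if (rz == lz && ry == ly && rx == lx) continue;
        if (rz < 1 || rz > nz || ry < 1 || ry > ny || rx < 1 || rx > nx) break;
        long idx = rz + Nz * (ry + Ny * rx);
        if (!orig[idx]) break;
        if (v[idx]) break; // merged into existing skeleton
        double stepd = std::sqrt((double)((rz - lz) * (rz - lz) +
                                          (ry - ly) * (ry - ly) +
                                          (rx - lx) * (rx - lx)));
        if (travelled + stepd > max_len) break;
        travelled += stepd;
        v[idx] = 1;
        lz = rz; ly = ry; lx = rx;
      }
    }
  }

  IntegerVector out(bin.size());
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z)
        out[z + (long)nz * (y + (long)ny * x)] =
          v[(z + 1) + Nz * ((y + 1) + Ny * (x + 1))];
  return out;
}
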