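#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// ---- union-find ------------------------------------------------------------

static int uf_find(std::vector<int>& p, int i) {
  while (p[i] != i) { p[i] = p[p[i]]; i = p[i]; }
  return i;
}

// Connected components over vertices linked by face edges. Returns 1-based
// component labels per vertex (vertices not used by any face keep their own).
// [[Rcpp::export]]
IntegerVector cpp_vertex_components(int nv, IntegerMatrix faces) {
  std::vector<int> p(nv);
  for (int i = 0; i < nv; ++i) p[i] = i;
  for (int f = 0; f < faces.nrow(); ++f) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    int ra = uf_find(p, a), rb = uf_find(p, b), rc = uf_find(p, c);
    p[rb] = ra; p[uf_find(p, rc)] = uf_find(p, ra);
  }
  std::map<int, int> relab;
  IntegerVector out(nv);
  for (int i = 0; i < nv; ++i) {
    int r = uf_find(p, i);
    auto it = relab.find(r);
    if (it == relab.end()) { int id = (int)relab.size() + 1; relab[r] = id; out[i] = id; }
    else out[i] = it->second;
  }
  return out;
}

// ---- point / triangle distance --------------------------------------------

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// squared distance point to triangle (Ericson, Real-Time Collision Detection)
static double pt_tri_d2(const double* p, const double* a, const double* b, const double* c) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i]-a[i]; ac[i] = c[i]-a[i]; ap[i] = p[i]-a[i]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) return ap[0]*ap[0]+ap[1]*ap[1]+ap[2]*ap[2];
  double bp[3]; for (int i=0;i<3;++i) bp[i]=p[i]-b[i];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) return bp[0]*bp[0]+bp[1]*bp[1]+bp[2]*bp[2];
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    double q[3]; for (int i=0;i<3;++i) q[i]=a[i]+v*ab[i]-p[i];
    return q[0]*q[0]+q[1]*q[1]+q[2]*q[2];
  }
  double cp[3]; for (int i=0;i<3;++i) cp[i]=p[i]-c[i];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) return cp[0]*cp[0]+cp[1]*cp[1]+cp[2]*cp[2];
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    double q[3]; for (int i=0;i<3;++i) q[i]=a[i]+w*ac[i]-p[i];
    return q[0]*q[0]+q[1]*q[1]+q[2]*q[2];
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double q[3]; for (int i=0;i<3;++i) q[i]=b[i]+w*(c[i]-b[i])-p[i];
    return q[0]*q[0]+q[1]*q[1]+q[2]*q[2];
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  double q[3]; for (int i=0;i<3;++i) q[i]=a[i]+ab[i]*v+ac[i]*w-p[i];
  return q[0]*q[0]+q[1]*q[1]+q[2]*q[2];
}

// min distance from each query point to a triangle mesh
// [[Rcpp::export]]
NumericVector cpp_point_mesh_distance(NumericMatrix pts, NumericMatrix V, IntegerMatrix F) {
  int np = pts.nrow(), nf = F.nrow();
  NumericVector out(np);
  std::vector<double> vx(V.nrow()*3);
  for (int i = 0; i < V.nrow(); ++i)
    for (int j = 0; j < 3; ++j) vx[3*i+j] = V(i, j);
  for (int ip = 0; ip < np; ++ip) {
    double p[3] = { pts(ip,0), pts(ip,1), pts(ip,2) };
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      const double* a = &vx[3*(F(f,0)-1)];
      const double* b = &vx[3*(F(f,1)-1)];
      const double* c = &vx[3*(F(f,2)-1)];
      double d2 = pt_tri_d2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[ip] = std::sqrt(best);
  }
  return out;
}

// Grid-accelerated min distance from query points to a triangle mesh.
// Triangles are binned into a uniform grid by bounding box; queries scan
// expanding Chebyshev shells and stop once the best distance is provably
// smaller than anything in unscanned cells.
// [[Rcpp::export]]
NumericVector cpp_point_mesh_distance_fast(NumericMatrix pts, NumericMatrix V,
                                           IntegerMatrix F) {
  int np = pts.nrow(), nf = F.nrow(), nv = V.nrow();
  NumericVector out(np);
  if (nf == 0) { out.fill(R_PosInf); return out; }
  std::vector<double> vx((size_t)nv * 3);
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) vx[3 * i + j] = V(i, j);
  double lo[3], hi[3];
  for (int j = 0; j < 3; ++j) { lo[j] = R_PosInf; hi[j] = R_NegInf; }
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) {
      if (vx[3 * i + j] < lo[j]) lo[j] = vx[3 * i + j];
      if (vx[3 * i + j] > hi[j]) hi[j] = vx[3 * i + j];
    }
  // cell size: aim at ~ nf cells, bounded to keep memory sane
  double ext = std::max(hi[0] - lo[0], std::max(hi[1] - lo[1], hi[2] - lo[2]));
  if (ext <= 0) ext = 1;
  int nCell = (int)std::ceil(std::cbrt((double)nf));
  nCell = std::max(4, std::min(128, nCell));
  double h = ext / nCell;
  int dims[3];
  for (int j = 0; j < 3; ++j)
    dims[j] = std::max(1, (int)std::ceil((hi[j] - lo[j]) / h) + 1);
  auto cellId = [&](int cx, int cy, int cz) -> size_t {
    return ((size_t)cz * dims[1] + cy) * dims[0] + cx;
  };
  std::vector< std::vector<int> > cells((size_t)dims[0] * dims[1] * dims[2]);
  for (int f = 0; f < nf; ++f) {
    double tlo[3], thi[3];
    for (int j = 0; j < 3; ++j) {
      double a = vx[3 * (F(f, 0) - 1) + j], b = vx[3 * (F(f, 1) - 1) + j],
             c = vx[3 * (F(f, 2) - 1) + j];
      tlo[j] = std::min(a, std::min(b, c));
      thi[j] = std::max(a, std::max(b, c));
    }
    int c0[3], c1[3];
    for (int j = 0; j < 3; ++j) {
      c0[j] = std::max(0, std::min(dims[j] - 1, (int)((tlo[j] - lo[j]) / h)));
      c1[j] = std::max(0, std::min(dims[j] - 1, (int)((thi[j] - lo[j]) / h)));
    }
    for (int cz = c0[2]; cz <= c1[2]; ++cz)
      for (int cy = c0[1]; cy <= c1[1]; ++cy)
        for (int cx = c0[0]; cx <= c1[0]; ++cx)
          cells[cellId(cx, cy, cz)].push_back(f);
  }
  int maxR = dims[0] + dims[1] + dims[2];
  for (int ip = 0; ip < np; ++ip) {
    double p[3] = { pts(ip, 0), pts(ip, 1), pts(ip, 2) };
    int pc[3];
    for (int j = 0; j < 3; ++j)
      pc[j] = std::max(0, std::min(dims[j] - 1, (int)((p[j] - lo[j]) / h)));
    double best = R_PosInf;
    for (int r = 0; r <= maxR; ++r) {
      if (best <= (double)(r - 1) * h && r > 0) break;
      bool any = false;
      int x0 = pc[0] - r, x1 = pc[0] + r;
      int y0 = pc[1] - r, y1 = pc[1] + r;
      int z0 = pc[2] - r, z1 = pc[2] + r;
      for (int cz = std::max(0, z0); cz <= std::min(dims[2] - 1, z1); ++cz)
        for (int cy = std::max(0, y0); cy <= std::min(dims[1] - 1, y1); ++cy)
          for (int cx = std::max(0, x0); cx <= std::min(dims[0] - 1, x1); ++cx) {
            // shell only: skip interior cells already scanned
            if (r > 0 && cx != x0 && cx != x1 && cy != y0 && cy != y1 &&
                cz != z0 && cz != z1) continue;
            any = true;
            const std::vector<int>& cl = cells[cellId(cx, cy, cz)];
            for (int f : cl) {
              double d2 = pt_tri_d2(p, &vx[3 * (F(f, 0) - 1)],
                                    &vx[3 * (F(f, 1) - 1)],
                                    &vx[3 * (F(f, 2) - 1)]);
              if (d2 < best * best) best = std::sqrt(d2);
            }
          }
      if (!any && r > 0 && (x0 < 0 && x1 >= dims[0] && y0 < 0 &&
                            y1 >= dims[1] && z0 < 0 && z1 >= dims[2]))
        break;  // grid exhausted
    }
    out[ip] = best;
  }
  return out;
}

// min distance from each query point to a 3D polyline (open)
// [[Rcpp::export]]
NumericVector cpp_point_polyline_distance(NumericMatrix pts, NumericMatrix poly) {
  int np = pts.nrow(), ns = poly.nrow() - 1;
  NumericVector out(np);
  for (int ip = 0; ip < np; ++ip) {
    double best = R_PosInf;
    for (int s = 0; s < ns; ++s) {
      double ax = poly(s,0), ay = poly(s,1), az = poly(s,2);
      double bx = poly(s+1,0)-ax, by = poly(s+1,1)-ay, bz = poly(s+1,2)-az;
      double px = pts(ip,0)-ax, py = pts(ip,1)-ay, pz = pts(ip,2)-az;
      double den = bx*bx+by*by+bz*bz;
      double t = den > 0 ? clampd((px*bx+py*by+pz*bz)/den, 0.0, 1.0) : 0.0;
      double dx = px-t*bx, dy = py-t*by, dz = pz-t*bz;
      double d2 = dx*dx+dy*dy+dz*dz;
      if (d2 < best) best = d2;
    }
    out[ip] = std::sqrt(best);
  }
  return out;
}

// ---- z-column ray casting --------------------------------------------------

// For each query point, count intersections of the upward +z ray with the mesh;
// odd count => inside. Query xy jittered by caller to avoid edge hits.
// [[Rcpp::export]]
LogicalVector cpp_points_inside(NumericMatrix pts, NumericMatrix V, IntegerMatrix F) {
  int np = pts.nrow(), nf = F.nrow();
  LogicalVector out(np);
  for (int ip = 0; ip < np; ++ip) {
    double x = pts(ip,0), y = pts(ip,1), z = pts(ip,2);
    int cross = 0;
    for (int f = 0; f < nf; ++f) {
      double ax = V(F(f,0)-1,0), ay = V(F(f,0)-1,1), az = V(F(f,0)-1,2);
      double bx = V(F(f,1)-1,0), by = V(F(f,1)-1,1), bz = V(F(f,1)-1,2);
      double cx = V(F(f,2)-1,0), cy = V(F(f,2)-1,1), cz = V(F(f,2)-1,2);
      // 2D barycentric in xy
      double d = (by-cy)*(ax-cx) + (cx-bx)*(ay-cy);
      if (d == 0) continue;
      double l1 = ((by-cy)*(x-cx) + (cx-bx)*(y-cy)) / d;
      double l2 = ((cy-ay)*(x-cx) + (ax-cx)*(y-cy)) / d;
      double l3 = 1.0 - l1 - l2;
      if (l1 < 0 || l2 < 0 || l3 < 0) continue;
      double zt = l1*az + l2*bz + l3*cz;
      if (zt > z) ++cross;
    }
    out[ip] = (cross % 2) == 1;
  }
  return out;
}

// All z crossings of vertical grid columns with a mesh.  Grid columns are at
// x0 + i*h, y0 + j*h (i in 0..nx-1, j in 0..ny-1), jittered internally by a
// tiny deterministic epsilon to dodge exact edge hits.  Returns a list with
// per-column sorted crossing heights.
// [[Rcpp::export]]
List cpp_column_crossings(NumericMatrix V, IntegerMatrix F,
                          double x0, double y0, double h, int nx, int ny) {
  std::vector< std::vector<double> > cols((size_t)nx * ny);
  const double jx = h * 1e-4, jy = h * 7e-5;  // deterministic jitter
  int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    double ax = V(F(f,0)-1,0), ay = V(F(f,0)-1,1), az = V(F(f,0)-1,2);
    double bx = V(F(f,1)-1,0), by = V(F(f,1)-1,1), bz = V(F(f,1)-1,2);
    double cx = V(F(f,2)-1,0), cy = V(F(f,2)-1,1), cz = V(F(f,2)-1,2);
    double mnx = std::min(ax, std::min(bx, cx)), mxx = std::max(ax, std::max(bx, cx));
    double mny = std::min(ay, std::min(by, cy)), mxy = std::max(ay, std::max(by, cy));
    int i0 = std::max(0, (int)std::ceil((mnx - jx - x0) / h) - 1);
    int i1 = std::min(nx - 1, (int)std::floor((mxx - jx - x0) / h) + 1);
    int j0 = std::max(0, (int)std::ceil((mny - jy - y0) / h) - 1);
    int j1 = std::min(ny - 1, (int)std::floor((mxy - jy - y0) / h) + 1);
    double d = (by-cy)*(ax-cx) + (cx-bx)*(ay-cy);
    if (d == 0) continue;
    for (int i = i0; i <= i1; ++i) {
      double x = x0 + i * h + jx;
      for (int j = j0; j <= j1; ++j) {
        double y = y0 + j * h + jy;
        double l1 = ((by-cy)*(x-cx) + (cx-bx)*(y-cy)) / d;
        double l2 = ((cy-ay)*(x-cx) + (ax-cx)*(y-cy)) / d;
        double l3 = 1.0 - l1 - l2;
        if (l1 < 0 || l2 < 0 || l3 < 0) continue;
        cols[(size_t)j * nx + i].push_back(l1*az + l2*bz + l3*cz);
      }
    }
  }
  List out((size_t)nx * ny);
  for (size_t k = 0; k < cols.size(); ++k) {
    std::sort(cols[k].begin(), cols[k].end());
    out[k] = NumericVector(cols[k].begin(), cols[k].end());
  }
  return out;
}

// Signed z-distance field on an (nx,ny,nz) node grid from column crossings.
// Positive inside.  Values clamped to +-clamp.
// [[Rcpp::export]]
NumericVector cpp_zdist_field(List crossings, double z0, double h, int nx, int ny, int nz,
                              double clamp) {
  NumericVector field((R_xlen_t)nx * ny * nz, -clamp);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      NumericVector cr = crossings[(size_t)j * nx + i];
      int m = cr.size();
      if (m % 2 == 1) m -= 1;  // numeric fallout: drop unmatched crossing
      for (int k = 0; k < nz; ++k) {
        double z = z0 + k * h;
        double f = -clamp;
        for (int c = 0; c + 1 < m; c += 2) {
          double lo = cr[c], hi = cr[c + 1];
          double v;
          if (z >= lo && z <= hi) v = std::min(z - lo, hi - z);
          else v = -std::min(std::fabs(z - lo), std::fabs(z - hi));
          if (v > f) f = v;
        }
        if (f > clamp) f = clamp;
        if (f < -clamp) f = -clamp;
        field[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] = f;
      }
    }
  }
  return field;
}

// Volume integral from column crossings: sum of inside-interval lengths * h^2.
// [[Rcpp::export]]
double cpp_column_volume(List crossings, double h) {
  double vol = 0.0;
  for (R_xlen_t k = 0; k < crossings.size(); ++k) {
    NumericVector cr = crossings[k];
    int m = cr.size();
    if (m % 2 == 1) m -= 1;
    for (int c = 0; c + 1 < m; c += 2) vol += cr[c + 1] - cr[c];
  }
  return vol * h * h;
}

// ---- marching tetrahedra ---------------------------------------------------

// Extract the iso=0 surface of a node field by splitting each cube into 6
// tetrahedra.  Guaranteed watertight for fields negative on the grid boundary.
// Vertices welded on shared grid edges.  Triangles oriented outward
// (normal pointing toward negative field).
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, int nx, int ny, int nz,
                       double x0, double y0, double z0, double h) {
  std::map< std::pair<R_xlen_t, R_xlen_t>, int > edgeVert;
  std::vector<double> verts;
  std::vector<int> tris;
  auto nodeId = [&](int i, int j, int k) -> R_xlen_t {
    return (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
  };
  auto nodePos = [&](R_xlen_t id, double* p) {
    int k = (int)(id / ((R_xlen_t)nx * ny));
    R_xlen_t r = id - (R_xlen_t)k * nx * ny;
    int j = (int)(r / nx), i = (int)(r % nx);
    p[0] = x0 + i * h; p[1] = y0 + j * h; p[2] = z0 + k * h;
  };
  auto fval = [&](R_xlen_t id) {
    double f = field[id];
    if (f == 0.0) f = 1e-12;  // avoid degenerate iso hits
    return f;
  };
  auto edgeVertex = [&](R_xlen_t a, R_xlen_t b) -> int {
    if (a > b) std::swap(a, b);
    auto key = std::make_pair(a, b);
    auto it = edgeVert.find(key);
    if (it != edgeVert.end()) return it->second;
    double fa = fval(a), fb = fval(b);
    double t = fa / (fa - fb);
    // keep iso vertices strictly off the grid nodes so that vertices from
    // different edges never coincide (which would create degenerate faces)
    if (t < 1e-4) t = 1e-4;
    if (t > 1.0 - 1e-4) t = 1.0 - 1e-4;
    double pa[3], pb[3];
    nodePos(a, pa); nodePos(b, pb);
    verts.push_back(pa[0] + t * (pb[0] - pa[0]));
    verts.push_back(pa[1] + t * (pb[1] - pa[1]));
    verts.push_back(pa[2] + t * (pb[2] - pa[2]));
    int id = (int)(verts.size() / 3);
    edgeVert[key] = id;  // 1-based
    return id;
  };
  // Freudenthal split of the cube 0..7 (binary xyz order)
  static const int tets[6][4] = {
    {0,1,3,7}, {0,1,5,7}, {0,2,3,7}, {0,2,6,7}, {0,4,5,7}, {0,4,6,7}
  };
  auto emitTri = [&](int v1, int v2, int v3, const double* posRef) {
    // orient so normal points away from the positive (inside) reference point
    double* p1 = &verts[3*(v1-1)];
    double* p2 = &verts[3*(v2-1)];
    double* p3 = &verts[3*(v3-1)];
    double u[3] = { p2[0]-p1[0], p2[1]-p1[1], p2[2]-p1[2] };
    double w[3] = { p3[0]-p1[0], p3[1]-p1[1], p3[2]-p1[2] };
    double n[3] = { u[1]*w[2]-u[2]*w[1], u[2]*w[0]-u[0]*w[2], u[0]*w[1]-u[1]*w[0] };
    double cx = (p1[0]+p2[0]+p3[0])/3 - posRef[0];
    double cy = (p1[1]+p2[1]+p3[1])/3 - posRef[1];
    double cz = (p1[2]+p2[2]+p3[2])/3 - posRef[2];
    if (n[0]*cx + n[1]*cy + n[2]*cz < 0) std::swap(v2, v3);
    tris.push_back(v1); tris.push_back(v2); tris.push_back(v3);
  };
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        R_xlen_t corner[8];
        for (int c = 0; c < 8; ++c)
          corner[c] = nodeId(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1));
        for (int t = 0; t < 6; ++t) {
          R_xlen_t n0 = corner[tets[t][0]], n1 = corner[tets[t][1]],
                   n2 = corner[tets[t][2]], n3 = corner[tets[t][3]];
          double f0 = fval(n0), f1 = fval(n1), f2 = fval(n2), f3 = fval(n3);
          int mask = (f0 > 0) | ((f1 > 0) << 1) | ((f2 > 0) << 2) | ((f3 > 0) << 3);
          if (mask == 0 || mask == 15) continue;
          // reference inside point: centroid of positive nodes
          double pr[3] = {0,0,0}; int nin = 0;
          R_xlen_t nd[4] = {n0,n1,n2,n3};
          double fv[4] = {f0,f1,f2,f3};
          for (int c = 0; c < 4; ++c) if (fv[c] > 0) {
            double p[3]; nodePos(nd[c], p);
            pr[0]+=p[0]; pr[1]+=p[1]; pr[2]+=p[2]; ++nin;
          }
          pr[0]/=nin; pr[1]/=nin; pr[2]/=nin;
          // collect sign-change edges among the 6 tet edges
          static const int te[6][2] = {{0,1},{0,2},{0,3},{1,2},{1,3},{2,3}};
          int evs[4]; int ne = 0;
          for (int e = 0; e < 6; ++e) {
            int aI = te[e][0], bI = te[e][1];
            if ((fv[aI] > 0) != (fv[bI] > 0))
              evs[ne++] = edgeVertex(nd[aI], nd[bI]);
          }
          if (ne == 3) emitTri(evs[0], evs[1], evs[2], pr);
          else if (ne == 4) {
            // split quad; edge order from the loop above needs pairing:
            // edges sharing a tet vertex are adjacent. Pair by geometry:
            // connect in order 0,1,3,2 (works for the te enumeration when
            // exactly two nodes are positive).
            emitTri(evs[0], evs[1], evs[3], pr);
            emitTri(evs[0], evs[3], evs[2], pr);
          }
        }
      }
  NumericMatrix Vm(verts.size() / 3, 3);
  for (size_t i = 0; i < verts.size() / 3; ++i)
    for (int j = 0; j < 3; ++j) Vm(i, j) = verts[3 * i + j];
  IntegerMatrix Fm(tris.size() / 3, 3);
  for (size_t i = 0; i < tris.size() / 3; ++i)
    for (int j = 0; j < 3; ++j) Fm(i, j) = tris[3 * i + j];
  return List::create(_["vertices"] = Vm, _["faces"] = Fm);
}

// ---- smoothing -------------------------------------------------------------

// Taubin lambda/mu smoothing with optional per-vertex displacement clamp.
// clampMax[i] < 0 means unconstrained.
// [[Rcpp::export]]
NumericMatrix cpp_taubin_smooth(NumericMatrix V, IntegerMatrix F,
                                double lambda, double mu, int iterations,
                                NumericVector clampMax) {
  int nv = V.nrow(), nf = F.nrow();
  std::vector< std::vector<int> > adj(nv);
  for (int f = 0; f < nf; ++f) {
    int a = F(f,0)-1, b = F(f,1)-1, c = F(f,2)-1;
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (int i = 0; i < nv; ++i) {
    std::sort(adj[i].begin(), adj[i].end());
    adj[i].erase(std::unique(adj[i].begin(), adj[i].end()), adj[i].end());
  }
  std::vector<double> cur(nv * 3), nxt(nv * 3), orig(nv * 3);
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) { cur[3*i+j] = V(i,j); orig[3*i+j] = V(i,j); }
  auto pass = [&](double w) {
    for (int i = 0; i < nv; ++i) {
      if (adj[i].empty()) {
        for (int j = 0; j < 3; ++j) nxt[3*i+j] = cur[3*i+j];
        continue;
      }
      double m[3] = {0,0,0};
      for (int n : adj[i]) for (int j = 0; j < 3; ++j) m[j] += cur[3*n+j];
      for (int j = 0; j < 3; ++j) {
        m[j] /= adj[i].size();
        nxt[3*i+j] = cur[3*i+j] + w * (m[j] - cur[3*i+j]);
      }
    }
    std::swap(cur, nxt);
  };
  auto clampPass = [&]() {
    for (int i = 0; i < nv; ++i) {
      double cm = clampMax[i];
      if (cm < 0) continue;
      double dx = cur[3*i] - orig[3*i], dy = cur[3*i+1] - orig[3*i+1], dz = cur[3*i+2] - orig[3*i+2];
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (d > cm && d > 0) {
        double s = cm / d;
        cur[3*i]   = orig[3*i]   + dx * s;
        cur[3*i+1] = orig[3*i+1] + dy * s;
        cur[3*i+2] = orig[3*i+2] + dz * s;
      }
    }
  };
  for (int it = 0; it < iterations; ++it) {
    pass(lambda);
    pass(mu);
    clampPass();
  }
  NumericMatrix out(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = cur[3*i+j];
  return out;
}
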