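#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra on the Freudenthal (Kuhn)
// decomposition: every grid cube is split into the same 6 tetrahedra around
// the (0,0,0)-(1,1,1) diagonal, which is compatible across neighbouring
// cubes, so the extracted surface is crack-free. Surface vertices live on
// global tetrahedron edges and are de-duplicated through an edge hash, which
// makes the mesh watertight. "Above" means value > iso; triangles are wound
// so normals point away from the supra-threshold region.

static inline uint64_t edge_key(uint64_t a, uint64_t b) {
    if (a > b) std::swap(a, b);
    return (a << 32) | b;
}

// [[Rcpp::export(name = ".mt_isosurface")]]
List mt_isosurface(NumericVector data, IntegerVector dims, double iso,
                   NumericVector spacing, NumericVector origin) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
    const double ox = origin[0], oy = origin[1], oz = origin[2];

    // the six tetrahedra of the Kuhn subdivision, as corner indices of the
    // cube corner offsets below (path 0 -> e_s1 -> e_s1+e_s2 -> (1,1,1))
    static const int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
    // cube corner offset -> bit code (ix | iy<<1 | iz<<2)
    std::unordered_map<uint64_t, int> vmap;
    std::vector<double> vx, vy, vz;
    std::vector<int> tri;

    auto lin = [&](int i, int j, int k) -> uint64_t {
        return (uint64_t)i + (uint64_t)nx * ((uint64_t)j + (uint64_t)ny * (uint64_t)k);
    };

    // emit (or reuse) the interpolated vertex on global grid edge (a,b)
    auto edge_vertex = [&](uint64_t ga, uint64_t gb, double va, double vb) -> int {
        uint64_t key = edge_key(ga, gb);
        auto it = vmap.find(key);
        if (it != vmap.end()) return it->second;
        // decompose linear indices back to (i,j,k)
        int ai = (int)(ga % nx), aj = (int)((ga / nx) % ny), ak = (int)(ga / ((uint64_t)nx * ny));
        int bi = (int)(gb % nx), bj = (int)((gb / nx) % ny), bk = (int)(gb / ((uint64_t)nx * ny));
        double t = (iso - va) / (vb - va);
        double px = ai + t * (bi - ai);
        double py = aj + t * (bj - aj);
        double pz = ak + t * (bk - ak);
        int id = (int)vx.size();
        vx.push_back(ox + px * dx);
        vy.push_back(oy + py * dy);
        vz.push_back(oz + pz * dz);
        vmap.emplace(key, id);
        return id;
    };

    // append triangle p0,p1,p2 oriented so its normal points away from the
    // above-iso side, using "above_pt" (an above-iso tet corner) as witness
    auto add_tri = [&](int a, int b, int c,
                       double axp, double ayp, double azp) {
        if (a == b || b == c || a == c) return;
        double ux = vx[b]-vx[a], uy = vy[b]-vy[a], uz = vz[b]-vz[a];
        double wx = vx[c]-vx[a], wy = vy[c]-vy[a], wz = vz[c]-vz[a];
        double nxv = uy*wz - uz*wy, nyv = uz*wx - ux*wz, nzv = ux*wy - uy*wx;
        double n2 = nxv*nxv + nyv*nyv + nzv*nzv;
        if (n2 <= 0.0) return; // degenerate
        double cx = (vx[a]+vx[b]+vx[c])/3.0, cy = (vy[a]+vy[b]+vy[c])/3.0,
               cz = (vz[a]+vz[b]+vz[c])/3.0;
        double d = nxv*(axp-cx) + nyv*(ayp-cy) + nzv*(azp-cz);
        if (d > 0) std::swap(b, c); // flip so normal faces away from above side
        tri.push_back(a); tri.push_back(b); tri.push_back(c);
    };

    int ti[4]; double tv[4]; uint64_t tg[4]; double tcx[4], tcy[4], tcz[4];

    for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
    for (int i = 0; i + 1 < nx; ++i) {
        // cube corner values
        double cv[8]; uint64_t cg[8]; int cxo[8], cyo[8], czo[8];
        bool any_above = false, any_below = false;
        for (int c = 0; c < 8; ++c) {
            int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
            cg[c] = lin(i + di, j + dj, k + dk);
            cv[c] = data[cg[c]];
            cxo[c] = i + di; cyo[c] = j + dj; czo[c] = k + dk;
            if (cv[c] > iso) any_above = true; else any_below = true;
        }
        if (!any_above || !any_below) continue;

        for (int p = 0; p < 6; ++p) {
            // corners of this tet as cube-corner codes
            int code = 0;
            int corner[4];
            corner[0] = 0;
            code = 0;
            code |= 1 << perms[p][0];
            corner[1] = code;
            code |= 1 << perms[p][1];
            corner[2] = code;
            corner[3] = 7;
            int mask = 0;
            for (int c = 0; c < 4; ++c) {
                int cc = corner[c];
                tv[c] = cv[cc]; tg[c] = cg[cc];
                tcx[c] = cxo[cc]; tcy[c] = cyo[cc]; tcz[c] = czo[cc];
                if (tv[c] > iso) mask |= 1 << c;
                ti[c] = c;
            }
            if (mask == 0 || mask == 15) continue;

            int above[4], below[4], na = 0, nb = 0;
            for (int c = 0; c < 4; ++c) {
                if (mask & (1 << c)) above[na++] = c; else below[nb++] = c;
            }
            // witness point on the above side (world coords of first above corner)
            double axp = ox + tcx[above[0]] * dx;
            double ayp = oy + tcy[above[0]] * dy;
            double azp = oz + tcz[above[0]] * dz;

            if (na == 1) {
                int a = above[0];
                int e0 = edge_vertex(tg[a], tg[below[0]], tv[a], tv[below[0]]);
                int e1 = edge_vertex(tg[a], tg[below[1]], tv[a], tv[below[1]]);
                int e2 = edge_vertex(tg[a], tg[below[2]], tv[a], tv[below[2]]);
                add_tri(e0, e1, e2, axp, ayp, azp);
            } else if (nb == 1) {
                int b = below[0];
                int e0 = edge_vertex(tg[above[0]], tg[b], tv[above[0]], tv[b]);
                int e1 = edge_vertex(tg[above[1]], tg[b], tv[above[1]], tv[b]);
                int e2 = edge_vertex(tg[above[2]], tg[b], tv[above[2]], tv[b]);
                add_tri(e0, e1, e2, axp, ayp, azp);
            } else { // 2-2: quad split into two triangles
                int a0 = above[0], a1 = above[1], b0 = below[0], b1 = below[1];
                int q0 = edge_vertex(tg[a0], tg[b0], tv[a0], tv[b0]);
                int q1 = edge_vertex(tg[a0], tg[b1], tv[a0], tv[b1]);
                int q2 = edge_vertex(tg[a1], tg[b1], tv[a1], tv[b1]);
                int q3 = edge_vertex(tg[a1], tg[b0], tv[a1], tv[b0]);
                add_tri(q0, q1, q2, axp, ayp, azp);
                add_tri(q0, q2, q3, axp, ayp, azp);
            }
        }
    }

    int nv = (int)vx.size();
    NumericMatrix V(nv, 3);
    for (int v = 0; v < nv; ++v) { V(v,0) = vx[v]; V(v,1) = vy[v]; V(v,2) = vz[v]; }
    int nt = (int)tri.size() / 3;
    IntegerMatrix T(nt, 3);
    for (int t = 0; t < nt; ++t) {
        T(t,0) = tri[3*t] + 1; T(t,1) = tri[3*t+1] + 1; T(t,2) = tri[3*t+2] + 1;
    }
    return List::create(_["vertices"] = V, _["triangles"] = T);
}

// Even-odd (crossing number) point-in-polygon; strictly interior points only.
// Points exactly on an edge are not guaranteed either way; callers place
// polygon vertices on a lattice offset from query points to avoid ties.
// [[Rcpp::export(name = ".pip_evenodd")]]
LogicalVector pip_evenodd(NumericVector px, NumericVector py,
                          NumericVector vx, NumericVector vy) {
    const int np = px.size(), nv = vx.size();
    LogicalVector inside(np);
    for (int p = 0; p < np; ++p) {
        double x = px[p], y = py[p];
        bool in = false;
        for (int i = 0, j = nv - 1; i < nv; j = i++) {
            if (((vy[i] > y) != (vy[j] > y))) {
                double xcross = vx[j] + (y - vy[j]) * (vx[i] - vx[j]) / (vy[i] - vy[j]);
                if (x < xcross) in = !in;
            }
        }
        inside[p] = in;
    }
    return inside;
}

static inline double cross2(double ox, double oy, double ax, double ay,
                            double bx, double by) {
    return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

// True if any two non-adjacent edges of the closed polygon properly intersect
// or overlap. Shared endpoints of adjacent edges are ignored.
// [[Rcpp::export(name = ".polygon_self_intersects")]]
bool polygon_self_intersects(NumericVector vx, NumericVector vy) {
    const int n = vx.size();
    for (int i = 0; i < n; ++i) {
        int i2 = (i + 1) % n;
        for (int j = i + 1; j < n; ++j) {
            int j2 = (j + 1) % n;
            if (j == i2 || j2 == i) continue; // adjacent edges share a vertex
            double d1 = cross2(vx[i], vy[i], vx[i2], vy[i2], vx[j], vy[j]);
            double d2 = cross2(vx[i], vy[i], vx[i2], vy[i2], vx[j2], vy[j2]);
            double d3 = cross2(vx[j], vy[j], vx[j2], vy[j2], vx[i], vy[i]);
            double d4 = cross2(vx[j], vy[j], vx[j2], vy[j2], vx[i2], vy[i2]);
            if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
                ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return true;
            // collinear overlap
            if (d1 == 0 && d2 == 0 && d3 == 0 && d4 == 0) {
                double minix = std::min(vx[i], vx[i2]), maxix = std::max(vx[i], vx[i2]);
                double miniy = std::min(vy[i], vy[i2]), maxiy = std::max(vy[i], vy[i2]);
                double minjx = std::min(vx[j], vx[j2]), maxjx = std::max(vx[j], vx[j2]);
                double minjy = std::min(vy[j], vy[j2]), maxjy = std::max(vy[j], vy[j2]);
                if (maxix >= minjx && maxjx >= minix &&
                    maxiy >= minjy && maxjy >= miniy) return true;
            }
        }
    }
    return false;
}
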