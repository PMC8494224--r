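#include <Rcpp.h>
#include <array>
#include <map>
#include <set>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Incremental Bowyer-Watson tetrahedralization. Coordinates are rescaled to
// the unit cube before insertion so the floating-point predicates operate at
// a common scale; callers are expected to reject duplicate points upstream.

typedef std::array<double, 3> P3;

static double orient3d(const P3& a, const P3& b, const P3& c, const P3& d) {
    double ad0 = a[0] - d[0], ad1 = a[1] - d[1], ad2 = a[2] - d[2];
    double bd0 = b[0] - d[0], bd1 = b[1] - d[1], bd2 = b[2] - d[2];
    double cd0 = c[0] - d[0], cd1 = c[1] - d[1], cd2 = c[2] - d[2];
    return ad0 * (bd1 * cd2 - bd2 * cd1)
         - ad1 * (bd0 * cd2 - bd2 * cd0)
         + ad2 * (bd0 * cd1 - bd1 * cd0);
}

// > 0 iff p lies inside the circumsphere of the positively oriented (a,b,c,d)
static double insphere(const P3& a, const P3& b, const P3& c, const P3& d,
                       const P3& p) {
    double m[4][4];
    const P3* q[4] = { &a, &b, &c, &d };
    for (int r = 0; r < 4; ++r) {
        double dx = (*q[r])[0] - p[0];
        double dy = (*q[r])[1] - p[1];
        double dz = (*q[r])[2] - p[2];
        m[r][0] = dx; m[r][1] = dy; m[r][2] = dz;
        m[r][3] = dx * dx + dy * dy + dz * dz;
    }
    // 4x4 determinant by cofactor expansion along the last column
    double det = 0.0;
    for (int r = 0; r < 4; ++r) {
        double sub[3][3];
        int rr = 0;
        for (int i = 0; i < 4; ++i) {
            if (i == r) continue;
            sub[rr][0] = m[i][0]; sub[rr][1] = m[i][1]; sub[rr][2] = m[i][2];
            ++rr;
        }
        double minor = sub[0][0] * (sub[1][1] * sub[2][2] - sub[1][2] * sub[2][1])
                     - sub[0][1] * (sub[1][0] * sub[2][2] - sub[1][2] * sub[2][0])
                     + sub[0][2] * (sub[1][0] * sub[2][1] - sub[1][1] * sub[2][0]);
        det += ((r % 2 == 0) ? 1.0 : -1.0) * m[r][3] * minor;
    }
    // det as computed is for rows (a,b,c,d) with the |.|^2 column last and an
    // implicit expansion sign; the conventional insphere determinant is its
    // negation for positively oriented tetrahedra.
    return -det;
}

struct Tet {
    int v[4];
    bool alive;
};

static void make_positive(Tet& t, const std::vector<P3>& pts) {
    if (orient3d(pts[t.v[0]], pts[t.v[1]], pts[t.v[2]], pts[t.v[3]]) < 0)
        std::swap(t.v[2], t.v[3]);
}

// [[Rcpp::export(name = ".delaunay3dEdges")]]
IntegerMatrix delaunay3d_edges(NumericMatrix coords) {
    const int n = coords.nrow();
    if (coords.ncol() != 3) stop("coords must have 3 columns");
    if (n < 4) stop("need at least 4 points for 3D triangulation");

    std::vector<P3> pts(n + 4);
    double mn[3], mx[3];
    for (int k = 0; k < 3; ++k) { mn[k] = R_PosInf; mx[k] = R_NegInf; }
    for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) {
            double v = coords(i, k);
            if (v < mn[k]) mn[k] = v;
            if (v > mx[k]) mx[k] = v;
        }
    double scale = 0.0;
    for (int k = 0; k < 3; ++k) scale = std::max(scale, mx[k] - mn[k]);
    if (scale <= 0) stop("all points coincide");
    for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
            pts[i][k] = (coords(i, k) - mn[k]) / scale;

    // super-tetrahedron comfortably enclosing the unit cube
    const double L = 50.0;
    pts[n]     = { -L, -L, -L };
    pts[n + 1] = { 4 * L, -L, -L };
    pts[n + 2] = { -L, 4 * L, -L };
    pts[n + 3] = { -L, -L, 4 * L };

    std::vector<Tet> tets;
    Tet t0; t0.v[0] = n; t0.v[1] = n + 1; t0.v[2] = n + 2; t0.v[3] = n + 3;
    t0.alive = true;
    make_positive(t0, pts);
    tets.push_back(t0);

    typedef std::array<int, 3> Face;
    for (int i = 0; i < n; ++i) {
        const P3& p = pts[i];
        std::vector<int> bad;
        for (size_t t = 0; t < tets.size(); ++t) {
            if (!tets[t].alive) continue;
            if (insphere(pts[tets[t].v[0]], pts[tets[t].v[1]],
                         pts[tets[t].v[2]], pts[tets[t].v[3]], p) > 0)
                bad.push_back((int)t);
        }
        if (bad.empty()) {
            // p coincides with or is degenerate w.r.t. current mesh
            stop("degenerate configuration during 3D triangulation; "
                 "enable jitter for grid-like or duplicated inputs");
        }
        std::map<Face, int> faceCount;
        static const int fidx[4][3] = { {0,1,2}, {0,1,3}, {0,2,3}, {1,2,3} };
        for (int b : bad) {
            for (int f = 0; f < 4; ++f) {
                Face fc = { tets[b].v[fidx[f][0]], tets[b].v[fidx[f][1]],
                            tets[b].v[fidx[f][2]] };
                std::sort(fc.begin(), fc.end());
                faceCount[fc]++;
            }
        }
        for (int b : bad) tets[b].alive = false;
        for (std::map<Face, int>::iterator it = faceCount.begin();
             it != faceCount.end(); ++it) {
            if (it->second != 1) continue;  // interior cavity face
            Tet nt;
            nt.v[0] = i;
            nt.v[1] = it->first[0];
            nt.v[2] = it->first[1];
            nt.v[3] = it->first[2];
            nt.alive = true;
            double o = orient3d(pts[nt.v[0]], pts[nt.v[1]], pts[nt.v[2]],
                                pts[nt.v[3]]);
            if (o == 0) continue;  // flat sliver; skip
            if (o < 0) std::swap(nt.v[2], nt.v[3]);
            tets.push_back(nt);
        }
    }

    std::set<std::pair<int, int> > edges;
    for (size_t t = 0; t < tets.size(); ++t) {
        if (!tets[t].alive) continue;
        bool real = true;
        for (int k = 0; k < 4; ++k)
            if (tets[t].v[k] >= n) { real = false; break; }
        if (!real) continue;
        for (int a = 0; a < 3; ++a)
            for (int b = a + 1; b < 4; ++b) {
                int u = tets[t].v[a], v = tets[t].v[b];
                if (u > v) std::swap(u, v);
                edges.insert(std::make_pair(u, v));
            }
    }
    if (edges.empty())
        stop("3D triangulation produced no tetrahedra; input may be coplanar");

    IntegerMatrix out((int)edges.size(), 2);
    int r = 0;
    for (std::set<std::pair<int, int> >::iterator it = edges.begin();
         it != edges.end(); ++it, ++r) {
        out(r, 0) = it->first + 1;   // 1-based for R
        out(r, 1) = it->second + 1;
    }
    return out;
}
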