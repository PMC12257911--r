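#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Large finite stand-in for "no source on this line yet"; keeps the
// lower-envelope arithmetic free of inf/nan. Real squared distances on
// clinical grids are < 1e6 mm^2, so the sentinel can never win.
static const double BIG = 1e15;

// 1D squared-distance transform along a sampled line (lower-envelope
// algorithm of Felzenszwalb & Huttenlocher). `step` is the physical grid
// spacing along this line in mm; `f` holds squared distances on input and
// is overwritten with the transformed values.
static void dt1d(std::vector<double>& f, double step,
                 std::vector<int>& v, std::vector<double>& z,
                 std::vector<double>& d) {
    const double INF = std::numeric_limits<double>::infinity();
    int n = (int)f.size();
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; q++) {
        double qq = q * step;
        double s = ((f[q] + qq * qq) - (f[v[k]] + (v[k] * step) * (v[k] * step)))
                   / (2.0 * (qq - v[k] * step));
        while (s <= z[k]) {
            k--;
            s = ((f[q] + qq * qq) - (f[v[k]] + (v[k] * step) * (v[k] * step)))
                / (2.0 * (qq - v[k] * step));
        }
        k++;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; q++) {
        double qq = q * step;
        while (z[k + 1] < qq) k++;
        double vv = v[k] * step;
        d[q] = (qq - vv) * (qq - vv) + f[v[k]];
    }
    for (int q = 0; q < n; q++) f[q] = d[q];
}

// Exact anisotropic squared Euclidean distance transform of a 3D logical
// mask: squared distance in mm^2 from every voxel centre to the nearest
// TRUE voxel centre. Separable: one 1D pass per axis.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : BIG;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // axis x (fastest-varying)
    for (int kz = 0; kz < nz; kz++)
        for (int ky = 0; ky < ny; ky++) {
            R_xlen_t base = (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
            f.assign(out.begin() + base, out.begin() + base + nx);
            dt1d(f, spacing[0], v, z, d);
            for (int i = 0; i < nx; i++) out[base + i] = f[i];
        }
    // axis y
    for (int kz = 0; kz < nz; kz++)
        for (int kx = 0; kx < nx; kx++) {
            R_xlen_t base = (R_xlen_t)kz * nx * ny + kx;
            f.resize(ny);
            for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)j * nx];
            dt1d(f, spacing[1], v, z, d);
            for (int j = 0; j < ny; j++) out[base + (R_xlen_t)j * nx] = f[j];
        }
    // axis z
    R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int ky = 0; ky < ny; ky++)
        for (int kx = 0; kx < nx; kx++) {
            R_xlen_t base = (R_xlen_t)ky * nx + kx;
            f.resize(nz);
            for (int k = 0; k < nz; k++) f[k] = out[base + (R_xlen_t)k * nxy];
            dt1d(f, spacing[2], v, z, d);
            for (int k = 0; k < nz; k++) out[base + (R_xlen_t)k * nxy] = f[k];
        }
    return out;
}

// For each row of `a` (points in mm, n x 3), the Euclidean distance to the
// nearest row of `b`. Brute force; surfaces on the grids this package
// targets stay below ~2e4 points.
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix a, NumericMatrix b) {
    int na = a.nrow(), nb = b.nrow();
    NumericVector out(na);
    for (int i = 0; i < na; i++) {
        double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
        double best = std::numeric_limits<double>::infinity();
        for (int j = 0; j < nb; j++) {
            double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < best) best = d2;
        }
        out[i] = std::sqrt(best);
    }
    return out;
}
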