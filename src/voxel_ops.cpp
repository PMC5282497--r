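#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Arrays are R 3D arrays with dim = (nz, ny, nx), column-major:
// linear index = z + nz * (y + ny * x), all 0-based here.

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform of a sampled function (Felzenszwalb &
// Huttenlocher 2012), grid pitch w. f holds squared distances on entry.
static void dt1d(const double* f, double* d, int* v, double* z, int n, double w)
{
    double w2 = w * w;
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; ++q) {
        if (f[q] == INF && f[v[k]] == INF) {
            // both parabolas at infinity: keep the earlier one
            continue;
        }
        double s;
        while (true) {
            double fq = f[q], fv = f[v[k]];
            if (fv == INF) { // q's parabola dominates everywhere left of v[k]
                --k;
                if (k < 0) { s = -INF; break; }
                continue;
            }
            s = ((fq + w2 * q * q) - (fv + w2 * v[k] * v[k])) /
                (2.0 * w2 * (q - v[k]));
            if (s <= z[k]) {
                --k;
                if (k < 0) { s = -INF; break; }
            } else break;
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        double dq = w * (q - v[k]);
        double fv = f[v[k]];
        d[q] = (fv == INF) ? INF : dq * dq + fv;
    }
}

//' @noRd
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dim, NumericVector spacing)
{
    const int nz = dim[0], ny = dim[1], nx = dim[2];
    const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    NumericVector out(n);

    // init: 0 at background, INF at foreground
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = mask[i] ? INF : 0.0;

    int nmax = std::max(nz, std::max(ny, nx));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along z (fastest-varying)
    for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y) {
            double* col = &out[(R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
            dt1d(col, d.data(), v.data(), z.data(), nz, dz);
            std::copy(d.begin(), d.begin() + nz, col);
        }
    // pass along y
    for (int x = 0; x < nx; ++x)
        for (int zz = 0; zz < nz; ++zz) {
            for (int y = 0; y < ny; ++y)
                f[y] = out[zz + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
            dt1d(f.data(), d.data(), v.data(), z.data(), ny, dy);
            for (int y = 0; y < ny; ++y)
                out[zz + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = d[y];
        }
    // pass along x
    for (int y = 0; y < ny; ++y)
        for (int zz = 0; zz < nz; ++zz) {
            for (int x = 0; x < nx; ++x)
                f[x] = out[zz + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
            dt1d(f.data(), d.data(), v.data(), z.data(), nx, dx);
            for (int x = 0; x < nx; ++x)
                out[zz + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = d[x];
        }

    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = std::sqrt(out[i]);
    out.attr("dim") = dim;
    return out;
}

//' @noRd
// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask, IntegerVector dim, int connectivity)
{
    const int nz = dim[0], ny = dim[1], nx = dim[2];
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    IntegerVector lab(n, 0);

    // neighbour offsets
    std::vector<std::array<int, 3>> nb;
    if (connectivity == 6) {
        nb = { {{1,0,0}},{{-1,0,0}},{{0,1,0}},{{0,-1,0}},{{0,0,1}},{{0,0,-1}} };
    } else { // 26
        for (int a = -1; a <= 1; ++a)
            for (int b = -1; b <= 1; ++b)
                for (int c = -1; c <= 1; ++c)
                    if (a || b || c) nb.push_back({{a, b, c}});
    }

    std::vector<R_xlen_t> stack;
    int next = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (!mask[i] || lab[i]) continue;
        ++next;
        lab[i] = next;
        stack.push_back(i);
        while (!stack.empty()) {
            R_xlen_t cur = stack.back();
            stack.pop_back();
            int zz = cur % nz;
            int rest = cur / nz;
            int y = rest % ny;
            int x = rest / ny;
            for (auto& o : nb) {
                int z2 = zz + o[0], y2 = y + o[1], x2 = x + o[2];
                if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny ||
                    x2 < 0 || x2 >= nx) continue;
                R_xlen_t j = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
                if (mask[j] && !lab[j]) {
                    lab[j] = next;
                    stack.push_back(j);
                }
            }
        }
    }
    lab.attr("dim") = dim;
    return lab;
}

// separable 1D Gaussian convolution along one axis, reflecting boundary
static void blur_axis(std::vector<double>& img, int nz, int ny, int nx,
                      int axis, double sigma_vox)
{
    if (sigma_vox <= 0) return;
    int r = (int)std::ceil(4.0 * sigma_vox);
    std::vector<double> k(2 * r + 1);
    double s = 0;
    for (int i = -r; i <= r; ++i) {
        k[i + r] = std::exp(-0.5 * i * i / (sigma_vox * sigma_vox));
        s += k[i + r];
    }
    for (auto& kk : k) kk /= s;

    int len = axis == 0 ? nz : axis == 1 ? ny : nx;
    std::vector<double> line(len), res(len);
    R_xlen_t nzl = nz;

    auto idx = [&](int zz, int y, int x) -> R_xlen_t {
        return zz + nzl * (y + (R_xlen_t)ny * x);
    };
    auto reflect = [&](int i) {
        while (i < 0 || i >= len) {
            if (i < 0) i = -i - 1;
            if (i >= len) i = 2 * len - i - 1;
        }
        return i;
    };

    int d1 = axis == 0 ? ny : nz;
    int d2 = axis == 2 ? ny : nx;
    for (int a = 0; a < d1; ++a)
        for (int b = 0; b < d2; ++b) {
            for (int i = 0; i < len; ++i) {
                int zz = axis == 0 ? i : a;
                int y  = axis == 1 ? i : (axis == 0 ? a : b);
                int x  = axis == 2 ? i : b;
                line[i] = img[idx(zz, y, x)];
            }
            for (int i = 0; i < len; ++i) {
                double acc = 0;
                for (int j = -r; j <= r; ++j)
                    acc += k[j + r] * line[reflect(i + j)];
                res[i] = acc;
            }
            for (int i = 0; i < len; ++i) {
                int zz = axis == 0 ? i : a;
                int y  = axis == 1 ? i : (axis == 0 ? a : b);
                int x  = axis == 2 ? i : b;
                img[idx(zz, y, x)] = res[i];
            }
        }
}

//' @noRd
// [[Rcpp::export(name = ".blur3d")]]
NumericVector blur3d(NumericVector img, IntegerVector dim, NumericVector sigma_vox)
{
    const int nz = dim[0], ny = dim[1], nx = dim[2];
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    std::vector<double> buf(n);
    for (R_xlen_t i = 0; i < n; ++i) buf[i] = img[i];
    blur_axis(buf, nz, ny, nx, 0, sigma_vox[0]);
    blur_axis(buf, nz, ny, nx, 1, sigma_vox[1]);
    blur_axis(buf, nz, ny, nx, 2, sigma_vox[2]);
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = buf[i];
    out.attr("dim") = dim;
    return out;
}
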