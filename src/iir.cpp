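#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter applied down each column.
// b, a are the numerator/denominator coefficient vectors with a[0] == 1.
// [[Rcpp::export]]
NumericMatrix iirFilterMatrix(NumericMatrix x, NumericVector b,
                              NumericVector a) {
    const int nT = x.nrow(), nC = x.ncol();
    const int nb = b.size(), na = a.size();
    const int nz = std::max(nb, na) - 1;
    NumericMatrix y(nT, nC);
    std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
    for (int i = 0; i < nb; ++i) bb[i] = b[i];
    for (int i = 0; i < na; ++i) aa[i] = a[i];
    std::vector<double> z(nz);
    const double *bp = bb.data(), *ap = aa.data();
    double *zp = z.data();
    for (int c = 0; c < nC; ++c) {
        std::fill(z.begin(), z.end(), 0.0);
        const double *xc = &x(0, c);
        double *yc = &y(0, c);
        for (int t = 0; t < nT; ++t) {
            const double xn = xc[t];
            const double yn = bp[0] * xn + zp[0];
            for (int k = 0; k < nz - 1; ++k)
                zp[k] = bp[k + 1] * xn + zp[k + 1] - ap[k + 1] * yn;
            zp[nz - 1] = bp[nz] * xn - ap[nz] * yn;
            yc[t] = yn;
        }
    }
    return y;
}
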