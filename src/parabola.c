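/* 1-D quadratic-structuring-function erosion/dilation passes for the
 * sliding-parabola filter, via the lower-envelope-of-parabolas algorithm
 * (O(n) per line). Erosion along columns of a numeric matrix:
 *   out[i, j] = min_k ( m[i, k] + c * (k - j)^2 )
 * Dilation is the max variant. The envelope is computed over the full
 * line, which matches truncating the structuring-function support at the
 * image border (no padding values are invented).
 */
#include <R.h>
#include <Rinternals.h>
#include <float.h>

static void envelope_line(const double *f, double *out, int n, double c,
                          int *v, double *z, int maximize) {
  /* standard lower envelope of parabolas f[q] + c (p - q)^2; for the
   * dilation (maximize) the input is negated by the caller */
  int k = 0;
  v[0] = 0;
  z[0] = -DBL_MAX;
  z[1] = DBL_MAX;
  for (int q = 1; q < n; q++) {
    double s;
    for (;;) {
      int p = v[k];
      s = ((f[q] + c * q * q) - (f[p] + c * p * p)) / (2.0 * c * (q - p));
      if (s <= z[k]) {
        k--;
        if (k < 0) { k = 0; v[0] = q; z[0] = -DBL_MAX; z[1] = DBL_MAX; goto placed; }
      } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DBL_MAX;
placed:;
  }
  k = 0;
  for (int p = 0; p < n; p++) {
    while (z[k + 1] < p) k++;
    double d = (double)(p - v[k]);
    out[p] = f[v[k]] + c * d * d;
  }
  (void)maximize;
}

/* op = 0 erosion (min), 1 dilation (max); pass along columns (within each
 * column index runs over rows) then the caller transposes as needed.   */
SEXP quad_pass_c(SEXP mat, SEXP curvature, SEXP op) {
  SEXP dim = getAttrib(mat, R_DimSymbol);
  int nr = INTEGER(dim)[0], nc = INTEGER(dim)[1];
  double c = REAL(curvature)[0];
  int maximize = INTEGER(op)[0];
  SEXP out = PROTECT(allocMatrix(REALSXP, nr, nc));
  const double *m = REAL(mat);
  double *o = REAL(out);
  double *f = (double *) R_alloc(nr, sizeof(double));
  double *g = (double *) R_alloc(nr, sizeof(double));
  int *v = (int *) R_alloc(nr, sizeof(int));
  double *z = (double *) R_alloc(nr + 1, sizeof(double));
  for (int j = 0; j < nc; j++) {
    const double *col = m + (size_t) j * nr;
    if (maximize) {
      for (int i = 0; i < nr; i++) f[i] = -col[i];
    } else {
      for (int i = 0; i < nr; i++) f[i] = col[i];
    }
    envelope_line(f, g, nr, c, v, z, maximize);
    double *ocol = o + (size_t) j * nr;
    if (maximize) {
      for (int i = 0; i < nr; i++) ocol[i] = -g[i];
    } else {
      for (int i = 0; i < nr; i++) ocol[i] = g[i];
    }
  }
  UNPROTECT(1);
  return out;
}

#include <R_ext/Rdynload.h>
SEXP binary_dilate_c(SEXP mask, SEXP steps, SEXP conn, SEXP support);
static const R_CallMethodDef CallEntries[] = {
  {"quad_pass_c", (DL_FUNC) &quad_pass_c, 3},
  {"binary_dilate_c", (DL_FUNC) &binary_dilate_c, 4},
  {NULL, NULL, 0}
};

void R_init_httquant(DllInfo *dll) {
  R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
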