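/* Iterative binary dilation (4- or 8-connected), optionally constrained to
 * a support mask (geodesic dilation). Used by rim construction, cytoplasm
 * growth and the synthetic-scene generator. */
#include <R.h>
#include <Rinternals.h>

SEXP binary_dilate_c(SEXP mask, SEXP steps, SEXP conn, SEXP support) {
  SEXP dim = getAttrib(mask, R_DimSymbol);
  int nr = INTEGER(dim)[0], nc = INTEGER(dim)[1];
  int k = INTEGER(steps)[0];
  int use8 = INTEGER(conn)[0] == 8;
  int has_sup = !isNull(support);
  const int *m = LOGICAL(mask);
  const int *sup = has_sup ? LOGICAL(support) : NULL;
  SEXP out = PROTECT(allocMatrix(LGLSXP, nr, nc));
  int *cur = LOGICAL(out);
  memcpy(cur, m, (size_t) nr * nc * sizeof(int));
  int *buf = (int *) R_alloc((size_t) nr * nc, sizeof(int));
  for (int it = 0; it < k; it++) {
    memcpy(buf, cur, (size_t) nr * nc * sizeof(int));
    int changed = 0;
    for (int j = 0; j < nc; j++) {
      for (int i = 0; i < nr; i++) {
        size_t p = (size_t) j * nr + i;
        if (buf[p]) continue;
        if (has_sup && !sup[p]) continue;
        int hit = 0;
        int jlo = j > 0 ? j - 1 : j, jhi = j < nc - 1 ? j + 1 : j;
        int ilo = i > 0 ? i - 1 : i, ihi = i < nr - 1 ? i + 1 : i;
        if (use8) {
          for (int jj = jlo; jj <= jhi && !hit; jj++)
            for (int ii = ilo; ii <= ihi; ii++)
              if (buf[(size_t) jj * nr + ii]) { hit = 1; break; }
        } else {
          if (i > 0 && buf[p - 1]) hit = 1;
          else if (i < nr - 1 && buf[p + 1]) hit = 1;
          else if (j > 0 && buf[p - nr]) hit = 1;
          else if (j < nc - 1 && buf[p + nr]) hit = 1;
        }
        if (hit) { cur[p] = 1; changed = 1; }
      }
    }
    if (!changed) break;
  }
  UNPROTECT(1);
  return out;
}
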