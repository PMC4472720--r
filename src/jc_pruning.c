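/* Felsenstein pruning for the Jukes-Cantor model on compressed site
 * patterns. Transition acts as P L = e L + (1-e)/4 * sum(L), with
 * e = exp(-4 d / 3) supplied per edge.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* upat: integer matrix ntip x npat, states 1..4, 0 = missing.
 * edges: integer matrix nedge x 2, columns (parent, child), 1-based
 *        node ids, ordered so every child's subtree edges come first.
 * efac:  double vector nedge, exp(-4 d / 3) per edge.
 * nnode_: total node count (tips + internals).
 * root_: 1-based id of the root node.
 * Returns: double vector npat of per-pattern site likelihoods.
 */
SEXP C_jc_sitelik(SEXP upat, SEXP edges, SEXP efac, SEXP nnode_, SEXP root_)
{
    const int ntip = nrows(upat);
    const int npat = ncols(upat);
    const int nedge = nrows(edges);
    const int nnode = asInteger(nnode_);
    const int root = asInteger(root_) - 1;
    const int *pat = INTEGER(upat);
    const int *ep = INTEGER(edges);
    const double *e = REAL(efac);

    double *cl = (double *) R_alloc((size_t) nnode * 4 * npat, sizeof(double));
    char *ready = (char *) R_alloc((size_t) nnode, sizeof(char));
    memset(ready, 0, (size_t) nnode);

    /* leaves */
    for (int t = 0; t < ntip; t++) {
        double *row = cl + (size_t) t * 4 * npat;
        for (int s = 0; s < npat; s++) {
            int st = pat[t + (size_t) s * ntip];
            if (st == 0) {
                row[4 * s] = row[4 * s + 1] = row[4 * s + 2] = row[4 * s + 3] = 1.0;
            } else {
                row[4 * s] = row[4 * s + 1] = row[4 * s + 2] = row[4 * s + 3] = 0.0;
                row[4 * s + (st - 1)] = 1.0;
            }
        }
        ready[t] = 1;
    }

    for (int k = 0; k < nedge; k++) {
        int par = ep[k] - 1;
        int chi = ep[k + nedge] - 1;
        double ek = e[k];
        double *cp = cl + (size_t) par * 4 * npat;
        double *cc = cl + (size_t) chi * 4 * npat;
        if (!ready[par]) {   /* initialize parent partials to 1 */
            for (int i = 0; i < 4 * npat; i++) cp[i] = 1.0;
            ready[par] = 1;
        }
        for (int s = 0; s < npat; s++) {
            double *x = cc + 4 * s;
            double sum = x[0] + x[1] + x[2] + x[3];
            double add = (1.0 - ek) * 0.25 * sum;
            double *y = cp + 4 * s;
            y[0] *= ek * x[0] + add;
            y[1] *= ek * x[1] + add;
            y[2] *= ek * x[2] + add;
            y[3] *= ek * x[3] + add;
        }
    }

    SEXP out = PROTECT(allocVector(REALSXP, npat));
    double *o = REAL(out);
    double *cr = cl + (size_t) root * 4 * npat;
    for (int s = 0; s < npat; s++) {
        o[s] = 0.25 * (cr[4 * s] + cr[4 * s + 1] + cr[4 * s + 2] + cr[4 * s + 3]);
    }
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef CallEntries[] = {
    {"C_jc_sitelik", (DL_FUNC) &C_jc_sitelik, 5},
    {NULL, NULL, 0}
};

void R_init_statbin(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
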