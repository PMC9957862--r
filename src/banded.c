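/* Complex banded direct solve via LAPACK zgbsv.
 *
 * The FEM system is assembled in R into LAPACK band storage
 * (ldab x n, ldab = 2*kl + ku + 1, entry A[i,j] at ab[kl+ku+i-j, j-1]);
 * zgbsv factorises with partial pivoting, which needs the extra kl rows.
 * Both ab and b are overwritten copies, the caller's objects are untouched.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/RS.h>

extern void F77_NAME(zgbsv)(const int *n, const int *kl, const int *ku,
                            const int *nrhs, Rcomplex *ab, const int *ldab,
                            int *ipiv, Rcomplex *b, const int *ldb, int *info);

SEXP C_zgbsv(SEXP ab, SEXP kl_, SEXP ku_, SEXP b)
{
    if (!isComplex(ab) || !isComplex(b))
        error("banded solve: 'ab' and 'b' must be complex");
    SEXP dim = getAttrib(ab, R_DimSymbol);
    if (isNull(dim) || LENGTH(dim) != 2)
        error("banded solve: 'ab' must be a matrix");
    int ldab = INTEGER(dim)[0];
    int n = INTEGER(dim)[1];
    int kl = asInteger(kl_), ku = asInteger(ku_);
    if (n != LENGTH(b))
        error("banded solve: dimension mismatch (n=%d, length(b)=%d)", n, LENGTH(b));
    if (ldab < 2 * kl + ku + 1)
        error("banded solve: ldab=%d < 2*kl+ku+1=%d", ldab, 2 * kl + ku + 1);

    SEXP ab2 = PROTECT(duplicate(ab));
    SEXP x = PROTECT(duplicate(b));
    int *ipiv = (int *) R_alloc(n, sizeof(int));
    int nrhs = 1, info = 0;
    F77_CALL(zgbsv)(&n, &kl, &ku, &nrhs, COMPLEX(ab2), &ldab, ipiv,
                    COMPLEX(x), &n, &info);
    UNPROTECT(2);
    if (info > 0)
        error("banded solve: singular system (zero pivot at %d)", info);
    if (info < 0)
        error("banded solve: invalid argument %d to zgbsv", -info);
    return x;
}
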