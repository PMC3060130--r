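#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_sha256(SEXP raw);
SEXP C_crc32(SEXP raw);

static const R_CallMethodDef CallEntries[] = {
    {"C_sha256", (DL_FUNC)&C_sha256, 1},
    {"C_crc32", (DL_FUNC)&C_crc32, 1},
    {NULL, NULL, 0}};

void R_init_cytostd(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
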