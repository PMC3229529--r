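/* CRC-32 (IEEE 802.3 polynomial, reflected), as used by gzip/zip. */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static unsigned int crc_table[256];
static int table_ready = 0;

static void make_table(void)
{
    unsigned int c;
    int n, k;
    for (n = 0; n < 256; n++) {
        c = (unsigned int) n;
        for (k = 0; k < 8; k++)
            c = (c & 1U) ? 0xEDB88320U ^ (c >> 1) : c >> 1;
        crc_table[n] = c;
    }
    table_ready = 1;
}

SEXP samzip_crc32(SEXP data)
{
    R_xlen_t i, n;
    unsigned int c = 0xFFFFFFFFU;
    const unsigned char *p;
    unsigned char *o;
    SEXP out;

    if (TYPEOF(data) != RAWSXP)
        error("crc32 input must be a raw vector");
    if (!table_ready)
        make_table();
    n = XLENGTH(data);
    p = RAW(data);
    for (i = 0; i < n; i++)
        c = crc_table[(c ^ p[i]) & 0xFFU] ^ (c >> 8);
    c ^= 0xFFFFFFFFU;

    /* little-endian 4-byte digest */
    out = PROTECT(allocVector(RAWSXP, 4));
    o = RAW(out);
    o[0] = c & 0xFFU;
    o[1] = (c >> 8) & 0xFFU;
    o[2] = (c >> 16) & 0xFFU;
    o[3] = (c >> 24) & 0xFFU;
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef call_methods[] = {
    {"samzip_crc32", (DL_FUNC) &samzip_crc32, 1},
    {NULL, NULL, 0}
};

void R_init_samzip(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_methods, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
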