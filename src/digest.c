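/* SHA-256 and CRC-32 over raw vectors, used for ACS member integrity. */

#include <R.h>
#include <Rinternals.h>
#include <stdint.h>
#include <string.h>

/* ---------------- SHA-256 (FIPS 180-4) ---------------- */

static const uint32_t K256[64] = {
    0x428a2f98, 0x71374491, 0xb5c0fbcf, 0xe9b5dba5, 0x3956c25b, 0x59f111f1,
    0x923f82a4, 0xab1c5ed5, 0xd807aa98, 0x12835b01, 0x243185be, 0x550c7dc3,
    0x72be5d74, 0x80deb1fe, 0x9bdc06a7, 0xc19bf174, 0xe49b69c1, 0xefbe4786,
    0x0fc19dc6, 0x240ca1cc, 0x2de92c6f, 0x4a7484aa, 0x5cb0a9dc, 0x76f988da,
    0x983e5152, 0xa831c66d, 0xb00327c8, 0xbf597fc7, 0xc6e00bf3, 0xd5a79147,
    0x06ca6351, 0x14292967, 0x27b70a85, 0x2e1b2138, 0x4d2c6dfc, 0x53380d13,
    0x650a7354, 0x766a0abb, 0x81c2c92e, 0x92722c85, 0xa2bfe8a1, 0xa81a664b,
    0xc24b8b70, 0xc76c51a3, 0xd192e819, 0xd6990624, 0xf40e3585, 0x106aa070,
    0x19a4c116, 0x1e376c08, 0x2748774c, 0x34b0bcb5, 0x391c0cb3, 0x4ed8aa4a,
    0x5b9cca4f, 0x682e6ff3, 0x748f82ee, 0x78a5636f, 0x84c87814, 0x8cc70208,
    0x90befffa, 0xa4506ceb, 0xbef9a3f7, 0xc67178f2};

#define ROTR(x, n) (((x) >> (n)) | ((x) << (32 - (n))))

static void sha256_block(uint32_t h[8], const unsigned char *p)
{
    uint32_t w[64], a, b, c, d, e, f, g, hh, t1, t2;
    int i;
    for (i = 0; i < 16; i++)
        w[i] = ((uint32_t)p[4 * i] << 24) | ((uint32_t)p[4 * i + 1] << 16) |
               ((uint32_t)p[4 * i + 2] << 8) | (uint32_t)p[4 * i + 3];
    for (i = 16; i < 64; i++) {
        uint32_t s0 = ROTR(w[i - 15], 7) ^ ROTR(w[i - 15], 18) ^ (w[i - 15] >> 3);
        uint32_t s1 = ROTR(w[i - 2], 17) ^ ROTR(w[i - 2], 19) ^ (w[i - 2] >> 10);
        w[i] = w[i - 16] + s0 + w[i - 7] + s1;
    }
    a = h[0]; b = h[1]; c = h[2]; d = h[3];
    e = h[4]; f = h[5]; g = h[6]; hh = h[7];
    for (i = 0; i < 64; i++) {
        uint32_t S1 = ROTR(e, 6) ^ ROTR(e, 11) ^ ROTR(e, 25);
        uint32_t ch = (e & f) ^ (~e & g);
        uint32_t S0 = ROTR(a, 2) ^ ROTR(a, 13) ^ ROTR(a, 22);
        uint32_t maj = (a & b) ^ (a & c) ^ (b & c);
        t1 = hh + S1 + ch + K256[i] + w[i];
        t2 = S0 + maj;
        hh = g; g = f; f = e; e = d + t1;
        d = c; c = b; b = a; a = t1 + t2;
    }
    h[0] += a; h[1] += b; h[2] += c; h[3] += d;
    h[4] += e; h[5] += f; h[6] += g; h[7] += hh;
}

SEXP C_sha256(SEXP raw)
{
    R_xlen_t n = XLENGTH(raw), i;
    const unsigned char *msg = RAW(raw);
    uint32_t h[8] = {0x6a09e667, 0xbb67ae85, 0x3c6ef372, 0xa54ff53a,
                     0x510e527f, 0x9b05688c, 0x1f83d9ab, 0x5be0cd19};
    unsigned char tail[128];
    R_xlen_t full = n - (n % 64);
    for (i = 0; i < full; i += 64)
        sha256_block(h, msg + i);
    /* padding: 0x80, zeros, 64-bit big-endian bit length */
    {
        size_t rem = (size_t)(n - full);
        size_t padded = (rem <= 55) ? 64 : 128;
        uint64_t bits = (uint64_t)n * 8;
        memset(tail, 0, sizeof(tail));
        memcpy(tail, msg + full, rem);
        tail[rem] = 0x80;
        for (i = 0; i < 8; i++)
            tail[padded - 1 - i] = (unsigned char)(bits >> (8 * i));
        sha256_block(h, tail);
        if (padded == 128)
            sha256_block(h, tail + 64);
    }
    {
        char hex[65];
        static const char d[] = "0123456789abcdef";
        int j;
        for (j = 0; j < 8; j++) {
            hex[8 * j]     = d[(h[j] >> 28) & 0xF];
            hex[8 * j + 1] = d[(h[j] >> 24) & 0xF];
            hex[8 * j + 2] = d[(h[j] >> 20) & 0xF];
            hex[8 * j + 3] = d[(h[j] >> 16) & 0xF];
            hex[8 * j + 4] = d[(h[j] >> 12) & 0xF];
            hex[8 * j + 5] = d[(h[j] >> 8) & 0xF];
            hex[8 * j + 6] = d[(h[j] >> 4) & 0xF];
            hex[8 * j + 7] = d[h[j] & 0xF];
        }
        hex[64] = '\0';
        return mkString(hex);
    }
}

/* ---------------- CRC-32 (ISO 3309, as used by ZIP) ---------------- */

SEXP C_crc32(SEXP raw)
{
    static uint32_t table[256];
    static int have_table = 0;
    R_xlen_t n = XLENGTH(raw), i;
    const unsigned char *p = RAW(raw);
    uint32_t crc = 0xFFFFFFFFu;
    if (!have_table) {
        uint32_t c;
        int k, b;
        for (k = 0; k < 256; k++) {
            c = (uint32_t)k;
            for (b = 0; b < 8; b++)
                c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : (c >> 1);
            table[k] = c;
        }
        have_table = 1;
    }
    for (i = 0; i < n; i++)
        crc = table[(crc ^ p[i]) & 0xFF] ^ (crc >> 8);
    crc ^= 0xFFFFFFFFu;
    return ScalarReal((double)crc);
}
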