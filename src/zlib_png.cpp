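// zlib bindings and PNG scanline filtering for the built-in PNG codec.
// PNG needs a raw zlib stream (RFC 1950) which memCompress() does not
// expose, hence the direct binding.
#include <Rcpp.h>
#include <zlib.h>
using namespace Rcpp;

// [[Rcpp::export]]
RawVector zlib_deflate(RawVector data, int level = 6) {
  uLong srclen = (uLong) data.size();
  uLongf bound = compressBound(srclen);
  std::vector<Bytef> buf(bound);
  uLongf outlen = bound;
  int ret = compress2(buf.data(), &outlen,
                      (const Bytef*) RAW(data), srclen, level);
  if (ret != Z_OK) stop("zlib deflate failed (code %d)", ret);
  RawVector out(outlen);
  memcpy(RAW(out), buf.data(), outlen);
  return out;
}

// [[Rcpp::export]]
RawVector zlib_inflate(RawVector data, double expected_size) {
  uLongf outlen = (uLongf) expected_size;
  std::vector<Bytef> buf(outlen > 0 ? outlen : 1);
  int ret = uncompress(buf.data(), &outlen,
                       (const Bytef*) RAW(data), (uLong) data.size());
  if (ret != Z_OK) stop("zlib inflate failed (code %d)", ret);
  RawVector out(outlen);
  memcpy(RAW(out), buf.data(), outlen);
  return out;
}

// [[Rcpp::export]]
double crc32_raw(RawVector data) {
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, (const Bytef*) RAW(data), (uInt) data.size());
  return (double) crc;
}

static inline int paeth(int a, int b, int c) {
  int p = a + b - c;
  int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

// Undo per-row PNG filters (types 0-4). `data` is the inflated stream:
// height rows of (1 filter byte + rowbytes). `bpp` = bytes per pixel.
// [[Rcpp::export]]
RawVector png_unfilter(RawVector data, int height, int rowbytes, int bpp) {
  if ((double) data.size() < (double) height * (rowbytes + 1))
    stop("PNG data stream truncated");
  RawVector out((R_xlen_t) height * rowbytes);
  const unsigned char* src = RAW(data);
  unsigned char* dst = RAW(out);
  for (int y = 0; y < height; ++y) {
    int ft = src[(R_xlen_t) y * (rowbytes + 1)];
    const unsigned char* row = src + (R_xlen_t) y * (rowbytes + 1) + 1;
    unsigned char* cur = dst + (R_xlen_t) y * rowbytes;
    const unsigned char* up = (y > 0) ? cur - rowbytes : NULL;
    for (int x = 0; x < rowbytes; ++x) {
      int a = (x >= bpp) ? cur[x - bpp] : 0;
      int b = up ? up[x] : 0;
      int c = (up && x >= bpp) ? up[x - bpp] : 0;
      int v = row[x];
      switch (ft) {
        case 0: break;
        case 1: v += a; break;
        case 2: v += b; break;
        case 3: v += (a + b) / 2; break;
        case 4: v += paeth(a, b, c); break;
        default: stop("unsupported PNG filter type %d", ft);
      }
      cur[x] = (unsigned char) (v & 0xff);
    }
  }
  return out;
}
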