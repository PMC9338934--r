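#include <Rcpp.h>
#include <zlib.h>
#include <cstring>
#include <vector>

using namespace Rcpp;

// Size in bytes of the raw DEFLATE stream (windowBits = -15, i.e. no zlib
// or gzip container) of each input string, compressed at level 1
// (Z_BEST_SPEED) with memLevel 8. The container convention is pinned here
// and mirrored in the R constant deflate_convention(); header/trailer
// bytes would shift every ratio additively, so only the bare stream is
// counted.
// [[Rcpp::export]]
IntegerVector deflate_sizes_cpp(CharacterVector seqs) {
  const int n = seqs.size();
  IntegerVector out(n);

  z_stream zs;
  std::memset(&zs, 0, sizeof(zs));
  if (deflateInit2(&zs, 1 /* Z_BEST_SPEED */, Z_DEFLATED,
                   -15 /* raw deflate */, 8, Z_DEFAULT_STRATEGY) != Z_OK)
    stop("zlib deflateInit2 failed");

  std::vector<unsigned char> buf;
  for (int i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    const char *str = CHAR(STRING_ELT(seqs, i));
    uLong inlen = static_cast<uLong>(std::strlen(str));
    if (inlen == 0) { out[i] = NA_INTEGER; continue; }
    deflateReset(&zs);
    uLong bound = deflateBound(&zs, inlen);
    if (buf.size() < bound) buf.resize(bound);
    zs.next_in = reinterpret_cast<Bytef *>(const_cast<char *>(str));
    zs.avail_in = static_cast<uInt>(inlen);
    zs.next_out = buf.data();
    zs.avail_out = static_cast<uInt>(buf.size());
    int ret = deflate(&zs, Z_FINISH);
    out[i] = (ret == Z_STREAM_END) ? static_cast<int>(zs.total_out)
                                   : NA_INTEGER;
  }
  deflateEnd(&zs);
  return out;
}
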