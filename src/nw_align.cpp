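#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Needleman-Wunsch global alignment with a linear gap penalty and a fixed,
// deterministic traceback preference: diagonal, then up (gap in b), then
// left (gap in a). 'N' never matches anything, including another 'N'.

static inline double subScore(char x, char y, double match, double mismatch) {
  if (x == 'N' || y == 'N') return mismatch;
  return (x == y) ? match : mismatch;
}

// [[Rcpp::export(name = ".nwAlignCpp")]]
List nwAlignCpp(std::string a, std::string b, double match, double mismatch,
                double gap) {
  const size_t la = a.size(), lb = b.size();
  std::vector<double> F((la + 1) * (lb + 1));
  const size_t W = lb + 1;
  for (size_t i = 0; i <= la; ++i) F[i * W] = gap * (double)i;
  for (size_t j = 0; j <= lb; ++j) F[j] = gap * (double)j;
  for (size_t i = 1; i <= la; ++i) {
    const char ai = a[i - 1];
    for (size_t j = 1; j <= lb; ++j) {
      double diag = F[(i - 1) * W + (j - 1)] + subScore(ai, b[j - 1], match, mismatch);
      double up = F[(i - 1) * W + j] + gap;
      double left = F[i * W + (j - 1)] + gap;
      double best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      F[i * W + j] = best;
    }
  }
  // traceback, preferring diagonal, then up, then left
  std::string ra, rb;
  ra.reserve(la + lb);
  rb.reserve(la + lb);
  size_t i = la, j = lb;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        std::abs(F[i * W + j] - (F[(i - 1) * W + (j - 1)] +
                                 subScore(a[i - 1], b[j - 1], match, mismatch))) < eps) {
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      --i; --j;
    } else if (i > 0 &&
               std::abs(F[i * W + j] - (F[(i - 1) * W + j] + gap)) < eps) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
    } else {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = F[la * W + lb]);
}
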