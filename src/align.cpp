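#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman) over IUPAC bit-mask encoded
// sequences. Two codes score as a match when their base sets intersect.
// A gap of length L costs gap_open + gap_extend * L.
//
// Returns the single best local alignment: score, 0-based half-open query
// and subject spans, number of matching columns and total alignment length.

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector q, IntegerVector s,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int n = q.size(), m = s.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0);

  const int NEG = -1000000000;
  const int open_cost = gap_open + gap_extend;

  std::vector<int> H((n + 1) * (m + 1), 0);
  std::vector<int> E((n + 1) * (m + 1), NEG); // gap in query (consumes subject)
  std::vector<int> F((n + 1) * (m + 1), NEG); // gap in subject (consumes query)
  // traceback codes for H: 0 stop, 1 diagonal, 2 from E, 3 from F
  std::vector<unsigned char> TH((n + 1) * (m + 1), 0);
  // for E/F: 0 opened here, 1 extended
  std::vector<unsigned char> TE((n + 1) * (m + 1), 0);
  std::vector<unsigned char> TF((n + 1) * (m + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int qi = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int idx = i * (m + 1) + j;
      const int up = (i - 1) * (m + 1) + j;
      const int left = idx - 1;
      const int diag = up - 1;

      int e_open = H[left] - open_cost;
      int e_ext = E[left] - gap_extend;
      if (e_ext > e_open) { E[idx] = e_ext; TE[idx] = 1; }
      else { E[idx] = e_open; TE[idx] = 0; }

      int f_open = H[up] - open_cost;
      int f_ext = F[up] - gap_extend;
      if (f_ext > f_open) { F[idx] = f_ext; TF[idx] = 1; }
      else { F[idx] = f_open; TF[idx] = 0; }

      const int sub = ((qi & s[j - 1]) != 0) ? match : mismatch;
      int h = H[diag] + sub;
      unsigned char th = 1;
      if (E[idx] > h) { h = E[idx]; th = 2; }
      if (F[idx] > h) { h = F[idx]; th = 3; }
      if (h <= 0) { h = 0; th = 0; }
      H[idx] = h; TH[idx] = th;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best <= 0)
    return List::create(_["score"] = 0);

  // traceback
  int i = bi, j = bj;
  int matches = 0, alen = 0;
  int state = 0; // 0 in H, 1 in E, 2 in F
  while (true) {
    const int idx = i * (m + 1) + j;
    if (state == 0) {
      unsigned char t = TH[idx];
      if (t == 0) break;
      if (t == 1) {
        if ((q[i - 1] & s[j - 1]) != 0) ++matches;
        ++alen; --i; --j;
      } else if (t == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      ++alen;
      unsigned char t = TE[idx];
      --j;
      if (t == 0) state = 0;
    } else {
      ++alen;
      unsigned char t = TF[idx];
      --i;
      if (t == 0) state = 0;
    }
    if (i == 0 || j == 0) break;
  }

  return List::create(
    _["score"] = best,
    _["qstart"] = i, _["qend"] = bi,   // 0-based half-open on query
    _["sstart"] = j, _["send"] = bj,   // 0-based half-open on subject
    _["matches"] = matches,
    _["align_len"] = alen);
}
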