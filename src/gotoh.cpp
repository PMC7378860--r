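#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>

using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gap penalties, computed
// with Gotoh's three-state recursion.  A gap of length k costs
// gap_open + k * gap_extend (both passed as negative scores).
//
// State matrices:
//   M[i][j] : best score ending in an aligned pair (a_i, b_j)
//   X[i][j] : best score ending in a gap in the read  (consumes ref base i)
//   Y[i][j] : best score ending in a gap in the reference (consumes read base j)
//
// Traceback ties are broken deterministically: aligned pair (M) is preferred
// over a read gap (X), which is preferred over a reference gap (Y).  Within a
// gap state, extending the open gap is preferred, which pushes gap runs as
// far left as the score allows.

static const int NEG = std::numeric_limits<int>::min() / 4;

static inline int score_pair(char a, char b, int match, int mismatch) {
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string ref, std::string read,
                 int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int) ref.size();
  const int m = (int) read.size();
  const size_t W = (size_t) m + 1;

  std::vector<int> M((size_t)(n + 1) * W, NEG);
  std::vector<int> X((size_t)(n + 1) * W, NEG);
  std::vector<int> Y((size_t)(n + 1) * W, NEG);
  // traceback: which state each cell's best predecessor was in (0=M,1=X,2=Y)
  std::vector<unsigned char> tM((size_t)(n + 1) * W, 0);
  std::vector<unsigned char> tX((size_t)(n + 1) * W, 0);
  std::vector<unsigned char> tY((size_t)(n + 1) * W, 0);

#define IDX(i, j) ((size_t)(i) * W + (size_t)(j))

  M[IDX(0, 0)] = 0;
  for (int i = 1; i <= n; ++i) {
    X[IDX(i, 0)] = gap_open + i * gap_extend;
    tX[IDX(i, 0)] = 1;
  }
  tX[IDX(1, 0)] = 0;
  for (int j = 1; j <= m; ++j) {
    Y[IDX(0, j)] = gap_open + j * gap_extend;
    tY[IDX(0, j)] = 2;
  }
  tY[IDX(0, 1)] = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int s = score_pair(ref[i - 1], read[j - 1], match, mismatch);
      // M: from any state at (i-1, j-1); prefer M, then X, then Y
      {
        int best = M[IDX(i - 1, j - 1)]; unsigned char st = 0;
        if (X[IDX(i - 1, j - 1)] > best) { best = X[IDX(i - 1, j - 1)]; st = 1; }
        if (Y[IDX(i - 1, j - 1)] > best) { best = Y[IDX(i - 1, j - 1)]; st = 2; }
        M[IDX(i, j)] = (best <= NEG) ? NEG : best + s;
        tM[IDX(i, j)] = st;
      }
      // X: gap in read, consumes ref base i; prefer extension on ties
      {
        int ext = X[IDX(i - 1, j)] <= NEG ? NEG : X[IDX(i - 1, j)] + gap_extend;
        int opnM = M[IDX(i - 1, j)] <= NEG ? NEG : M[IDX(i - 1, j)] + gap_open + gap_extend;
        int opnY = Y[IDX(i - 1, j)] <= NEG ? NEG : Y[IDX(i - 1, j)] + gap_open + gap_extend;
        int best = ext; unsigned char st = 1;
        if (opnM > best) { best = opnM; st = 0; }
        if (opnY > best) { best = opnY; st = 2; }
        X[IDX(i, j)] = best;
        tX[IDX(i, j)] = st;
      }
      // Y: gap in reference, consumes read base j
      {
        int ext = Y[IDX(i, j - 1)] <= NEG ? NEG : Y[IDX(i, j - 1)] + gap_extend;
        int opnM = M[IDX(i, j - 1)] <= NEG ? NEG : M[IDX(i, j - 1)] + gap_open + gap_extend;
        int opnX = X[IDX(i, j - 1)] <= NEG ? NEG : X[IDX(i, j - 1)] + gap_open + gap_extend;
        int best = ext; unsigned char st = 2;
        if (opnM > best) { best = opnM; st = 0; }
        if (opnX > best) { best = opnX; st = 1; }
        Y[IDX(i, j)] = best;
        tY[IDX(i, j)] = st;
      }
    }
  }

  // terminal state: prefer M over X over Y on ties
  int best = M[IDX(n, m)]; int state = 0;
  if (X[IDX(n, m)] > best) { best = X[IDX(n, m)]; state = 1; }
  if (Y[IDX(n, m)] > best) { best = Y[IDX(n, m)]; state = 2; }

  std::string aref, aread;
  aref.reserve(n + m); aread.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char prev = tM[IDX(i, j)];
      aref.push_back(ref[i - 1]);
      aread.push_back(read[j - 1]);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      unsigned char prev = tX[IDX(i, j)];
      aref.push_back(ref[i - 1]);
      aread.push_back('-');
      --i;
      state = prev;
    } else {
      unsigned char prev = tY[IDX(i, j)];
      aref.push_back('-');
      aread.push_back(read[j - 1]);
      --j;
      state = prev;
    }
  }
  std::reverse(aref.begin(), aref.end());
  std::reverse(aread.begin(), aread.end());

#undef IDX

  return List::create(_["ref"] = aref, _["read"] = aread, _["score"] = best);
}
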