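#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Affine-gap semi-global alignment (Gotoh): the read is aligned globally,
// the reference contributes free (unpenalised) end gaps. A gap of length L
// costs gap_open + L * gap_extend.
//
// Three-state DP over (read position i, reference position j):
//   M: read[i-1] aligned to ref[j-1]
//   X: read[i-1] aligned to a gap (insertion relative to the reference)
//   Y: ref[j-1] aligned to a gap (deletion from the read)
// The alignment may start after any reference prefix at zero cost and the
// final score is maximised over reference end positions (free suffix).
// Tie-breaking is deterministic: state preference M > X > Y at every
// choice point, and the smallest reference end position on final ties.

static const double NEG = -1e18;

// predecessor codes for traceback
enum Pred { FROM_START = 0, FROM_M = 1, FROM_X = 2, FROM_Y = 3 };

// [[Rcpp::export(name = ".gotoh_semiglobal")]]
List gotoh_semiglobal(std::string read, std::string ref,
                      double match = 1.0, double mismatch = -1.0,
                      double gap_open = -4.0, double gap_extend = -1.0) {
  const int n = (int)read.size();
  const int m = (int)ref.size();
  if (n == 0 || m == 0) stop("empty sequence");

  const double go = gap_open + gap_extend;  // cost of first gapped base
  const double ge = gap_extend;

  std::vector<double> M((size_t)(n + 1) * (m + 1), NEG);
  std::vector<double> X((size_t)(n + 1) * (m + 1), NEG);
  std::vector<double> Y((size_t)(n + 1) * (m + 1), NEG);
  std::vector<signed char> tbM((size_t)(n + 1) * (m + 1), -1);
  std::vector<signed char> tbX((size_t)(n + 1) * (m + 1), -1);
  std::vector<signed char> tbY((size_t)(n + 1) * (m + 1), -1);
  const int W = m + 1;
#define IDX(i, j) ((size_t)(i) * W + (j))

  for (int i = 1; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      // M: diagonal move, requires j >= 1
      if (j >= 1) {
        double s = (read[i - 1] == ref[j - 1]) ? match : mismatch;
        double best;
        signed char from;
        if (i == 1) {  // free reference prefix [0, j-1)
          best = 0.0;
          from = FROM_START;
        } else {
          best = M[IDX(i - 1, j - 1)];
          from = FROM_M;
          if (X[IDX(i - 1, j - 1)] > best) { best = X[IDX(i - 1, j - 1)]; from = FROM_X; }
          if (Y[IDX(i - 1, j - 1)] > best) { best = Y[IDX(i - 1, j - 1)]; from = FROM_Y; }
        }
        if (best > NEG / 2) {
          M[IDX(i, j)] = best + s;
          tbM[IDX(i, j)] = from;
        }
      }
      // X: insertion (consume read base i against a gap at ref position j)
      if (i == 1) {
        // open a gap straight from the start state (free ref prefix [0, j))
        X[IDX(i, j)] = go;
        tbX[IDX(i, j)] = FROM_START;
      } else {
        double candM = (M[IDX(i - 1, j)] > NEG / 2) ? M[IDX(i - 1, j)] + go : NEG;
        double candX = (X[IDX(i - 1, j)] > NEG / 2) ? X[IDX(i - 1, j)] + ge : NEG;
        double candY = (Y[IDX(i - 1, j)] > NEG / 2) ? Y[IDX(i - 1, j)] + go : NEG;
        double best = candM;
        signed char from = FROM_M;
        if (candX > best) { best = candX; from = FROM_X; }
        if (candY > best) { best = candY; from = FROM_Y; }
        if (best > NEG / 2) {
          X[IDX(i, j)] = best;
          tbX[IDX(i, j)] = from;
        }
      }
      // Y: deletion (consume ref base j against a gap), requires j >= 1, i >= 1
      if (j >= 1) {
        double candM = (M[IDX(i, j - 1)] > NEG / 2) ? M[IDX(i, j - 1)] + go : NEG;
        double candX = (X[IDX(i, j - 1)] > NEG / 2) ? X[IDX(i, j - 1)] + go : NEG;
        double candY = (Y[IDX(i, j - 1)] > NEG / 2) ? Y[IDX(i, j - 1)] + ge : NEG;
        double best = candM;
        signed char from = FROM_M;
        if (candX > best) { best = candX; from = FROM_X; }
        if (candY > best) { best = candY; from = FROM_Y; }
        if (best > NEG / 2) {
          Y[IDX(i, j)] = best;
          tbY[IDX(i, j)] = from;
        }
      }
    }
  }

  // final: max over reference end positions, states M then X (a trailing
  // deletion before a free suffix is never reported); smallest j on ties
  double bestScore = NEG;
  int bestJ = -1;
  signed char bestState = FROM_M;
  for (int j = 0; j <= m; ++j) {
    if (M[IDX(n, j)] > bestScore) { bestScore = M[IDX(n, j)]; bestJ = j; bestState = FROM_M; }
    if (X[IDX(n, j)] > bestScore) { bestScore = X[IDX(n, j)]; bestJ = j; bestState = FROM_X; }
  }
  if (bestJ < 0) stop("alignment failed");

  // traceback: per-base ops, 1=match 2=mismatch 3=ins 4=del
  std::vector<int> ops;
  int i = n, j = bestJ;
  signed char state = bestState;
  while (true) {
    signed char from;
    if (state == FROM_M) {
      from = tbM[IDX(i, j)];
      ops.push_back(read[i - 1] == ref[j - 1] ? 1 : 2);
      --i; --j;
    } else if (state == FROM_X) {
      from = tbX[IDX(i, j)];
      ops.push_back(3);
      --i;
    } else {
      from = tbY[IDX(i, j)];
      ops.push_back(4);
      --j;
    }
    if (from == FROM_START) break;
    state = from;
  }
  int refStart = j;  // reference prefix [0, refStart) skipped for free
  std::reverse(ops.begin(), ops.end());

  // compress per-base ops into runs with coordinates
  std::vector<int> runOp, runLen, runRef, runRead;
  int rp = refStart, qp = 0;
  for (size_t k = 0; k < ops.size();) {
    size_t k2 = k;
    while (k2 < ops.size() && ops[k2] == ops[k]) ++k2;
    int len = (int)(k2 - k);
    runOp.push_back(ops[k]);
    runLen.push_back(len);
    runRef.push_back(rp);
    runRead.push_back(qp);
    if (ops[k] == 1 || ops[k] == 2) { rp += len; qp += len; }
    else if (ops[k] == 3) { qp += len; }
    else { rp += len; }
    k = k2;
  }

  IntegerMatrix runs((int)runOp.size(), 4);
  for (int r = 0; r < (int)runOp.size(); ++r) {
    runs(r, 0) = runOp[r];
    runs(r, 1) = runLen[r];
    runs(r, 2) = runRef[r];
    runs(r, 3) = runRead[r];
  }
  colnames(runs) = CharacterVector::create("op", "length", "ref_pos", "read_pos");

  return List::create(_["score"] = bestScore,
                      _["runs"] = runs,
                      _["ref_start"] = refStart,
                      _["ref_end"] = rp);
}
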