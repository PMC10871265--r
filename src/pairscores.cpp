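#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Best common-line score between every pair of images.
//
// sig: numeric array with dim (L, A, n): 1D line projections, L bins per
// signal, A projection angles, n images. For each ordered image pair the
// measure is evaluated on all A x A angle pairs and the optimum kept
// (minimum for distances L1/L2/wasserstein, maximum for similarities
// cosine/correlation), ties broken by the lexicographically smallest
// (angle_i, angle_j) index pair. Zero-variance signals under correlation
// (and zero-norm under cosine) score 0 and are skipped for the argmax;
// their count is returned in n_degenerate.
//
// Returns score, ai, aj as n x n matrices (0-based angle indices, diag NA).

enum Measure { M_L1, M_L2, M_COS, M_COR, M_WAS };

// [[Rcpp::export]]
List pair_scores_cpp(NumericVector sig, std::string measure) {
  IntegerVector dims = sig.attr("dim");
  if (dims.size() != 3) stop("sig must have dim (L, A, n)");
  const int L = dims[0], A = dims[1], n = dims[2];

  Measure ms;
  if (measure == "L1") ms = M_L1;
  else if (measure == "L2") ms = M_L2;
  else if (measure == "cosine") ms = M_COS;
  else if (measure == "correlation") ms = M_COR;
  else if (measure == "wasserstein") ms = M_WAS;
  else stop("unknown measure: " + measure);

  const bool is_dist = (ms == M_L1 || ms == M_L2 || ms == M_WAS);
  const double *x = REAL(sig);

  // preprocessed signals: centered (correlation), raw + norms (cosine),
  // CDF of min-shifted mass-normalized signal (wasserstein)
  std::vector<double> prep;
  std::vector<double> nrm((size_t)n * A, 0.0);
  int degenerate = 0;
  if (ms == M_COR || ms == M_WAS || ms == M_COS) {
    prep.resize((size_t)n * A * L);
    for (int i = 0; i < n; ++i) for (int a = 0; a < A; ++a) {
      const double *s = x + ((size_t)i * A + a) * L;
      double *p = &prep[((size_t)i * A + a) * L];
      if (ms == M_COR) {
        double m = 0; for (int l = 0; l < L; ++l) m += s[l];
        m /= L;
        double ss = 0;
        for (int l = 0; l < L; ++l) { p[l] = s[l] - m; ss += p[l] * p[l]; }
        nrm[(size_t)i * A + a] = std::sqrt(ss);
        if (ss == 0) ++degenerate;
      } else if (ms == M_COS) {
        double ss = 0;
        for (int l = 0; l < L; ++l) { p[l] = s[l]; ss += s[l] * s[l]; }
        nrm[(size_t)i * A + a] = std::sqrt(ss);
        if (ss == 0) ++degenerate;
      } else {
        double mn = s[0];
        for (int l = 1; l < L; ++l) if (s[l] < mn) mn = s[l];
        double mass = 0;
        for (int l = 0; l < L; ++l) mass += s[l] - mn;
        if (mass <= 0) stop("wasserstein: zero-mass signal");
        double c = 0;
        for (int l = 0; l < L; ++l) { c += (s[l] - mn) / mass; p[l] = c; }
      }
    }
  }
  const double *pp = prep.empty() ? x : prep.data();

  NumericMatrix score(n, n), aim(n, n), ajm(n, n);
  std::fill(score.begin(), score.end(), NA_REAL);
  std::fill(aim.begin(), aim.end(), NA_REAL);
  std::fill(ajm.begin(), ajm.end(), NA_REAL);

  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      // track the optimum under both tie-break orders: (ai,aj) for entry
      // (i,j) and (aj,ai) for entry (j,i)
      double best_ij = is_dist ? R_PosInf : R_NegInf;
      int bi_ij = -1, bj_ij = -1;
      double best_ji = best_ij;
      int bi_ji = -1, bj_ji = -1;
      for (int a = 0; a < A; ++a) {
        const double *si = pp + ((size_t)i * A + a) * L;
        const double ni = nrm[(size_t)i * A + a];
        for (int b = 0; b < A; ++b) {
          const double *sj = pp + ((size_t)j * A + b) * L;
          double v = 0.0;
          switch (ms) {
          case M_L1:
            for (int l = 0; l < L; ++l) v += std::fabs(si[l] - sj[l]);
            break;
          case M_L2: {
            for (int l = 0; l < L; ++l) {
              double d = si[l] - sj[l]; v += d * d;
            }
            v = std::sqrt(v);
            break;
          }
          case M_WAS:
            for (int l = 0; l < L; ++l) v += std::fabs(si[l] - sj[l]);
            break;
          case M_COS: {
            double nj = nrm[(size_t)j * A + b];
            if (ni == 0 || nj == 0) { v = 0; break; }
            double dp = 0;
            for (int l = 0; l < L; ++l) dp += si[l] * sj[l];
            v = dp / (ni * nj);
            break;
          }
          case M_COR: {
            double nj = nrm[(size_t)j * A + b];
            if (ni == 0 || nj == 0) { v = 0; break; }
            double dp = 0;
            for (int l = 0; l < L; ++l) dp += si[l] * sj[l];
            v = dp / (ni * nj);
            break;
          }
          }
          bool skip = false;
          if ((ms == M_COS || ms == M_COR) &&
              (ni == 0 || nrm[(size_t)j * A + b] == 0))
            skip = true; // degenerate pair: similarity 0, not an argmax
          if (!skip) {
            if (is_dist ? (v < best_ij) : (v > best_ij)) {
              best_ij = v; bi_ij = a; bj_ij = b;
            }
            // order (b, a) lexicographic for the mirrored entry: b-major
            // scanning would visit (b, a); strict improvement on that order
            if (is_dist ? (v < best_ji) : (v > best_ji)) {
              best_ji = v; bi_ji = a; bj_ji = b;
            } else if (v == best_ji &&
                       (b < bj_ji || (b == bj_ji && a < bi_ji))) {
              bi_ji = a; bj_ji = b;
            }
          }
        }
      }
      if (bi_ij < 0) { // all pairs degenerate
        best_ij = 0; bi_ij = 0; bj_ij = 0;
        best_ji = 0; bi_ji = 0; bj_ji = 0;
      }
      score(i, j) = best_ij; aim(i, j) = bi_ij; ajm(i, j) = bj_ij;
      score(j, i) = best_ji; aim(j, i) = bj_ji; ajm(j, i) = bi_ji;
    }
  }

  return List::create(_["score"] = score, _["ai"] = aim, _["aj"] = ajm,
                      _["n_degenerate"] = degenerate);
}
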