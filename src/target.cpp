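#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Expectation scoring of a milRNA against a target site, psRNATarget-style.
//
// q   = reverse complement of the milRNA, so it reads in the target's 5'->3'
//       orientation and a perfect site equals q letter-for-letter.
// y   = candidate target site (5'->3').
// q position k (1-based) corresponds to milRNA position n-k+1 from the
// milRNA 5' end; penalties at milRNA positions in the seed range are
// multiplied by seed_mult. G:U wobbles appear, after the q transform, as
// (q,y) = (C,U) or (A,G).
//
// Alignment is global in q with at most gap_max gaps, which confines the
// DP to the band |i-j| <= gap_max; with free_end the aligned site may
// stop short of the end of y (used by the window scan). An insertion
// (unaligned y base) is attributed to the milRNA position of the
// following q base (clamped at the milRNA 5' end).

static const double INF = std::numeric_limits<double>::infinity();

struct DPRes {
  double score;
  int y_used;                // site bases consumed
  std::vector<int> ops;      // 0 match, 1 wobble, 2 mismatch, 3 del(q), 4 ins(y)
  std::vector<int> milpos;   // milRNA position (1-based) per alignment column
};

static inline int cls(char a, char b) {
  if (a == b) return 0;
  if ((a == 'C' && b == 'U') || (a == 'A' && b == 'G')) return 1;  // G:U wobble
  return 2;
}

struct Scorer {
  std::string q;
  double w_mismatch, w_wobble, w_gap, seed_mult;
  int seed_lo, seed_hi, gap_max;
  std::vector<double> dp;  // reused across calls

  Scorer(const std::string& q_, double wm, double ww, double wg, double sm,
         int lo, int hi, int g)
      : q(q_), w_mismatch(wm), w_wobble(ww), w_gap(wg), seed_mult(sm),
        seed_lo(lo), seed_hi(hi), gap_max(g) {}

  double wt(int qpos) const {  // weight of milRNA position for q index qpos
    int n = q.size();
    int mp = n - qpos + 1;
    if (mp < 1) mp = 1;
    return (mp >= seed_lo && mp <= seed_hi) ? seed_mult : 1.0;
  }
  double wsub(int c) const {
    return c == 0 ? 0.0 : (c == 1 ? w_wobble : w_mismatch);
  }

  // DP over q vs y[y_off .. y_off+y_len), banded to |i-j| <= gap_max.
  DPRes run(const std::string& y, int y_off, int y_len, bool free_end,
            bool traceback) {
    int n = q.size(), m = y_len;
    int G = gap_max + 1;
    DPRes res;
    res.score = INF;
    res.y_used = -1;
    if (!free_end && std::abs(n - m) > gap_max) return res;

    size_t need = (size_t)(n + 1) * (m + 1) * G;
    if (dp.size() < need) dp.resize(need);
    auto D = [&](int i, int j, int g) -> double& {
      return dp[((size_t)i * (m + 1) + j) * G + g];
    };
    // initialize only band cells
    for (int i = 0; i <= n; ++i) {
      int jlo = std::max(0, i - gap_max), jhi = std::min(m, i + gap_max);
      for (int j = jlo; j <= jhi; ++j)
        for (int g = 0; g < G; ++g) D(i, j, g) = INF;
    }
    D(0, 0, 0) = 0.0;
    for (int i = 0; i <= n; ++i) {
      int jlo = std::max(0, i - gap_max), jhi = std::min(m, i + gap_max);
      for (int j = jlo; j <= jhi; ++j) {
        for (int g = 0; g < G; ++g) {
          double cur = D(i, j, g);
          if (cur == INF) continue;
          if (i < n && j < m) {
            double v = cur + wsub(cls(q[i], y[y_off + j])) * wt(i + 1);
            if (v < D(i + 1, j + 1, g)) D(i + 1, j + 1, g) = v;
          }
          if (g + 1 < G) {
            if (i < n && std::abs((i + 1) - j) <= gap_max) {
              double v = cur + w_gap * wt(i + 1);  // q base unaligned
              if (v < D(i + 1, j, g + 1)) D(i + 1, j, g + 1) = v;
            }
            if (j < m && std::abs(i - (j + 1)) <= gap_max) {
              int nxt = (i < n) ? i + 1 : n;  // y base unaligned
              double v = cur + w_gap * wt(nxt);
              if (v < D(i, j + 1, g + 1)) D(i, j + 1, g + 1) = v;
            }
          }
        }
      }
    }
    int j_lo = free_end ? std::max(0, n - gap_max) : m;
    int best_j = -1, best_g = -1;
    for (int j = j_lo; j <= m; ++j) {
      if (std::abs(n - j) > gap_max) continue;
      for (int g = 0; g < G; ++g) {
        if (D(n, j, g) < res.score) {
          res.score = D(n, j, g);
          best_j = j;
          best_g = g;
        }
      }
    }
    res.y_used = best_j;
    if (!traceback || best_j < 0) return res;

    // deterministic backward traceback: diagonal first, then del, then ins
    int i = n, j = best_j, g = best_g;
    const double eps = 1e-9;
    while (i > 0 || j > 0) {
      double cur = D(i, j, g);
      if (i > 0 && j > 0 &&
          std::abs(D(i - 1, j - 1, g) +
                   wsub(cls(q[i - 1], y[y_off + j - 1])) * wt(i) - cur) < eps) {
        res.ops.push_back(cls(q[i - 1], y[y_off + j - 1]));
        res.milpos.push_back((int)q.size() - i + 1);
        --i; --j;
      } else if (i > 0 && g > 0 &&
                 std::abs(D(i - 1, j, g - 1) + w_gap * wt(i) - cur) < eps) {
        res.ops.push_back(3);
        res.milpos.push_back((int)q.size() - i + 1);
        --i; --g;
      } else {
        int nq = q.size();
        int nxt = (i < nq) ? i + 1 : nq;
        res.ops.push_back(4);
        int mp = nq - nxt + 1;
        res.milpos.push_back(mp < 1 ? 1 : mp);
        --j; --g;
      }
    }
    std::reverse(res.ops.begin(), res.ops.end());
    std::reverse(res.milpos.begin(), res.milpos.end());
    return res;
  }
};

// [[Rcpp::export]]
List expectation_dp_cpp(std::string q, std::string y, double w_mismatch,
                        double w_wobble, double w_gap, double seed_mult,
                        int seed_lo, int seed_hi, int gap_max) {
  Scorer sc(q, w_mismatch, w_wobble, w_gap, seed_mult, seed_lo, seed_hi,
            gap_max);
  DPRes r = sc.run(y, 0, y.size(), false, true);
  return List::create(_["score"] = r.score,
                      _["ops"] = IntegerVector(r.ops.begin(), r.ops.end()),
                      _["milpos"] = IntegerVector(r.milpos.begin(), r.milpos.end()));
}

// Scan every window start of `target` against q; report the minimal-
// expectation site (ties: smallest start).
// [[Rcpp::export]]
List target_scan_cpp(std::string q, std::string target, double w_mismatch,
                     double w_wobble, double w_gap, double seed_mult,
                     int seed_lo, int seed_hi, int gap_max, double exp_max) {
  int n = q.size(), T = target.size();
  Scorer sc(q, w_mismatch, w_wobble, w_gap, seed_mult, seed_lo, seed_hi,
            gap_max);
  double best = INF;
  int best_start = -1, best_len = -1;
  for (int p = 0; p < T; ++p) {
    int L = std::min(n + gap_max, T - p);
    if (L < n - gap_max) break;
    DPRes r = sc.run(target, p, L, true, false);
    if (r.score < best - 1e-12) {
      best = r.score;
      best_start = p;
      best_len = r.y_used;
    }
  }
  if (best_start < 0 || best > exp_max) {
    return List::create(_["found"] = false);
  }
  DPRes r = sc.run(target, best_start, best_len, false, true);
  return List::create(_["found"] = true, _["score"] = r.score,
                      _["start"] = best_start, _["len"] = best_len,
                      _["ops"] = IntegerVector(r.ops.begin(), r.ops.end()),
                      _["milpos"] = IntegerVector(r.milpos.begin(), r.milpos.end()));
}
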