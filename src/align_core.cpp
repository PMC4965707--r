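#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Log-likelihood-ratio scoring for Rmap overlap alignment.
// A matched interval pair (gap ga in map a, gap gb in map b, skipping ka/kb
// labels since the previous match) scores
//   match_reward - delta^2 / (2 sigma^2) - (ka + kb) * skip_penalty
// with delta = ga - gb and sigma^2 = (sizing_sd/1000)^2 * (ga^2 + gb^2):
// both maps carry interval-proportional sizing noise, so the discrepancy
// variance is the sum of the two variances. match_reward is the
// -log chance probability of two labels co-locating within sizing error;
// skip_penalty is -log of the probability that a label is erroneous
// (a false positive, or its partner site unlabeled).

struct ScoreModel {
  double sizing_sd;     // bp per kbp of interval
  double match_reward;  // per matched pair
  double skip_penalty;  // per skipped label inside the overlap
  int max_skip;         // max skipped labels per side between matches
};

static ScoreModel make_model(double fp_per_100kbp, double fn_rate,
                             double sizing_sd, double site_density,
                             int max_skip) {
  ScoreModel m;
  m.sizing_sd = sizing_sd;
  m.max_skip = max_skip;
  double fp_frac = fp_per_100kbp / (fp_per_100kbp + site_density);
  double p_err = fn_rate + fp_frac - fn_rate * fp_frac;
  p_err = std::min(std::max(p_err, 1e-6), 0.999);
  m.skip_penalty = -std::log(p_err);
  double mean_spacing = 1e5 / site_density;           // bp between true sites
  double sigma_bar = sizing_sd * mean_spacing / 1000; // typical sizing sd
  double p_chance = 4.0 * sigma_bar / mean_spacing;   // label within ~2 sd
  p_chance = std::min(std::max(p_chance, 1e-6), 0.9);
  m.match_reward = -std::log(p_chance);
  return m;
}

static inline double chunk_score(double ga, double gb, int ka, int kb,
                                 const ScoreModel& m) {
  double sigma = std::max(m.sizing_sd * std::sqrt(ga * ga + gb * gb) / 1000.0,
                          1e-6);
  double delta = ga - gb;
  return m.match_reward - 0.5 * delta * delta / (sigma * sigma)
         - (ka + kb) * m.skip_penalty;
}

struct DpResult {
  double score;
  int npairs;
  std::vector<int> ai, bi; // 0-based matched indices
  bool found;
};

// Ends-free DP over monotone matchings with bounded skips between
// consecutive matches. Reported alignments need >= 2 matched pairs, so two
// quantities are tracked per cell: S, the best chain ending at (i, j) of
// any length (what extensions build on; a fresh single match may beat any
// continuation), and S2, the best chain of length >= 2 ending at (i, j)
// (what may be reported).
static DpResult dp_align(const std::vector<double>& a,
                         const std::vector<double>& b,
                         const ScoreModel& m) {
  int n = (int)a.size(), mm = (int)b.size();
  DpResult res; res.found = false; res.score = -1e300; res.npairs = 0;
  if (n < 2 || mm < 2) return res;
  size_t sz = (size_t)n * mm;
  std::vector<double> S(sz, 0.0), S2(sz, -1e300);
  std::vector<int> L(sz, 1), L2(sz, 0), P(sz, -1), P2(sz, -1);
  int besti = -1;
  double bestS = -1e300; int bestL = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < mm; ++j) {
      size_t c = (size_t)i * mm + j;
      double t = -1e300; int tlen = 0; int tpar = -1;
      int i0 = std::max(0, i - 1 - m.max_skip);
      int j0 = std::max(0, j - 1 - m.max_skip);
      for (int ip = i - 1; ip >= i0; --ip) {
        double ga = a[i] - a[ip];
        for (int jp = j - 1; jp >= j0; --jp) {
          size_t cp = (size_t)ip * mm + jp;
          double cand = S[cp] + chunk_score(ga, b[j] - b[jp],
                                            i - ip - 1, j - jp - 1, m);
          int cl = L[cp] + 1;
          if (cand > t + 1e-12 ||
              (cand > t - 1e-12 && cl > tlen)) {
            t = cand; tlen = cl; tpar = (int)cp;
          }
        }
      }
      S2[c] = t; L2[c] = tlen; P2[c] = tpar;
      if (t > m.match_reward + 1e-12 ||
          (t > m.match_reward - 1e-12 && tlen > 1)) {
        S[c] = t; L[c] = tlen; P[c] = tpar;
      } else {
        S[c] = m.match_reward; L[c] = 1; P[c] = -1;
      }
      if (tlen >= 2 && (t > bestS + 1e-12 ||
                        (t > bestS - 1e-12 && tlen > bestL))) {
        bestS = t; bestL = tlen; besti = (int)c;
      }
    }
  }
  if (besti < 0) return res;
  res.found = true; res.score = bestS; res.npairs = bestL;
  res.ai.push_back(besti / mm);
  res.bi.push_back(besti % mm);
  int c = P2[besti];
  while (c >= 0) {
    res.ai.push_back(c / mm);
    res.bi.push_back(c % mm);
    c = P[c];
  }
  std::reverse(res.ai.begin(), res.ai.end());
  std::reverse(res.bi.begin(), res.bi.end());
  return res;
}

static std::vector<double> reflect(const std::vector<double>& b, double len) {
  std::vector<double> r(b.size());
  for (size_t k = 0; k < b.size(); ++k) r[k] = len - b[b.size() - 1 - k];
  return r;
}

static double offset_of(const std::vector<double>& a,
                        const std::vector<double>& bo, const DpResult& r) {
  double s = 0;
  for (int k = 0; k < r.npairs; ++k) s += a[r.ai[k]] - bo[r.bi[k]];
  return s / r.npairs;
}

// Best alignment over both orientations of b. Tie-break: higher score, more
// matched pairs, smaller |offset|, forward orientation.
static void best_both(const std::vector<double>& a,
                      const std::vector<double>& b, double len_b,
                      const ScoreModel& m,
                      DpResult& best, int& orient, double& offset,
                      const std::vector<double>** bo_used,
                      std::vector<double>& brev_store) {
  DpResult fw = dp_align(a, b, m);
  brev_store = reflect(b, len_b);
  DpResult rv = dp_align(a, brev_store, m);
  double off_f = fw.found ? offset_of(a, b, fw) : 0;
  double off_r = rv.found ? offset_of(a, brev_store, rv) : 0;
  bool take_rv;
  if (!fw.found) take_rv = rv.found;
  else if (!rv.found) take_rv = false;
  else if (rv.score > fw.score + 1e-9) take_rv = true;
  else if (fw.score > rv.score + 1e-9) take_rv = false;
  else if (rv.npairs != fw.npairs) take_rv = rv.npairs > fw.npairs;
  else take_rv = std::fabs(off_r) < std::fabs(off_f) - 1e-9;
  if (take_rv) {
    best = rv; orient = -1; offset = off_r;
    if (bo_used) *bo_used = &brev_store;
  } else {
    best = fw; orient = 1; offset = off_f;
    if (bo_used) *bo_used = &b;
  }
}

// [[Rcpp::export]]
List rmap_align_core(NumericVector a_pos, NumericVector b_pos, double len_b,
                     double fp_per_100kbp, double fn_rate, double sizing_sd,
                     double site_density, int max_skip, int null_reps) {
  std::vector<double> a(a_pos.begin(), a_pos.end());
  std::vector<double> b(b_pos.begin(), b_pos.end());
  ScoreModel m = make_model(fp_per_100kbp, fn_rate, sizing_sd,
                            site_density, max_skip);
  DpResult best; int orient = 1; double offset = 0;
  const std::vector<double>* bo = nullptr;
  std::vector<double> brev;
  best_both(a, b, len_b, m, best, orient, offset, &bo, brev);

  if (!best.found) {
    return List::create(_["found"] = false);
  }
  // unmatched labels strictly inside the matched window
  int ua = (best.ai.back() - best.ai.front() + 1) - best.npairs;
  int ub = (best.bi.back() - best.bi.front() + 1) - best.npairs;

  NumericVector nulls(null_reps);
  if (null_reps > 0) {
    int nb = (int)b.size();
    std::vector<double> gaps(nb), shuffled(nb), bstar(nb);
    gaps[0] = b[0];
    for (int k = 1; k < nb; ++k) gaps[k] = b[k] - b[k - 1];
    for (int r = 0; r < null_reps; ++r) {
      shuffled = gaps;
      for (int k = nb - 1; k > 0; --k) {  // Fisher-Yates via R's RNG
        int j = (int)std::floor(unif_rand() * (k + 1));
        if (j > k) j = k;
        std::swap(shuffled[k], shuffled[j]);
      }
      double cum = 0;
      for (int k = 0; k < nb; ++k) { cum += shuffled[k]; bstar[k] = cum; }
      DpResult nb_best; int no; double noff;
      std::vector<double> tmp;
      best_both(a, bstar, len_b, m, nb_best, no, noff, nullptr, tmp);
      nulls[r] = nb_best.found ? nb_best.score : -1e300;
    }
  }

  IntegerVector ai(best.ai.begin(), best.ai.end());
  IntegerVector bi(best.bi.begin(), best.bi.end());
  // 1-based indices for R
  for (int k = 0; k < ai.size(); ++k) { ai[k] += 1; bi[k] += 1; }
  return List::create(
    _["found"] = true,
    _["score"] = best.score,
    _["orientation"] = orient,
    _["offset_bp"] = offset,
    _["idx_a"] = ai,
    _["idx_b"] = bi,
    _["unmatched_a"] = ua,
    _["unmatched_b"] = ub,
    _["null_scores"] = nulls);
}
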