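#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// ln(x!) via log-gamma; exact enough for N in the thousands, never overflows
static inline double lfact(int x) { return R::lgammafn((double)x + 1.0); }

// Flattened split structure of a cluster tree:
//   tips      : 1-based tip indices, concatenated over all children of all splits
//   child_ptr : 0-based offsets into tips, length (#children + 1)
//   split_ptr : 0-based offsets into child_ptr, length (R + 1)
// Label codes: 0 = missing, 1..kappa = class.

struct SplitScore {
  double score;
  bool degenerate; // N <= 1 after missing-exclusion, or a single non-empty child
};

static SplitScore score_one_split(const int *tips, const int *child_ptr,
                                  int c_from, int c_to,
                                  const int *codes, int kappa,
                                  std::vector<int> &n_buf,
                                  std::vector<int> &m_buf) {
  std::fill(n_buf.begin(), n_buf.end(), 0);
  int N = 0, nonempty = 0;
  double child_term = 0.0;
  for (int c = c_from; c < c_to; ++c) {
    std::fill(m_buf.begin(), m_buf.end(), 0);
    int mi = 0;
    for (int k = child_ptr[c]; k < child_ptr[c + 1]; ++k) {
      int lab = codes[tips[k] - 1];
      if (lab > 0) {
        ++m_buf[lab - 1];
        ++mi;
      }
    }
    if (mi > 0) ++nonempty;
    N += mi;
    double inner = lfact(mi);
    for (int l = 0; l < kappa; ++l) {
      if (m_buf[l] > 0) {
        inner -= lfact(m_buf[l]);
        n_buf[l] += m_buf[l];
      }
    }
    child_term += inner;
  }
  double s = lfact(N);
  for (int l = 0; l < kappa; ++l) s -= lfact(n_buf[l]);
  s -= child_term;
  if (s < 0.0) s = 0.0; // clip tiny negative round-off
  SplitScore out;
  out.score = s;
  out.degenerate = (N <= 1) || (nonempty <= 1);
  return out;
}

static double ti_from_scores(const std::vector<double> &scores) {
  size_t R = scores.size();
  if (R == 0) return 0.0;
  double mean = 0.0;
  for (double s : scores) mean += s;
  mean /= (double)R;
  double ss = 0.0;
  for (double s : scores) ss += (s - mean) * (s - mean);
  return std::sqrt(ss / (double)R); // population SD, divisor R
}

static double ti_core(const int *tips, const int *child_ptr, const int *split_ptr,
                      int R, const int *codes, int kappa, bool skip_degenerate,
                      std::vector<int> &n_buf, std::vector<int> &m_buf,
                      std::vector<double> &scores) {
  scores.clear();
  for (int r = 0; r < R; ++r) {
    SplitScore s = score_one_split(tips, child_ptr, split_ptr[r], split_ptr[r + 1],
                                   codes, kappa, n_buf, m_buf);
    if (skip_degenerate && s.degenerate) continue;
    scores.push_back(s.score);
  }
  return ti_from_scores(scores);
}

// [[Rcpp::export]]
List cpp_split_table(IntegerVector tips, IntegerVector child_ptr,
                     IntegerVector split_ptr, IntegerVector codes, int kappa) {
  int R = split_ptr.size() - 1;
  NumericVector score(R);
  IntegerVector N(R), n_children(R);
  LogicalVector degenerate(R);
  std::vector<int> n_buf(kappa), m_buf(kappa);
  for (int r = 0; r < R; ++r) {
    int c_from = split_ptr[r], c_to = split_ptr[r + 1];
    SplitScore s = score_one_split(tips.begin(), child_ptr.begin(), c_from, c_to,
                                   codes.begin(), kappa, n_buf, m_buf);
    score[r] = s.score;
    degenerate[r] = s.degenerate;
    n_children[r] = c_to - c_from;
    int tot = 0;
    for (int c = c_from; c < c_to; ++c)
      for (int k = child_ptr[c]; k < child_ptr[c + 1]; ++k)
        if (codes[tips[k] - 1] > 0) ++tot;
    N[r] = tot;
  }
  return List::create(_["score"] = score, _["N"] = N,
                      _["n_children"] = n_children, _["degenerate"] = degenerate);
}

// [[Rcpp::export]]
double cpp_ti(IntegerVector tips, IntegerVector child_ptr, IntegerVector split_ptr,
              IntegerVector codes, int kappa, bool skip_degenerate) {
  int R = split_ptr.size() - 1;
  std::vector<int> n_buf(kappa), m_buf(kappa);
  std::vector<double> scores;
  scores.reserve(R);
  return ti_core(tips.begin(), child_ptr.begin(), split_ptr.begin(), R,
                 codes.begin(), kappa, skip_degenerate, n_buf, m_buf, scores);
}

// r TIs of the fixed tree under independent uniform label permutations.
// Uses R's RNG (set.seed-reproducible).
// [[Rcpp::export]]
NumericVector cpp_permuted_tis(IntegerVector tips, IntegerVector child_ptr,
                               IntegerVector split_ptr, IntegerVector codes,
                               int kappa, int r, bool skip_degenerate) {
  int R = split_ptr.size() - 1;
  int d = codes.size();
  std::vector<int> perm(codes.begin(), codes.end());
  std::vector<int> n_buf(kappa), m_buf(kappa);
  std::vector<double> scores;
  scores.reserve(R);
  NumericVector out(r);
  for (int i = 0; i < r; ++i) {
    // Fisher-Yates shuffle of the full label vector (missing markers included)
    for (int j = d - 1; j > 0; --j) {
      int k = (int)(R::unif_rand() * (j + 1));
      if (k > j) k = j;
      std::swap(perm[j], perm[k]);
    }
    out[i] = ti_core(tips.begin(), child_ptr.begin(), split_ptr.begin(), R,
                     perm.data(), kappa, skip_degenerate, n_buf, m_buf, scores);
  }
  return out;
}

// r TIs of random ordered trees: kappa class-pure subtrees (random caterpillars,
// whose internal splits all score 0) merged by random pairwise joins; missing-
// labelled samples form one extra pure subtree. Only the join splits can score
// non-zero, so each draw is simulated on per-group class-count vectors.
// class_counts: non-missing count per class (length kappa); n_missing >= 0.
// [[Rcpp::export]]
NumericVector cpp_ordered_tis(IntegerVector class_counts, int n_missing,
                              int r, bool skip_degenerate) {
  int kappa = class_counts.size();
  int d = n_missing;
  std::vector<std::vector<int>> base_groups;
  std::vector<int> base_sizes; // leaf counts incl. missing members
  for (int l = 0; l < kappa; ++l) {
    if (class_counts[l] > 0) {
      std::vector<int> g(kappa, 0);
      g[l] = class_counts[l];
      base_groups.push_back(g);
      base_sizes.push_back(class_counts[l]);
      d += class_counts[l];
    }
  }
  if (n_missing > 0) {
    base_groups.push_back(std::vector<int>(kappa, 0));
    base_sizes.push_back(n_missing);
  }
  int g0 = (int)base_groups.size();
  NumericVector out(r);
  std::vector<double> scores;
  for (int it = 0; it < r; ++it) {
    std::vector<std::vector<int>> groups = base_groups;
    std::vector<int> sizes = base_sizes;
    scores.clear();
    // caterpillar-internal splits: zero score; degenerate only inside the
    // missing-labelled subtree (N = 0 there)
    if (!skip_degenerate) {
      for (int i = 0; i < (int)sizes.size(); ++i)
        for (int k = 1; k < sizes[i]; ++k) scores.push_back(0.0);
    } else {
      for (int i = 0; i < g0; ++i) {
        bool is_missing_grp = true;
        for (int l = 0; l < kappa; ++l)
          if (groups[i][l] > 0) { is_missing_grp = false; break; }
        if (!is_missing_grp)
          for (int k = 1; k < sizes[i]; ++k) scores.push_back(0.0);
      }
    }
    while (groups.size() > 1) {
      int g = (int)groups.size();
      int a = (int)(R::unif_rand() * g); if (a >= g) a = g - 1;
      int b = (int)(R::unif_rand() * (g - 1)); if (b >= g - 1) b = g - 2;
      if (b >= a) ++b;
      if (a > b) std::swap(a, b);
      int Na = 0, Nb = 0;
      double child_term = 0.0, inner;
      inner = 0.0;
      for (int l = 0; l < kappa; ++l) { Na += groups[a][l]; inner -= lfact(groups[a][l]); }
      child_term += lfact(Na) + inner;
      inner = 0.0;
      for (int l = 0; l < kappa; ++l) { Nb += groups[b][l]; inner -= lfact(groups[b][l]); }
      child_term += lfact(Nb) + inner;
      int N = Na + Nb;
      double s = lfact(N);
      for (int l = 0; l < kappa; ++l) s -= lfact(groups[a][l] + groups[b][l]);
      s -= child_term;
      if (s < 0.0) s = 0.0;
      bool degen = (N <= 1) || (Na == 0) || (Nb == 0);
      if (!(skip_degenerate && degen)) scores.push_back(s);
      for (int l = 0; l < kappa; ++l) groups[a][l] += groups[b][l];
      sizes[a] += sizes[b];
      groups.erase(groups.begin() + b);
      sizes.erase(sizes.begin() + b);
    }
    out[it] = ti_from_scores(scores);
  }
  return out;
}
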