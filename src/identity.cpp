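#include <Rcpp.h>
using namespace Rcpp;

// Semi-global ("overlap") alignment with linear gap costs:
//   match +1, mismatch -1, gap -1; terminal gaps free.
// Identity = matches / aligned columns, where columns contributed by the
// unaligned terminal overhangs are excluded.
//
// Determinism contract (must be mirrored by any independent oracle):
// among all alignments the one with the lexicographically maximal tuple
// (score, matches, -columns) is reported. All three components are
// additive along the path, so a cell-wise lexicographic dynamic program
// is exact; and each component is invariant under swapping the two
// sequences, which makes the reported identity symmetric even when many
// alignments tie on score.

struct Tup {
  int score;
  int matches;
  int cols;
};

static inline bool tup_less(const Tup& a, const Tup& b) {
  if (a.score != b.score) return a.score < b.score;
  if (a.matches != b.matches) return a.matches < b.matches;
  return a.cols > b.cols;  // fewer columns preferred
}

static Tup sg_align(const std::string& a, const std::string& b) {
  const int m = (int)a.size(), n = (int)b.size();
  const int W = n + 1;
  std::vector<Tup> D((size_t)(m + 1) * W);
  for (int j = 0; j <= n; ++j) D[j] = {0, 0, 0};
  for (int i = 1; i <= m; ++i) {
    D[(size_t)i * W] = {0, 0, 0};
    const char ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      const bool eq = (ai == b[j - 1]);
      const Tup& dg = D[(size_t)(i - 1) * W + (j - 1)];
      Tup best = {dg.score + (eq ? 1 : -1), dg.matches + (eq ? 1 : 0),
                  dg.cols + 1};
      const Tup& u = D[(size_t)(i - 1) * W + j];
      Tup up = {u.score - 1, u.matches, u.cols + 1};
      if (tup_less(best, up)) best = up;
      const Tup& l = D[(size_t)i * W + (j - 1)];
      Tup left = {l.score - 1, l.matches, l.cols + 1};
      if (tup_less(best, left)) best = left;
      D[(size_t)i * W + j] = best;
    }
  }
  // end cell: lexicographically best tuple over last row and last column
  // (free trailing overhang); all candidates carry full tuples already
  Tup best = D[n];  // (0, n)
  for (int i = 1; i <= m; ++i)
    if (tup_less(best, D[(size_t)i * W + n])) best = D[(size_t)i * W + n];
  for (int j = 0; j < n; ++j)
    if (tup_less(best, D[(size_t)m * W + j])) best = D[(size_t)m * W + j];
  return best;
}

static double sg_identity(const std::string& a, const std::string& b) {
  if (a == b) return 100.0;  // fast path for dereplicated data
  Tup r = sg_align(a, b);
  return r.cols > 0 ? 100.0 * r.matches / r.cols : 0.0;
}

// [[Rcpp::export]]
List identity_cpp(std::string a, std::string b) {
  Tup r = sg_align(a, b);
  const double id = r.cols > 0 ? 100.0 * r.matches / r.cols : 0.0;
  return List::create(_["identity_pct"] = id,
                      _["matches"] = r.matches,
                      _["scored_columns"] = r.cols,
                      _["score"] = r.score);
}

// [[Rcpp::export]]
NumericVector identity_to_all_cpp(std::string q, CharacterVector db) {
  const int n = db.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) out[k] = sg_identity(q, as<std::string>(db[k]));
  return out;
}

// 1-based index of the first centroid with identity >= threshold, 0 if none.
// [[Rcpp::export]]
int first_match_cpp(std::string q, CharacterVector centroids, double threshold) {
  const int n = centroids.size();
  for (int k = 0; k < n; ++k) {
    if (sg_identity(q, as<std::string>(centroids[k])) >= threshold - 1e-9)
      return k + 1;
  }
  return 0;
}

// 1-based index of the first centroid attaining the maximal identity,
// provided that maximum is >= threshold; 0 otherwise.
// [[Rcpp::export]]
int best_match_cpp(std::string q, CharacterVector centroids, double threshold) {
  const int n = centroids.size();
  int best_k = 0; double best_id = -1.0;
  for (int k = 0; k < n; ++k) {
    const double id = sg_identity(q, as<std::string>(centroids[k]));
    if (id > best_id + 1e-9) { best_id = id; best_k = k + 1; }
  }
  if (best_k > 0 && best_id >= threshold - 1e-9) return best_k;
  return 0;
}

// Best identity of each query against a sequence collection.
// [[Rcpp::export]]
NumericVector best_identity_many_cpp(CharacterVector qs, CharacterVector db) {
  const int nq = qs.size(), nd = db.size();
  NumericVector out(nq);
  std::vector<std::string> dbs(nd);
  for (int k = 0; k < nd; ++k) dbs[k] = as<std::string>(db[k]);
  for (int i = 0; i < nq; ++i) {
    const std::string q = as<std::string>(qs[i]);
    double best = 0.0;
    for (int k = 0; k < nd; ++k) {
      const double id = sg_identity(q, dbs[k]);
      if (id > best) best = id;
      if (best == 100.0) break;
    }
    out[i] = best;
  }
  return out;
}
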