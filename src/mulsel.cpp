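// Core compute kernels: peptide binary-tree lists, bounded top-M pair
// scoring, and affine-gap profile/profile dynamic programming.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Residue state codes: 0..19 = ACDEFGHIKLMNPQRSTVWY, 20 = X, 21 = gap.
static const std::string AA_ORDER = "ACDEFGHIKLMNPQRSTVWY";
static const int CODE_X = 20;
static const int CODE_GAP = 21;
static const int NSTATE = 21;   // scoring states (gap excluded)
static const double PEP_BASE = 25.0;
static const double NEG_INF = -1e30;

static inline int char_code(char c) {
  switch (c) {
    case 'A': return 0;  case 'C': return 1;  case 'D': return 2;
    case 'E': return 3;  case 'F': return 4;  case 'G': return 5;
    case 'H': return 6;  case 'I': return 7;  case 'K': return 8;
    case 'L': return 9;  case 'M': return 10; case 'N': return 11;
    case 'P': return 12; case 'Q': return 13; case 'R': return 14;
    case 'S': return 15; case 'T': return 16; case 'V': return 17;
    case 'W': return 18; case 'Y': return 19; case 'X': return CODE_X;
    case '-': return CODE_GAP;
    default:  return -1;
  }
}

// [[Rcpp::export]]
IntegerVector cpp_encode(std::string seq) {
  IntegerVector out(seq.size());
  for (size_t i = 0; i < seq.size(); ++i) {
    int c = char_code(seq[i]);
    if (c < 0) stop("invalid residue character '%s'", std::string(1, seq[i]));
    out[i] = c;
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_decode(IntegerVector codes) {
  std::string out(codes.size(), '?');
  for (int i = 0; i < codes.size(); ++i) {
    int c = codes[i];
    if (c >= 0 && c < 20) out[i] = AA_ORDER[c];
    else if (c == CODE_X) out[i] = 'X';
    else if (c == CODE_GAP) out[i] = '-';
    else stop("invalid residue code %d", c);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Peptide list: every overlapping k-peptide hashed base-25 over the residue
// codes and inserted (once) into an unbalanced binary search tree; an
// in-order (depth-first left-right) traversal emits the sorted distinct list.
struct PepNode { double key; int left, right; };

// [[Rcpp::export]]
NumericVector cpp_peptide_list(std::string seq, int k) {
  int L = (int)seq.size();
  if (k < 1) stop("k must be >= 1");
  if (L < k) return NumericVector(0);
  std::vector<int> code(L);
  for (int i = 0; i < L; ++i) {
    code[i] = char_code(seq[i]);
    if (code[i] < 0) stop("invalid residue character '%s'", std::string(1, seq[i]));
  }
  std::vector<PepNode> pool;
  pool.reserve(L - k + 1);
  int root = -1;
  double hash = 0.0, top = std::pow(PEP_BASE, k - 1);
  for (int i = 0; i + k <= L; ++i) {
    if (i == 0) {
      hash = 0.0;
      for (int j = 0; j < k; ++j) hash = hash * PEP_BASE + code[j];
    } else {
      hash = (hash - code[i - 1] * top) * PEP_BASE + code[i + k - 1];
    }
    if (root < 0) {
      pool.push_back({hash, -1, -1});
      root = 0;
      continue;
    }
    int at = root;
    for (;;) {                       // insert unique
      if (hash == pool[at].key) break;
      int &next = (hash < pool[at].key) ? pool[at].left : pool[at].right;
      if (next < 0) {
        pool.push_back({hash, -1, -1});
        next = (int)pool.size() - 1;
        break;
      }
      at = next;
    }
  }
  // iterative in-order traversal
  NumericVector out(pool.size());
  int n_out = 0;
  std::vector<int> stack;
  int at = root;
  while (at >= 0 || !stack.empty()) {
    while (at >= 0) { stack.push_back(at); at = pool[at].left; }
    at = stack.back(); stack.pop_back();
    out[n_out++] = pool[at].key;
    at = pool[at].right;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_peptides(NumericVector keys, int k) {
  CharacterVector out(keys.size());
  for (int i = 0; i < keys.size(); ++i) {
    double v = keys[i];
    std::string s(k, '?');
    for (int j = k - 1; j >= 0; --j) {
      double q = std::floor(v / PEP_BASE);
      int c = (int)(v - q * PEP_BASE);
      v = q;
      if (c < 20) s[j] = AA_ORDER[c];
      else if (c == CODE_X) s[j] = 'X';
      else s[j] = '-';
    }
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
int cpp_common_count(NumericVector a, NumericVector b) {
  int i = 0, j = 0, n = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else { ++n; ++i; ++j; }
  }
  return n;
}

// ---------------------------------------------------------------------------
// All-pairs peptide scoring with bounded per-sequence top-M retention.
// Pairs are evaluated within contiguous blocks of the current order only;
// adjacent pairs (|i-j| == 1) get a small bonus before thresholding.
// [[Rcpp::export]]
DataFrame cpp_score_pairs(List lists, int M, double min_score,
                          double adj_bonus, int n_blocks) {
  int N = lists.size();
  if (M < 1) stop("M must be >= 1");
  std::vector<NumericVector> pl(N);
  for (int i = 0; i < N; ++i) pl[i] = as<NumericVector>(lists[i]);
  std::vector<double> best_s((size_t)N * M, -1.0);
  std::vector<int> best_p((size_t)N * M, -1);

  int bs = (n_blocks <= 1) ? N : (N + n_blocks - 1) / n_blocks;
  if (bs < 1) bs = 1;

  auto offer = [&](int i, int j, double s) {
    // keep the M highest partners for sequence i; skip when M higher exist
    double *sl = &best_s[(size_t)i * M];
    int *pp = &best_p[(size_t)i * M];
    int min_at = 0;
    for (int m = 1; m < M; ++m) if (sl[m] < sl[min_at]) min_at = m;
    if (s > sl[min_at]) { sl[min_at] = s; pp[min_at] = j; }
  };

  for (int i = 0; i < N; ++i) {
    int block_end = std::min(N, ((i / bs) + 1) * bs);
    for (int j = i + 1; j < block_end; ++j) {
      if (pl[i].size() == 0 || pl[j].size() == 0) continue;
      int c = 0;
      {
        const NumericVector &a = pl[i], &b = pl[j];
        int u = 0, v = 0;
        while (u < a.size() && v < b.size()) {
          if (a[u] < b[v]) ++u;
          else if (a[u] > b[v]) ++v;
          else { ++c; ++u; ++v; }
        }
      }
      double s = c + ((j == i + 1) ? adj_bonus : 0.0);
      if (s < min_score || c == 0) continue;
      offer(i, j, s);
      offer(j, i, s);
    }
  }
  // union of retained pairs, deduplicated
  std::vector<std::pair<std::pair<int,int>, double> > pairs;
  for (int i = 0; i < N; ++i)
    for (int m = 0; m < M; ++m) {
      int j = best_p[(size_t)i * M + m];
      if (j < 0) continue;
      int a = std::min(i, j), b = std::max(i, j);
      pairs.push_back({{a, b}, best_s[(size_t)i * M + m]});
    }
  std::sort(pairs.begin(), pairs.end());
  pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());
  // global rank order: score descending, ties by (i, j) ascending
  std::stable_sort(pairs.begin(), pairs.end(),
    [](const std::pair<std::pair<int,int>,double> &x,
       const std::pair<std::pair<int,int>,double> &y) {
      if (x.second != y.second) return x.second > y.second;
      return x.first < y.first;
    });
  int np = (int)pairs.size();
  IntegerVector pi(np), pj(np);
  NumericVector ps(np);
  for (int q = 0; q < np; ++q) {
    pi[q] = pairs[q].first.first + 1;
    pj[q] = pairs[q].first.second + 1;
    ps[q] = pairs[q].second;
  }
  return DataFrame::create(_["i"] = pi, _["j"] = pj, _["score"] = ps);
}

// ---------------------------------------------------------------------------
// Profile/profile global alignment (Gotoh affine gaps, optional band, free
// terminal gaps). Column-pair score = 100 * average over member cross-pairs
// of mat[residue, residue], gap states scoring 0. Reported similarity =
// sum of column-pair scores along the optimal path / shorter profile length,
// so identical sequences under the identity matrix score 100. Gap penalties
// are given in points on that 0-100 scale.
struct Prof {
  int nmem, ncol;
  std::vector<std::vector<std::pair<int, double> > > cols; // (state, count)
};

static Prof prep_profile(const IntegerMatrix &m) {
  Prof p;
  p.nmem = m.nrow();
  p.ncol = m.ncol();
  p.cols.resize(p.ncol);
  for (int j = 0; j < p.ncol; ++j) {
    int cnt[NSTATE] = {0};
    for (int i = 0; i < p.nmem; ++i) {
      int c = m(i, j);
      if (c < 0 || c > CODE_GAP) stop("invalid residue code in profile");
      if (c != CODE_GAP) cnt[c]++;
    }
    for (int s = 0; s < NSTATE; ++s)
      if (cnt[s]) p.cols[j].push_back({s, (double)cnt[s]});
  }
  return p;
}

struct AlnResult {
  double score;                 // 0-100 similarity
  double objective;             // DP objective (penalised)
  std::vector<int> a_path, b_path; // merged columns: source col (1-based) or 0
};

static void align_core(const Prof &A, const Prof &B, const NumericMatrix &mat,
                       double go, double ge, int band, bool want_path,
                       AlnResult &res) {
  int La = A.ncol, Lb = B.ncol;
  if (La == 0 || Lb == 0) stop("empty profile");
  int Lmin = std::min(La, Lb);
  double denom = (double)A.nmem * (double)B.nmem;
  double go_raw = go * Lmin, ge_raw = ge * Lmin;

  // per-B-column state scores against the matrix
  std::vector<double> SB((size_t)NSTATE * Lb, 0.0);
  for (int j = 0; j < Lb; ++j)
    for (auto &sb : B.cols[j])
      for (int a = 0; a < NSTATE; ++a)
        SB[(size_t)a * Lb + j] += mat(a, sb.first) * sb.second;

  int dlo = std::min(0, Lb - La), dhi = std::max(0, Lb - La);
  if (band >= 0) { dlo -= band; dhi += band; }
  else { dlo = -La; dhi = Lb; }

  size_t W = (size_t)Lb + 1;
  std::vector<double> Mv((La + 1) * W, NEG_INF), Xv((La + 1) * W, NEG_INF),
      Yv((La + 1) * W, NEG_INF), Mm((La + 1) * W, 0.0), Xm((La + 1) * W, 0.0),
      Ym((La + 1) * W, 0.0);
  std::vector<unsigned char> tb;
  if (want_path) tb.assign(3 * (La + 1) * W, 0);
  // tb codes per state: M: 0=from M,1=from X,2=from Y ; X/Y likewise
  Mv[0] = 0.0;
  for (int i = 1; i <= La; ++i) { Xv[i * W] = 0.0; Xm[i * W] = 0.0;
    if (want_path) tb[1 * (La + 1) * W + i * W] = (i == 1) ? 0 : 1; }
  for (int j = 1; j <= Lb; ++j) { Yv[j] = 0.0; Ym[j] = 0.0;
    if (want_path) tb[2 * (La + 1) * W + j] = (j == 1) ? 0 : 2; }

  size_t planeX = (size_t)(La + 1) * W, planeY = 2 * planeX;
  for (int i = 1; i <= La; ++i) {
    int jlo = std::max(1, i + dlo), jhi = std::min(Lb, i + dhi);
    for (int j = jlo; j <= jhi; ++j) {
      size_t at = (size_t)i * W + j, di = at - W - 1, up = at - W, lf = at - 1;
      // column score
      double s = 0.0;
      for (auto &sa : A.cols[i - 1])
        s += sa.second * SB[(size_t)sa.first * Lb + (j - 1)];
      s = 100.0 * s / denom;
      // M state
      double bv = Mv[di], bm = Mm[di]; unsigned char bt = 0;
      if (Xv[di] > bv) { bv = Xv[di]; bm = Xm[di]; bt = 1; }
      if (Yv[di] > bv) { bv = Yv[di]; bm = Ym[di]; bt = 2; }
      if (bv > NEG_INF / 2) { Mv[at] = bv + s; Mm[at] = bm + s; }
      if (want_path) tb[at] = bt;
      // X state: consume A column i, gap in B (free at B boundaries)
      double open = (j == 0 || j == Lb) ? 0.0 : go_raw + ge_raw;
      double ext  = (j == 0 || j == Lb) ? 0.0 : ge_raw;
      bv = Mv[up] - open; bm = Mm[up]; bt = 0;
      if (Xv[up] - ext > bv) { bv = Xv[up] - ext; bm = Xm[up]; bt = 1; }
      if (bv > NEG_INF / 2) { Xv[at] = bv; Xm[at] = bm; }
      if (want_path) tb[planeX + at] = bt;
      // Y state: consume B column j, gap in A (free at A boundaries)
      open = (i == 0 || i == La) ? 0.0 : go_raw + ge_raw;
      ext  = (i == 0 || i == La) ? 0.0 : ge_raw;
      bv = Mv[lf] - open; bm = Mm[lf]; bt = 0;
      if (Yv[lf] - ext > bv) { bv = Yv[lf] - ext; bm = Ym[lf]; bt = 2; }
      if (bv > NEG_INF / 2) { Yv[at] = bv; Ym[at] = bm; }
      if (want_path) tb[planeY + at] = bt;
    }
  }
  size_t end = (size_t)La * W + Lb;
  double bv = Mv[end], bm = Mm[end]; int bstate = 0;
  if (Xv[end] > bv) { bv = Xv[end]; bm = Xm[end]; bstate = 1; }
  if (Yv[end] > bv) { bv = Yv[end]; bm = Ym[end]; bstate = 2; }
  res.objective = bv;
  res.score = (bv <= NEG_INF / 2) ? 0.0 : bm / Lmin;
  res.a_path.clear(); res.b_path.clear();
  if (!want_path) return;
  if (bv <= NEG_INF / 2) stop("alignment band too narrow to connect profiles");
  int i = La, j = Lb, st = bstate;
  std::vector<int> ap, bp;
  while (i > 0 || j > 0) {
    size_t at = (size_t)i * W + j;
    if (st == 0) {
      ap.push_back(i); bp.push_back(j);
      st = tb[at]; --i; --j;
    } else if (st == 1) {
      ap.push_back(i); bp.push_back(0);
      st = tb[planeX + at]; --i;
    } else {
      ap.push_back(0); bp.push_back(j);
      st = tb[planeY + at]; --j;
    }
  }
  std::reverse(ap.begin(), ap.end());
  std::reverse(bp.begin(), bp.end());
  res.a_path = ap; res.b_path = bp;
}

// [[Rcpp::export]]
List cpp_align_profiles(IntegerMatrix A, IntegerMatrix B, NumericMatrix mat,
                        double gap_open, double gap_extend, int band,
                        bool want_path) {
  if (mat.nrow() != NSTATE || mat.ncol() != NSTATE)
    stop("substitution matrix must be 21 x 21");
  Prof pa = prep_profile(A), pb = prep_profile(B);
  AlnResult res;
  align_core(pa, pb, mat, gap_open, gap_extend, band, want_path, res);
  return List::create(_["score"] = res.score, _["objective"] = res.objective,
                      _["a_path"] = wrap(res.a_path),
                      _["b_path"] = wrap(res.b_path));
}

// Score all profile pairs within `span` of each other in the current order,
// returning those at or above `cutoff`, rank-sorted (score desc, index asc).
// [[Rcpp::export]]
DataFrame cpp_span_pair_scores(List profiles, int span, NumericMatrix mat,
                               double gap_open, double gap_extend, int band,
                               double cutoff) {
  if (mat.nrow() != NSTATE || mat.ncol() != NSTATE)
    stop("substitution matrix must be 21 x 21");
  int N = profiles.size();
  std::vector<Prof> pf(N);
  for (int i = 0; i < N; ++i) pf[i] = prep_profile(as<IntegerMatrix>(profiles[i]));
  std::vector<int> vi, vj;
  std::vector<double> vs;
  AlnResult res;
  for (int i = 0; i < N; ++i) {
    int jmax = (span < 0) ? N - 1 : std::min(N - 1, i + span);
    for (int j = i + 1; j <= jmax; ++j) {
      align_core(pf[i], pf[j], mat, gap_open, gap_extend, band, false, res);
      if (res.score >= cutoff) {
        vi.push_back(i + 1); vj.push_back(j + 1); vs.push_back(res.score);
      }
    }
    if (N > 500 && i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  std::vector<int> ord(vi.size());
  for (size_t q = 0; q < ord.size(); ++q) ord[q] = (int)q;
  std::stable_sort(ord.begin(), ord.end(), [&](int x, int y) {
    if (vs[x] != vs[y]) return vs[x] > vs[y];
    if (vi[x] != vi[y]) return vi[x] < vi[y];
    return vj[x] < vj[y];
  });
  IntegerVector pi(ord.size()), pj(ord.size());
  NumericVector ps(ord.size());
  for (size_t q = 0; q < ord.size(); ++q) {
    pi[q] = vi[ord[q]]; pj[q] = vj[ord[q]]; ps[q] = vs[ord[q]];
  }
  return DataFrame::create(_["i"] = pi, _["j"] = pj, _["score"] = ps);
}
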