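// Numerical kernels: Kabsch superposition, the four alignment scores,
// block decomposition of non-sequential alignments, move enumeration and
// the best-first refinement loop, and an exhaustive search for tiny
// instances used as a validation oracle.
//
// Conventions: pairs arrive from R as a two-column integer matrix of
// 1-based (i, j) residue indices; everything here is 0-based internally.
// Coordinates are L x 3 matrices in Angstrom.

#include <RcppArmadillo.h>
#include <map>
#include <set>
#include <vector>
#include <algorithm>
#include <cmath>

// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef std::array<int, 2> Pair;   // (i, j), 0-based
typedef std::vector<Pair> PairVec;

// ---------------------------------------------------------------------------
// score specification

struct Spec {
  int fun;          // 0 DALI, 1 SP, 2 SO, 3 SO_L, 4 TM
  double d0_dali;
  double d0_sp;
  double alpha;
  double d0_so;
  double k;
  int tm_norm;      // 0 A, 1 B, 2 average
  int variant;      // 0 deviation (as-printed envelope), 1 mean_distance
};

static int fun_code(const std::string& s) {
  if (s == "DALI") return 0;
  if (s == "SP") return 1;
  if (s == "SO") return 2;
  if (s == "SO_L") return 3;
  if (s == "TM") return 4;
  stop("unknown scoring function '%s'", s.c_str());
  return -1;
}

static Spec as_spec(const List& sp) {
  Spec s;
  s.fun = fun_code(as<std::string>(sp["fun"]));
  s.d0_dali = as<double>(sp["d0_dali"]);
  s.d0_sp = as<double>(sp["d0_sp"]);
  s.alpha = as<double>(sp["alpha"]);
  s.d0_so = as<double>(sp["d0_so"]);
  s.k = as<double>(sp["k"]);
  std::string tn = as<std::string>(sp["tm_normalization"]);
  s.tm_norm = (tn == "A") ? 0 : (tn == "B") ? 1 : 2;
  std::string dv = as<std::string>(sp["dali_variant"]);
  s.variant = (dv == "mean_distance") ? 1 : 0;
  return s;
}

static PairVec as_pairs(const IntegerMatrix& m) {
  PairVec p(m.nrow());
  for (int t = 0; t < m.nrow(); ++t) {
    p[t][0] = m(t, 0) - 1;
    p[t][1] = m(t, 1) - 1;
  }
  return p;
}

static IntegerMatrix pairs_out(const PairVec& p) {
  IntegerMatrix m(p.size(), 2);
  for (size_t t = 0; t < p.size(); ++t) {
    m(t, 0) = p[t][0] + 1;
    m(t, 1) = p[t][1] + 1;
  }
  colnames(m) = CharacterVector::create("i", "j");
  return m;
}

// ---------------------------------------------------------------------------
// block decomposition
//
// Runs are grown greedily in increasing i; the orientation of a run is set
// by its first extension step, trying forward before reverse.  Singletons
// are forward by convention.

struct BlockInfo {
  std::vector<int> block_id;   // per pair, in sorted-by-i order
  std::vector<int> orient;     // per block: +1 forward, -1 reverse
  std::vector<int> size;       // per block
  PairVec sorted;              // pairs sorted by i
};

static BlockInfo decompose(const PairVec& pairs) {
  BlockInfo bi;
  bi.sorted = pairs;
  std::sort(bi.sorted.begin(), bi.sorted.end());
  int n = bi.sorted.size();
  bi.block_id.assign(n, -1);
  std::map<int, int> by_i;
  for (int t = 0; t < n; ++t) by_i[bi.sorted[t][0]] = t;
  int b = -1;
  for (int t = 0; t < n; ++t) {
    if (bi.block_id[t] >= 0) continue;
    ++b;
    bi.block_id[t] = b;
    int sz = 1;
    int dir = 0;
    int ci = bi.sorted[t][0], cj = bi.sorted[t][1];
    for (;;) {
      std::map<int, int>::iterator it = by_i.find(ci + 1);
      if (it == by_i.end()) break;
      int u = it->second;
      if (bi.block_id[u] >= 0) break;
      int nj = bi.sorted[u][1];
      if (dir == 0) {
        if (nj == cj + 1) dir = +1;
        else if (nj == cj - 1) dir = -1;
        else break;
      } else if (nj != cj + dir) {
        break;
      }
      bi.block_id[u] = b;
      ++sz;
      ci = bi.sorted[u][0];
      cj = nj;
    }
    bi.orient.push_back(dir == -1 ? -1 : +1);
    bi.size.push_back(sz);
  }
  return bi;
}

static bool valid_alignment(const PairVec& pairs, int min_block,
                            bool allow_reverse) {
  if (pairs.empty()) return true;
  BlockInfo bi = decompose(pairs);
  for (size_t b = 0; b < bi.size.size(); ++b) {
    if (bi.size[b] < min_block) return false;
    if (!allow_reverse && bi.orient[b] == -1 && bi.size[b] >= 2) return false;
  }
  return true;
}

// [[Rcpp::export]]
List cpp_blocks(IntegerMatrix pairs) {
  BlockInfo bi = decompose(as_pairs(pairs));
  int n = bi.sorted.size();
  IntegerVector bid(n);
  for (int t = 0; t < n; ++t) bid[t] = bi.block_id[t] + 1;
  IntegerVector orient(bi.orient.begin(), bi.orient.end());
  IntegerVector size(bi.size.begin(), bi.size.end());
  return List::create(_["pairs"] = pairs_out(bi.sorted), _["block"] = bid,
                      _["orientation"] = orient, _["size"] = size);
}

// [[Rcpp::export]]
bool cpp_valid(IntegerMatrix pairs, int min_block, bool allow_reverse) {
  return valid_alignment(as_pairs(pairs), min_block, allow_reverse);
}

// ---------------------------------------------------------------------------
// Kabsch superposition (proper rotation only)

struct Fit {
  arma::mat33 R;
  arma::vec3 t;
  double rmsd;
};

// Least-RMSD proper rotation + translation mapping Q onto P (both n x 3).
static Fit kabsch_core(const arma::mat& P, const arma::mat& Q) {
  Fit f;
  int n = P.n_rows;
  arma::rowvec cp = arma::mean(P, 0), cq = arma::mean(Q, 0);
  arma::mat Pc = P.each_row() - cp;
  arma::mat Qc = Q.each_row() - cq;
  arma::mat H = Qc.t() * Pc;           // 3 x 3 covariance
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) stop("SVD failed in Kabsch superposition");
  double d = arma::det(V * U.t());
  arma::vec3 corr = {1.0, 1.0, (d < 0) ? -1.0 : 1.0};
  f.R = V * arma::diagmat(corr) * U.t();
  f.t = arma::vec(cp.t()) - f.R * arma::vec(cq.t());
  arma::mat Qfit = Qc * f.R.t();
  double ss = arma::accu(arma::square(Pc - Qfit));
  f.rmsd = std::sqrt(std::max(0.0, ss / n));
  return f;
}

// [[Rcpp::export]]
List cpp_kabsch(NumericMatrix P, NumericMatrix Q) {
  arma::mat Pm(P.begin(), P.nrow(), 3, false);
  arma::mat Qm(Q.begin(), Q.nrow(), 3, false);
  Fit f = kabsch_core(Pm, Qm);
  return List::create(_["rotation"] = wrap(arma::mat(f.R)),
                      _["translation"] = wrap(arma::vec(f.t)),
                      _["rmsd"] = f.rmsd);
}

// per-pair deviations after least-RMSD superposition of the aligned subsets
static void aligned_devs(const PairVec& pairs, const arma::mat& A,
                         const arma::mat& B, std::vector<double>& d) {
  int n = pairs.size();
  arma::mat P(n, 3), Q(n, 3);
  for (int t = 0; t < n; ++t) {
    P.row(t) = A.row(pairs[t][0]);
    Q.row(t) = B.row(pairs[t][1]);
  }
  Fit f = kabsch_core(P, Q);
  d.resize(n);
  for (int t = 0; t < n; ++t) {
    arma::vec3 q = f.R * Q.row(t).t() + f.t;
    d[t] = arma::norm(P.row(t).t() - q);
  }
}

// [[Rcpp::export]]
NumericVector cpp_aligned_devs(IntegerMatrix pairs, NumericMatrix A,
                               NumericMatrix B) {
  arma::mat Am(A.begin(), A.nrow(), 3, false);
  arma::mat Bm(B.begin(), B.nrow(), 3, false);
  std::vector<double> d;
  aligned_devs(as_pairs(pairs), Am, Bm, d);
  return NumericVector(d.begin(), d.end());
}

// ---------------------------------------------------------------------------
// score evaluation

static double eval_score(const PairVec& pairs, const arma::mat& A,
                         const arma::mat& B, const arma::mat& DA,
                         const arma::mat& DB, const Spec& s) {
  int n = pairs.size();
  if (n == 0) return 0.0;
  int LA = A.n_rows, LB = B.n_rows;

  if (s.fun == 0) {                       // DALI: distance matrices only
    double d0sq = s.d0_dali * s.d0_dali;
    double tot = 0.0;
    for (int a = 0; a < n; ++a) {
      for (int b = 0; b < n; ++b) {
        if (a == b) { tot += 0.2; continue; }
        double da = DA(pairs[a][0], pairs[b][0]);
        double db = DB(pairs[a][1], pairs[b][1]);
        double diff = std::fabs(da - db);
        double avg = 0.5 * (da + db);
        double w = (s.variant == 0) ? std::exp(-(diff * diff) / d0sq)
                                    : std::exp(-(avg * avg) / d0sq);
        double rel = (avg > 0.0) ? diff / avg : 0.0;
        tot += (0.2 - rel) * w;
      }
    }
    return tot;
  }

  std::vector<double> d;
  aligned_devs(pairs, A, B, d);

  if (s.fun == 2) {                       // SO
    int cnt = 0;
    for (int t = 0; t < n; ++t) if (d[t] <= s.d0_so) ++cnt;
    return (double)cnt / (double)std::min(LA, LB);
  }
  if (s.fun == 3) {                       // SO_L
    double tot = 0.0;
    for (int t = 0; t < n; ++t)
      tot += 1.0 - 1.0 / (1.0 + std::exp(-s.k * (d[t] - s.d0_so)));
    return tot / (double)std::min(LA, LB);
  }
  if (s.fun == 4) {                       // TM
    double tma = 0.0, tmb = 0.0;
    if (s.tm_norm == 0 || s.tm_norm == 2) {
      double d0 = std::max(0.5, 1.24 * std::cbrt((double)LA - 15.0) - 1.8);
      double sum = 0.0;
      for (int t = 0; t < n; ++t) sum += 1.0 / (1.0 + (d[t] / d0) * (d[t] / d0));
      tma = sum / LA;
    }
    if (s.tm_norm == 1 || s.tm_norm == 2) {
      double d0 = std::max(0.5, 1.24 * std::cbrt((double)LB - 15.0) - 1.8);
      double sum = 0.0;
      for (int t = 0; t < n; ++t) sum += 1.0 / (1.0 + (d[t] / d0) * (d[t] / d0));
      tmb = sum / LB;
    }
    if (s.tm_norm == 0) return tma;
    if (s.tm_norm == 1) return tmb;
    return 0.5 * (tma + tmb);
  }

  // SP.  Sum over pairs with d < 2*d0 (strict, as printed); core pairs use
  // d <= 2*d0.  Neighbours are counted per chain in its own coordinates and
  // averaged over the two chains.
  double d0 = s.d0_sp;
  double sum = 0.0;
  std::vector<int> coreA, coreB;
  for (int t = 0; t < n; ++t) {
    if (d[t] < 2.0 * d0)
      sum += 1.0 / (1.0 + (d[t] / d0) * (d[t] / d0)) - 0.2;
    if (d[t] <= 2.0 * d0) {
      coreA.push_back(pairs[t][0]);
      coreB.push_back(pairs[t][1]);
    }
  }
  int ncore = coreA.size();
  double thr = 3.0 * d0;
  double thr2 = thr * thr;
  std::vector<bool> isCoreA(LA, false), isCoreB(LB, false);
  for (size_t t = 0; t < coreA.size(); ++t) isCoreA[coreA[t]] = true;
  for (size_t t = 0; t < coreB.size(); ++t) isCoreB[coreB[t]] = true;
  int nbrA = 0, nbrB = 0;
  for (int r = 0; r < LA; ++r) {
    if (isCoreA[r]) continue;
    for (size_t t = 0; t < coreA.size(); ++t) {
      double dd = arma::accu(arma::square(A.row(r) - A.row(coreA[t])));
      if (dd <= thr2) { ++nbrA; break; }
    }
  }
  for (int r = 0; r < LB; ++r) {
    if (isCoreB[r]) continue;
    for (size_t t = 0; t < coreB.size(); ++t) {
      double dd = arma::accu(arma::square(B.row(r) - B.row(coreB[t])));
      if (dd <= thr2) { ++nbrB; break; }
    }
  }
  double L = ncore + 0.5 * (nbrA + nbrB);
  if (L <= 0.0) return 0.0;
  return sum / (3.0 * std::pow(L, 1.0 - s.alpha));
}

// [[Rcpp::export]]
double cpp_score(IntegerMatrix pairs, NumericMatrix A, NumericMatrix B,
                 NumericMatrix DA, NumericMatrix DB, List spec) {
  arma::mat Am(A.begin(), A.nrow(), A.ncol(), false);
  arma::mat Bm(B.begin(), B.nrow(), B.ncol(), false);
  arma::mat DAm(DA.begin(), DA.nrow(), DA.ncol(), false);
  arma::mat DBm(DB.begin(), DB.nrow(), DB.ncol(), false);
  return eval_score(as_pairs(pairs), Am, Bm, DAm, DBm, as_spec(spec));
}

// ---------------------------------------------------------------------------
// move enumeration and best-first refinement

struct Move {
  int kind;       // 0 delete_pair, 1 add_pair, 2 delete_block, 3 add_block
  PairVec prs;
  double delta;
  bool dead;
};

// tie-break among equal deltas: kind order delete_pair, add_pair,
// delete_block, add_block; then first pair's i, then j
static bool move_before(const Move& a, const Move& b) {
  if (a.delta != b.delta) return a.delta > b.delta;
  if (a.kind != b.kind) return a.kind < b.kind;
  if (a.prs[0][0] != b.prs[0][0]) return a.prs[0][0] < b.prs[0][0];
  return a.prs[0][1] < b.prs[0][1];
}

struct RefState {
  arma::mat A, B, DA, DB;
  Spec spec;
  int min_block;
  bool allow_reverse;
  double eps;
  int LA, LB;
  std::vector<int> mapA;   // i -> j or -1
  std::vector<int> mapB;   // j -> i or -1
  double cur;
  long n_eval;

  PairVec pairs() const {
    PairVec p;
    for (int i = 0; i < LA; ++i)
      if (mapA[i] >= 0) p.push_back({i, mapA[i]});
    return p;
  }
  double score_of(const PairVec& p) {
    ++n_eval;
    return eval_score(p, A, B, DA, DB, spec);
  }
};

// candidate pair list after applying a move; empty optional handled by caller
static PairVec apply_move(const RefState& st, const Move& mv) {
  PairVec p = st.pairs();
  if (mv.kind == 1 || mv.kind == 3) {
    for (size_t t = 0; t < mv.prs.size(); ++t) p.push_back(mv.prs[t]);
  } else {
    std::set<Pair> del(mv.prs.begin(), mv.prs.end());
    PairVec q;
    for (size_t t = 0; t < p.size(); ++t)
      if (!del.count(p[t])) q.push_back(p[t]);
    p = q;
  }
  std::sort(p.begin(), p.end());
  return p;
}

static bool applicable(const RefState& st, const Move& mv) {
  for (size_t t = 0; t < mv.prs.size(); ++t) {
    int i = mv.prs[t][0], j = mv.prs[t][1];
    if (mv.kind == 1 || mv.kind == 3) {
      if (st.mapA[i] >= 0 || st.mapB[j] >= 0) return false;
    } else {
      if (st.mapA[i] != j) return false;
    }
  }
  return true;
}

struct Touched {
  std::set<int> a, b;
  bool hits(const PairVec& prs) const {
    for (size_t t = 0; t < prs.size(); ++t)
      if (a.count(prs[t][0]) || b.count(prs[t][1])) return true;
    return false;
  }
};

// Enumerate admissible moves (optionally restricted to moves touching a
// residue set); keep a move when improving_only is false or delta > eps.
static std::vector<Move> collect_moves(RefState& st, const Touched* touched,
                                       bool improving_only) {
  std::vector<Move> out;
  PairVec cur_pairs = st.pairs();
  BlockInfo bi = decompose(cur_pairs);
  int nblk = bi.size.size();

  std::set<Pair> candidate_adds;
  std::set<PairVec> seen_blocks;

  // block pair lists
  std::vector<PairVec> blocks(nblk);
  for (size_t t = 0; t < bi.sorted.size(); ++t)
    blocks[bi.block_id[t]].push_back(bi.sorted[t]);

  // delete_pair
  for (size_t t = 0; t < cur_pairs.size(); ++t) {
    Move mv;
    mv.kind = 0;
    mv.prs.push_back(cur_pairs[t]);
    if (touched && !touched->hits(mv.prs)) continue;
    PairVec cand = apply_move(st, mv);
    if (!valid_alignment(cand, st.min_block, st.allow_reverse)) continue;
    mv.delta = st.score_of(cand) - st.cur;
    mv.dead = false;
    if (!improving_only || mv.delta > st.eps) out.push_back(mv);
  }

  // add_pair candidate positions
  if (st.min_block <= 1) {
    if (touched) {
      for (std::set<int>::const_iterator it = touched->a.begin();
           it != touched->a.end(); ++it) {
        int i = *it;
        if (i < 0 || i >= st.LA || st.mapA[i] >= 0) continue;
        for (int j = 0; j < st.LB; ++j)
          if (st.mapB[j] < 0) candidate_adds.insert({i, j});
      }
      for (std::set<int>::const_iterator it = touched->b.begin();
           it != touched->b.end(); ++it) {
        int j = *it;
        if (j < 0 || j >= st.LB || st.mapB[j] >= 0) continue;
        for (int i = 0; i < st.LA; ++i)
          if (st.mapA[i] < 0) candidate_adds.insert({i, j});
      }
    } else {
      for (int i = 0; i < st.LA; ++i) {
        if (st.mapA[i] >= 0) continue;
        for (int j = 0; j < st.LB; ++j)
          if (st.mapB[j] < 0) candidate_adds.insert({i, j});
      }
    }
  } else {
    // only block-adjacent additions can keep all blocks >= min size
    for (int b = 0; b < nblk; ++b) {
      const PairVec& blk = blocks[b];
      int dir = bi.orient[b];
      Pair first = blk.front(), last = blk.back();
      Pair ext[2] = {{first[0] - 1, first[1] - dir},
                     {last[0] + 1, last[1] + dir}};
      for (int e = 0; e < 2; ++e) {
        int i = ext[e][0], j = ext[e][1];
        if (i < 0 || i >= st.LA || j < 0 || j >= st.LB) continue;
        if (st.mapA[i] >= 0 || st.mapB[j] >= 0) continue;
        candidate_adds.insert({i, j});
      }
      if (bi.size[b] == 1) {
        // a singleton (only possible when it entered via fallback rules)
        // may also grow in the reverse direction
        Pair rev[2] = {{first[0] - 1, first[1] + 1}, {last[0] + 1, last[1] - 1}};
        for (int e = 0; e < 2; ++e) {
          int i = rev[e][0], j = rev[e][1];
          if (i < 0 || i >= st.LA || j < 0 || j >= st.LB) continue;
          if (st.mapA[i] >= 0 || st.mapB[j] >= 0) continue;
          candidate_adds.insert({i, j});
        }
      }
    }
  }
  for (std::set<Pair>::iterator it = candidate_adds.begin();
       it != candidate_adds.end(); ++it) {
    Move mv;
    mv.kind = 1;
    mv.prs.push_back(*it);
    if (touched && !touched->hits(mv.prs)) continue;
    PairVec cand = apply_move(st, mv);
    if (!valid_alignment(cand, st.min_block, st.allow_reverse)) continue;
    mv.delta = st.score_of(cand) - st.cur;
    mv.dead = false;
    if (!improving_only || mv.delta > st.eps) out.push_back(mv);
  }

  // delete_block
  for (int b = 0; b < nblk; ++b) {
    Move mv;
    mv.kind = 2;
    mv.prs = blocks[b];
    if (touched && !touched->hits(mv.prs)) continue;
    PairVec cand = apply_move(st, mv);
    if (!valid_alignment(cand, st.min_block, st.allow_reverse)) continue;
    mv.delta = st.score_of(cand) - st.cur;
    mv.dead = false;
    if (!improving_only || mv.delta > st.eps) out.push_back(mv);
  }

  // add_block: a run of exactly min_block pairs, forward and (if allowed)
  // reverse, at any placement over free residues
  if (st.min_block > 1) {
    int m = st.min_block;
    std::vector<bool> rowFree(st.LA - m + 1, false),
        colFree(std::max(st.LB - m + 1, 0), false);
    for (int i = 0; i + m <= st.LA; ++i) {
      bool ok = true;
      for (int t = 0; t < m; ++t) if (st.mapA[i + t] >= 0) { ok = false; break; }
      rowFree[i] = ok;
    }
    for (int j = 0; j + m <= st.LB; ++j) {
      bool ok = true;
      for (int t = 0; t < m; ++t) if (st.mapB[j + t] >= 0) { ok = false; break; }
      colFree[j] = ok;
    }
    for (int i = 0; i + m <= st.LA; ++i) {
      if (!rowFree[i]) continue;
      for (int j = 0; j + m <= st.LB; ++j) {
        if (!colFree[j]) continue;
        for (int rev = 0; rev < (st.allow_reverse ? 2 : 1); ++rev) {
          Move mv;
          mv.kind = 3;
          for (int t = 0; t < m; ++t)
            mv.prs.push_back({i + t, rev ? j + m - 1 - t : j + t});
          if (touched && !touched->hits(mv.prs)) continue;
          PairVec cand = apply_move(st, mv);
          if (!valid_alignment(cand, st.min_block, st.allow_reverse)) continue;
          mv.delta = st.score_of(cand) - st.cur;
          mv.dead = false;
          if (!improving_only || mv.delta > st.eps) out.push_back(mv);
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_moves(IntegerMatrix pairs, NumericMatrix A, NumericMatrix B,
               NumericMatrix DA, NumericMatrix DB, List spec, int min_block,
               bool allow_reverse, double eps, bool improving_only,
               IntegerVector touched_a, IntegerVector touched_b,
               bool use_touched) {
  RefState st;
  st.A = arma::mat(A.begin(), A.nrow(), A.ncol());
  st.B = arma::mat(B.begin(), B.nrow(), B.ncol());
  st.DA = arma::mat(DA.begin(), DA.nrow(), DA.ncol());
  st.DB = arma::mat(DB.begin(), DB.nrow(), DB.ncol());
  st.spec = as_spec(spec);
  st.min_block = min_block;
  st.allow_reverse = allow_reverse;
  st.eps = eps;
  st.LA = A.nrow();
  st.LB = B.nrow();
  st.mapA.assign(st.LA, -1);
  st.mapB.assign(st.LB, -1);
  PairVec p = as_pairs(pairs);
  for (size_t t = 0; t < p.size(); ++t) {
    st.mapA[p[t][0]] = p[t][1];
    st.mapB[p[t][1]] = p[t][0];
  }
  st.n_eval = 0;
  st.cur = st.score_of(p);
  Touched tch;
  for (int t = 0; t < touched_a.size(); ++t) tch.a.insert(touched_a[t] - 1);
  for (int t = 0; t < touched_b.size(); ++t) tch.b.insert(touched_b[t] - 1);
  std::vector<Move> mv =
      collect_moves(st, use_touched ? &tch : NULL, improving_only);
  std::sort(mv.begin(), mv.end(), move_before);
  CharacterVector kinds(mv.size());
  List prs(mv.size());
  NumericVector deltas(mv.size());
  const char* knames[4] = {"delete_pair", "add_pair", "delete_block",
                           "add_block"};
  for (size_t t = 0; t < mv.size(); ++t) {
    kinds[t] = knames[mv[t].kind];
    prs[t] = pairs_out(mv[t].prs);
    deltas[t] = mv[t].delta;
  }
  return List::create(_["kind"] = kinds, _["pairs"] = prs,
                      _["delta"] = deltas, _["n_evaluated"] = (double)st.n_eval);
}

// [[Rcpp::export]]
List cpp_refine(IntegerMatrix pairs, NumericMatrix A, NumericMatrix B,
                NumericMatrix DA, NumericMatrix DB, List spec, int min_block,
                bool allow_reverse, double eps) {
  RefState st;
  st.A = arma::mat(A.begin(), A.nrow(), A.ncol());
  st.B = arma::mat(B.begin(), B.nrow(), B.ncol());
  st.DA = arma::mat(DA.begin(), DA.nrow(), DA.ncol());
  st.DB = arma::mat(DB.begin(), DB.nrow(), DB.ncol());
  st.spec = as_spec(spec);
  st.min_block = min_block;
  st.allow_reverse = allow_reverse;
  st.eps = eps;
  st.LA = A.nrow();
  st.LB = B.nrow();
  st.mapA.assign(st.LA, -1);
  st.mapB.assign(st.LB, -1);
  PairVec p0 = as_pairs(pairs);
  for (size_t t = 0; t < p0.size(); ++t) {
    if (st.mapA[p0[t][0]] >= 0 || st.mapB[p0[t][1]] >= 0)
      stop("input alignment is not one-to-one");
    st.mapA[p0[t][0]] = p0[t][1];
    st.mapB[p0[t][1]] = p0[t][0];
  }
  st.n_eval = 0;
  st.cur = st.score_of(p0);

  std::vector<double> trace;
  int n_acc = 0;

  // Outer loop: the touched-residue bookkeeping can leave an improving move
  // undiscovered (every accepted move changes the global superposition), so
  // full rebuilds repeat until one finds nothing.  Each accepted move
  // strictly increases the score, so this terminates.
  for (;;) {
    std::vector<Move> list = collect_moves(st, NULL, true);
    if (list.empty()) break;
    while (!list.empty()) {
      size_t best = 0;
      for (size_t t = 1; t < list.size(); ++t)
        if (move_before(list[t], list[best])) best = t;
      Move mv = list[best];
      list.erase(list.begin() + best);
      if (!applicable(st, mv)) continue;
      PairVec cand = apply_move(st, mv);
      if (!valid_alignment(cand, st.min_block, st.allow_reverse)) continue;
      double sc = st.score_of(cand);
      if (sc - st.cur <= st.eps) continue;     // stale delta: discard
      // accept
      if (mv.kind == 1 || mv.kind == 3) {
        for (size_t t = 0; t < mv.prs.size(); ++t) {
          st.mapA[mv.prs[t][0]] = mv.prs[t][1];
          st.mapB[mv.prs[t][1]] = mv.prs[t][0];
        }
      } else {
        for (size_t t = 0; t < mv.prs.size(); ++t) {
          st.mapA[mv.prs[t][0]] = -1;
          st.mapB[mv.prs[t][1]] = -1;
        }
      }
      st.cur = sc;
      trace.push_back(sc);
      ++n_acc;
      Touched tch;
      for (size_t t = 0; t < mv.prs.size(); ++t) {
        tch.a.insert(mv.prs[t][0]);
        tch.b.insert(mv.prs[t][1]);
      }
      std::vector<Move> keep;
      for (size_t t = 0; t < list.size(); ++t)
        if (!tch.hits(list[t].prs)) keep.push_back(list[t]);
      list = keep;
      std::vector<Move> fresh = collect_moves(st, &tch, true);
      for (size_t t = 0; t < fresh.size(); ++t) list.push_back(fresh[t]);
    }
  }

  return List::create(_["pairs"] = pairs_out(st.pairs()),
                      _["score"] = st.cur,
                      _["score_trace"] = NumericVector(trace.begin(), trace.end()),
                      _["n_accepted"] = n_acc,
                      _["n_evaluated"] = (double)st.n_eval);
}

// ---------------------------------------------------------------------------
// exhaustive search over all constraint-satisfying alignments (tiny chains)
// used as an independent global-optimality oracle

struct EnumState {
  const arma::mat *A, *B, *DA, *DB;
  Spec spec;
  int min_block;
  bool allow_reverse;
  int LA, LB;
  std::vector<int> usedB;
  PairVec cur;
  double best;
  PairVec best_pairs;
  long n_checked;
};

static void enum_rec(EnumState& es, int i) {
  if (i == es.LA) {
    if (es.cur.empty()) return;
    if (!valid_alignment(es.cur, es.min_block, es.allow_reverse)) return;
    ++es.n_checked;
    double sc = eval_score(es.cur, *es.A, *es.B, *es.DA, *es.DB, es.spec);
    if (sc > es.best) {
      es.best = sc;
      es.best_pairs = es.cur;
    }
    return;
  }
  enum_rec(es, i + 1);                    // residue i unaligned
  for (int j = 0; j < es.LB; ++j) {
    if (es.usedB[j]) continue;
    es.usedB[j] = 1;
    es.cur.push_back({i, j});
    enum_rec(es, i + 1);
    es.cur.pop_back();
    es.usedB[j] = 0;
  }
}

// [[Rcpp::export]]
List cpp_enumerate_best(NumericMatrix A, NumericMatrix B, NumericMatrix DA,
                        NumericMatrix DB, List spec, int min_block,
                        bool allow_reverse) {
  if (A.nrow() > 10 || B.nrow() > 10)
    stop("exhaustive enumeration is limited to chains of at most 10 residues");
  EnumState es;
  arma::mat Am(A.begin(), A.nrow(), A.ncol());
  arma::mat Bm(B.begin(), B.nrow(), B.ncol());
  arma::mat DAm(DA.begin(), DA.nrow(), DA.ncol());
  arma::mat DBm(DB.begin(), DB.nrow(), DB.ncol());
  es.A = &Am; es.B = &Bm; es.DA = &DAm; es.DB = &DBm;
  es.spec = as_spec(spec);
  es.min_block = min_block;
  es.allow_reverse = allow_reverse;
  es.LA = A.nrow();
  es.LB = B.nrow();
  es.usedB.assign(es.LB, 0);
  es.best = -std::numeric_limits<double>::infinity();
  es.n_checked = 0;
  enum_rec(es, 0);
  if (es.best_pairs.empty())
    stop("no constraint-satisfying alignment exists for these chains");
  return List::create(_["score"] = es.best,
                      _["pairs"] = pairs_out(es.best_pairs),
                      _["n_checked"] = (double)es.n_checked);
}
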