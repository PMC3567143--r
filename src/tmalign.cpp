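// TM-score structural alignment core.
//
// Implements the fragment-seeded, iteratively refined alignment search used
// by the structural-distance layer: Kabsch superposition, the TM-score
// "Max" search over superpositions seeded from contiguous aligned fragments,
// sequential dynamic programming on a distance-derived score matrix, and the
// full pairwise alignment driver.  All heavy loops live here; the R layer
// only wraps inputs and results.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Transform {
  arma::mat33 R;   // proper rotation
  arma::vec3 t;    // translation, Å
};

// Least-squares superposition of B onto A (both k x 3), reflection-corrected.
// Returns transform such that  B' = B * R^T + t  minimises RMSD to A.
Transform kabsch(const arma::mat& A, const arma::mat& B) {
  arma::rowvec cA = arma::mean(A, 0);
  arma::rowvec cB = arma::mean(B, 0);
  arma::mat A0 = A.each_row() - cA;
  arma::mat B0 = B.each_row() - cB;
  arma::mat H = B0.t() * A0;              // 3x3 covariance
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t());
  arma::mat33 D = arma::eye(3, 3);
  D(2, 2) = (d < 0.0) ? -1.0 : 1.0;       // keep rotation proper
  Transform tr;
  tr.R = V * D * U.t();
  tr.t = cA.t() - tr.R * cB.t();
  return tr;
}

inline arma::mat apply_tr(const Transform& tr, const arma::mat& B) {
  arma::mat out = B * tr.R.t();
  out.each_row() += tr.t.t();
  return out;
}

double rmsd_after(const arma::mat& A, const arma::mat& Bt) {
  arma::mat d = A - Bt;
  return std::sqrt(arma::accu(d % d) / A.n_rows);
}

// TM-score sum for a fixed correspondence under a fixed transform.
double tm_sum(const arma::mat& A, const arma::mat& Bt, double d0) {
  double s = 0.0;
  const double d02 = d0 * d0;
  for (arma::uword i = 0; i < A.n_rows; ++i) {
    double dx = A(i, 0) - Bt(i, 0);
    double dy = A(i, 1) - Bt(i, 1);
    double dz = A(i, 2) - Bt(i, 2);
    s += 1.0 / (1.0 + (dx * dx + dy * dy + dz * dz) / d02);
  }
  return s;
}

// The "Max" search: best superposition for a fixed residue correspondence.
// Seeds from contiguous fragments of length L_ali, L_ali/2, L_ali/4 (>= 4);
// each seed refined by re-superposing on the subset of pairs closer than a
// growing inclusion cutoff until that subset is stable.  Returns the best
// TM sum and its transform.
double tm_search(const arma::mat& A, const arma::mat& B, double d0,
                 Transform& best_tr) {
  const arma::uword n = A.n_rows;
  double best = -1.0;
  std::vector<arma::uword> frag_lens;
  for (arma::uword L : {n, n / 2, n / 4}) {
    L = std::max<arma::uword>(L, 4);
    if (frag_lens.empty() || frag_lens.back() != L) frag_lens.push_back(L);
  }
  const double d_cut_max = std::max(8.0, d0 + 4.5);
  for (arma::uword Lf : frag_lens) {
    arma::uword step = std::max<arma::uword>(1, Lf / 2);
    for (arma::uword start = 0; start + Lf <= n; start += step) {
      Transform tr = kabsch(A.rows(start, start + Lf - 1),
                            B.rows(start, start + Lf - 1));
      arma::uvec prev;
      double d_cut = std::max(3.5, d0);
      for (int it = 0; it < 30; ++it) {
        arma::mat Bt = apply_tr(tr, B);
        double sc = tm_sum(A, Bt, d0);
        if (sc > best) { best = sc; best_tr = tr; }
        arma::vec d2(n);
        for (arma::uword i = 0; i < n; ++i) {
          arma::rowvec dd = A.row(i) - Bt.row(i);
          d2(i) = arma::dot(dd, dd);
        }
        arma::uvec inc = arma::find(d2 < d_cut * d_cut);
        while (inc.n_elem < 3 && d_cut < d_cut_max) {
          d_cut += 0.5;
          inc = arma::find(d2 < d_cut * d_cut);
        }
        if (inc.n_elem < 3) break;
        if (prev.n_elem == inc.n_elem && arma::all(prev == inc)) {
          if (d_cut >= d_cut_max) break;
          d_cut += 0.5;        // grow inclusion cutoff, keep refining
        }
        prev = inc;
        tr = kabsch(A.rows(inc), B.rows(inc));
      }
    }
  }
  return best;
}

// Sequential DP over score matrix S (na x nb), constant gap penalty
// (negative), terminal gaps free.  Tie-break: diagonal, then up (gap in B),
// then left.  Returns aligned index pairs (0-based, strictly increasing).
void dp_align(const arma::mat& S, double gap, std::vector<arma::uword>& ia,
              std::vector<arma::uword>& ib) {
  const arma::uword na = S.n_rows, nb = S.n_cols;
  arma::mat F(na + 1, nb + 1, arma::fill::zeros);
  arma::Mat<unsigned char> P(na + 1, nb + 1, arma::fill::zeros); // 1 diag 2 up 3 left
  for (arma::uword i = 1; i <= na; ++i) {
    for (arma::uword j = 1; j <= nb; ++j) {
      // terminal gaps free: gap cost only when strictly inside
      double gup = F(i - 1, j) + ((j == nb) ? 0.0 : gap);
      double glf = F(i, j - 1) + ((i == na) ? 0.0 : gap);
      double dg = F(i - 1, j - 1) + S(i - 1, j - 1);
      if (dg >= gup && dg >= glf) { F(i, j) = dg; P(i, j) = 1; }
      else if (gup >= glf)        { F(i, j) = gup; P(i, j) = 2; }
      else                        { F(i, j) = glf; P(i, j) = 3; }
    }
  }
  arma::uword i = na, j = nb;
  std::vector<arma::uword> ra, rb;
  while (i > 0 && j > 0) {
    if (P(i, j) == 1) { ra.push_back(i - 1); rb.push_back(j - 1); --i; --j; }
    else if (P(i, j) == 2) --i;
    else --j;
  }
  ia.assign(ra.rbegin(), ra.rend());
  ib.assign(rb.rbegin(), rb.rend());
}

// 3-state secondary-structure string from CA pseudo-dihedrals: H for the
// right-handed ~50 deg helical twist, E for extended (|dihedral| >= 140 deg),
// C otherwise.  Residues near the termini default to C.
std::string ss_string(const arma::mat& X) {
  const arma::uword n = X.n_rows;
  std::string ss(n, 'C');
  for (arma::uword i = 1; i + 2 < n; ++i) {
    arma::vec3 b1 = (X.row(i) - X.row(i - 1)).t();
    arma::vec3 b2 = (X.row(i + 1) - X.row(i)).t();
    arma::vec3 b3 = (X.row(i + 2) - X.row(i + 1)).t();
    arma::vec3 n1 = arma::cross(b1, b2);
    arma::vec3 n2 = arma::cross(b2, b3);
    double x = arma::dot(n1, n2);
    double y = arma::dot(arma::cross(n1, n2), arma::normalise(b2));
    double dih = std::atan2(y, x) * 180.0 / M_PI;
    if (dih > 20.0 && dih < 80.0) ss[i] = 'H';
    else if (std::fabs(dih) >= 140.0) ss[i] = 'E';
  }
  return ss;
}

struct Alignment {
  std::vector<arma::uword> ia, ib;
  bool operator==(const Alignment& o) const { return ia == o.ia && ib == o.ib; }
};

// Evaluate a candidate correspondence: run the Max search under d0_run and
// return the (sum / Lnorm_run) score together with its transform.
double eval_alignment(const arma::mat& A, const arma::mat& B,
                      const Alignment& al, double d0_run, double Lnorm_run,
                      Transform& tr) {
  if (al.ia.size() < 3) return -1.0;
  arma::uvec ua(al.ia.size()), ub(al.ib.size());
  for (size_t k = 0; k < al.ia.size(); ++k) { ua(k) = al.ia[k]; ub(k) = al.ib[k]; }
  double s = tm_search(A.rows(ua), B.rows(ub), d0_run, tr);
  return s / Lnorm_run;
}

} // namespace

// [[Rcpp::export(name = ".cpp_kabsch")]]
List cpp_kabsch(const arma::mat& A, const arma::mat& B) {
  Transform tr = kabsch(A, B);
  arma::mat Bt = apply_tr(tr, B);
  return List::create(_["rotation"] = arma::mat(tr.R),
                      _["translation"] = arma::vec(tr.t),
                      _["rmsd"] = rmsd_after(A, Bt));
}

// [[Rcpp::export(name = ".cpp_tm_search")]]
List cpp_tm_search(const arma::mat& A, const arma::mat& B, double d0,
                   double Lnorm) {
  Transform tr;
  double s = tm_search(A, B, d0, tr);
  return List::create(_["score"] = s / Lnorm,
                      _["rotation"] = arma::mat(tr.R),
                      _["translation"] = arma::vec(tr.t));
}

// [[Rcpp::export(name = ".cpp_dp_align")]]
IntegerMatrix cpp_dp_align(const arma::mat& S, double gap) {
  std::vector<arma::uword> ia, ib;
  dp_align(S, gap, ia, ib);
  IntegerMatrix out(ia.size(), 2);
  for (size_t k = 0; k < ia.size(); ++k) {
    out(k, 0) = ia[k] + 1;  // 1-based for R
    out(k, 1) = ib[k] + 1;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_ss_string")]]
std::string cpp_ss_string(const arma::mat& X) { return ss_string(X); }

// Full heuristic pairwise alignment.  Seeds: gapless threading offsets at
// the given stride, the best-matching pair of contiguous 8-residue fragments,
// and a DP alignment of 3-state secondary-structure strings.  Each seed is
// refined by {superpose -> score matrix -> DP -> new pairs} until the pair
// set repeats or max_iter iterations.  Reports the alignment maximising the
// symmetrised TM-score.
// [[Rcpp::export(name = ".cpp_align_pair")]]
List cpp_align_pair(const arma::mat& A, const arma::mat& B, double gap,
                    int max_iter, int seed_stride) {
  const arma::uword LA = A.n_rows, LB = B.n_rows;
  const arma::uword Lmax = std::max(LA, LB), Lmin = std::min(LA, LB);
  auto d0_of = [](double L) {
    double v = (L > 15.0) ? 1.24 * std::cbrt(L - 15.0) - 1.8 : 0.5;
    return std::max(v, 0.5);
  };
  const double d0_run = d0_of((double)Lmin);
  const double d0A = d0_of((double)LA), d0B = d0_of((double)LB);

  arma::uword stride = (seed_stride > 0)
      ? (arma::uword)seed_stride
      : std::max<arma::uword>(1, (Lmax + 19) / 20);

  std::vector<Alignment> seeds;
  const arma::sword min_ov = std::min<arma::uword>(Lmin, 8);
  // 1) gapless threading: offset = ia - ib
  for (arma::sword off = -(arma::sword)LB + min_ov;
       off <= (arma::sword)LA - min_ov; off += (arma::sword)stride) {
    Alignment al;
    for (arma::sword ib = 0; ib < (arma::sword)LB; ++ib) {
      arma::sword ia = ib + off;
      if (ia >= 0 && ia < (arma::sword)LA) {
        al.ia.push_back(ia);
        al.ib.push_back(ib);
      }
    }
    if (al.ia.size() >= 3) seeds.push_back(al);
  }
  // 2) best 8-residue fragment pair (sampled at stride 4), extended gaplessly
  if (Lmin >= 8) {
    double best_r = std::numeric_limits<double>::infinity();
    arma::uword bi = 0, bj = 0;
    for (arma::uword i = 0; i + 8 <= LA; i += 4) {
      for (arma::uword j = 0; j + 8 <= LB; j += 4) {
        Transform tr = kabsch(A.rows(i, i + 7), B.rows(j, j + 7));
        double r = rmsd_after(A.rows(i, i + 7), apply_tr(tr, B.rows(j, j + 7)));
        if (r < best_r) { best_r = r; bi = i; bj = j; }
      }
    }
    Alignment al;
    arma::sword off = (arma::sword)bi - (arma::sword)bj;
    for (arma::sword jb = 0; jb < (arma::sword)LB; ++jb) {
      arma::sword ja = jb + off;
      if (ja >= 0 && ja < (arma::sword)LA) { al.ia.push_back(ja); al.ib.push_back(jb); }
    }
    if (al.ia.size() >= 3) seeds.push_back(al);
  }
  // 3) secondary-structure string DP (match +1, mismatch 0, gap -1)
  {
    std::string sa = ss_string(A), sb = ss_string(B);
    arma::mat S(LA, LB);
    for (arma::uword i = 0; i < LA; ++i)
      for (arma::uword j = 0; j < LB; ++j)
        S(i, j) = (sa[i] == sb[j]) ? 1.0 : 0.0;
    Alignment al;
    dp_align(S, -1.0, al.ia, al.ib);
    if (al.ia.size() >= 3) seeds.push_back(al);
  }

  // Candidates are ranked during refinement by the score normalised with the
  // shorter length (cheap, one Max search); the symmetrised two-sided score
  // is evaluated only for the top few distinct candidates at the end.
  const size_t K = 4;
  std::vector<std::pair<double, Alignment>> top;  // run-score, alignment
  auto consider = [&](const Alignment& al, double run_score) {
    for (auto& p : top)
      if (p.second == al) {
        if (run_score > p.first) p.first = run_score;
        return;
      }
    top.emplace_back(run_score, al);
    std::sort(top.begin(), top.end(),
              [](const std::pair<double, Alignment>& a,
                 const std::pair<double, Alignment>& b) {
                return a.first > b.first;
              });
    if (top.size() > K) top.pop_back();
  };

  for (const Alignment& seed : seeds) {
    Alignment cur = seed;
    std::vector<Alignment> seen;
    for (int it = 0; it < max_iter; ++it) {
      Transform tr;
      double sc = eval_alignment(A, B, cur, d0_run, (double)Lmin, tr);
      if (sc < 0) break;
      consider(cur, sc);
      arma::mat Bt = apply_tr(tr, B);
      arma::mat S(LA, LB);
      const double d02 = d0_run * d0_run;
      for (arma::uword i = 0; i < LA; ++i) {
        for (arma::uword j = 0; j < LB; ++j) {
          double dx = A(i, 0) - Bt(j, 0), dy = A(i, 1) - Bt(j, 1),
                 dz = A(i, 2) - Bt(j, 2);
          S(i, j) = 1.0 / (1.0 + (dx * dx + dy * dy + dz * dz) / d02);
        }
      }
      Alignment nxt;
      dp_align(S, gap, nxt.ia, nxt.ib);
      if (nxt.ia.size() < 3) break;
      bool cycle = (nxt == cur);
      for (const Alignment& a : seen)
        if (a == nxt) { cycle = true; break; }
      seen.push_back(cur);
      cur = nxt;
      if (cycle) break;
    }
  }

  // two-sided evaluation of the retained candidates; report the best tm_sym
  double best_sym = -1.0, tmA = 0.0, tmB = 0.0;
  Alignment best_al;
  Transform best_tr;
  for (auto& p : top) {
    Transform trA, trB;
    double a = eval_alignment(A, B, p.second, d0A, (double)LA, trA);
    double b = eval_alignment(A, B, p.second, d0B, (double)LB, trB);
    double sym = 0.5 * (a + b);
    if (sym > best_sym) {
      best_sym = sym;
      tmA = a;
      tmB = b;
      best_al = p.second;
      best_tr = (LA <= LB) ? trA : trB;  // transform from the shorter-side search
    }
  }
  double tm_sym = best_sym;

  const size_t np = best_al.ia.size();
  IntegerMatrix pairs(np, 2);
  NumericVector di(np);
  arma::mat Bt = apply_tr(best_tr, B);
  for (size_t k = 0; k < np; ++k) {
    pairs(k, 0) = best_al.ia[k] + 1;
    pairs(k, 1) = best_al.ib[k] + 1;
    arma::rowvec dd = A.row(best_al.ia[k]) - Bt.row(best_al.ib[k]);
    di[k] = std::sqrt(arma::dot(dd, dd));
  }
  return List::create(_["pairs"] = pairs,
                      _["rotation"] = arma::mat(best_tr.R),
                      _["translation"] = arma::vec(best_tr.t),
                      _["per_pair_distance"] = di,
                      _["tm_norm_A"] = tmA,
                      _["tm_norm_B"] = tmB,
                      _["tm_sym"] = tm_sym);
}
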